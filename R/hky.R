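# HKY85 rate-matrix machinery shared by the pairwise-ML distance and the
# sequence-evolution simulator. Base order everywhere: A, C, G, T.

# equilibrium frequencies from a GC-symmetric parameterization (A = T, G = C)
.gc_freqs <- function(gc_equilibrium) {
  if (gc_equilibrium <= 0 || gc_equilibrium >= 1) stop("gc_equilibrium must be in (0,1)")
  at <- (1 - gc_equilibrium) / 2
  gc <- gc_equilibrium / 2
  c(A = at, C = gc, G = gc, T = at)
}

# HKY instantaneous rate matrix scaled to one expected substitution per site
# per unit time at equilibrium
.hky_Q <- function(freqs, kappa) {
  stopifnot(length(freqs) == 4, all(freqs > 0), abs(sum(freqs) - 1) < 1e-8)
  Q <- matrix(rep(freqs, each = 4), 4, 4,
              dimnames = list(.BASES, .BASES))
  # transitions: A<->G, C<->T
  Q["A", "G"] <- Q["A", "G"] * kappa
  Q["G", "A"] <- Q["G", "A"] * kappa
  Q["C", "T"] <- Q["C", "T"] * kappa
  Q["T", "C"] <- Q["T", "C"] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# spectral decomposition of a reversible Q for fast P(t) = exp(Qt)
.hky_eigen <- function(freqs, kappa) {
  Q <- .hky_Q(freqs, kappa)
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(vectors = e$vectors, values = e$values, d = d, Q = Q)
}

.hky_pmat <- function(eig, t) {
  P <- diag(1 / eig$d) %*% eig$vectors %*%
    diag(exp(eig$values * t)) %*% t(eig$vectors) %*% diag(eig$d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(.BASES, .BASES)
  P
}
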