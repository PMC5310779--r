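#' Construct a pairwise alignment
#'
#' @param seq_a,seq_b Equal-length gapped DNA strings.
#' @return A \code{pairwise_alignment} with \code{comparable_sites} = number of
#'   columns free of gaps and N in both sequences.
#' @export
pairwise_alignment <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop(sprintf("aligned sequences differ in length (%d vs %d)",
                 nchar(seq_a), nchar(seq_b)))
  }
  .validate_dna(seq_a, "seq_a"); .validate_dna(seq_b, "seq_b")
  a <- .chars(seq_a); b <- .chars(seq_b)
  keep <- a %in% .BASES & b %in% .BASES
  structure(list(seq_a = seq_a, seq_b = seq_b, comparable_sites = sum(keep)),
            class = "pairwise_alignment")
}

#' Pairwise deletion of gap/N columns
#'
#' Removes every column where either sequence carries \code{-} or \code{N}
#' (pairwise deletion, appropriate for remnants with gene-specific deletion
#' patterns).
#'
#' @param aln A \code{\link{pairwise_alignment}}.
#' @return The masked \code{pairwise_alignment}.
#' @export
pairwise_mask <- function(aln) {
  a <- .chars(aln$seq_a); b <- .chars(aln$seq_b)
  keep <- a %in% .BASES & b %in% .BASES
  if (!any(keep)) stop("no comparable sites after masking")
  pairwise_alignment(paste(a[keep], collapse = ""), paste(b[keep], collapse = ""))
}

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Pairwise nucleotide distance
#'
#' Closed forms for \code{p} (mismatch fraction), \code{JC69}
#' (\eqn{t = -\frac{3}{4}\ln(1 - 4p/3)}) and \code{K80}
#' (\eqn{t = -\frac{1}{2}\ln(1-2P-Q) - \frac{1}{4}\ln(1-2Q)} from transition /
#' transversion proportions P, Q), plus a numerical pairwise maximum-likelihood
#' \code{HKY} distance with empirical base frequencies. Saturated pairs
#' (non-positive log arguments) return \code{Inf} with \code{saturated = TRUE}.
#'
#' @param aln A \code{\link{pairwise_alignment}} (masked internally).
#' @param model One of \code{"p"}, \code{"jc69"}, \code{"k80"}, \code{"hky"}.
#' @return List with \code{model}, \code{t}, \code{kappa_hat} (K80/HKY),
#'   \code{se_t} (K80 delta method / HKY observed information),
#'   \code{p_raw}, \code{comparable_sites}, \code{saturated}.
#' @export
nucleotide_distance <- function(aln, model = c("k80", "p", "jc69", "hky")) {
  model <- match.arg(model)
  aln <- pairwise_mask(aln)
  a <- .chars(aln$seq_a); b <- .chars(aln$seq_b)
  n <- length(a)
  diff <- a != b
  p <- mean(diff)
  res <- list(model = model, t = NA_real_, kappa_hat = NA_real_,
              se_t = NA_real_, p_raw = p, comparable_sites = n,
              saturated = FALSE)
  if (model == "p") {
    res$t <- p
  } else if (model == "jc69") {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) { res$t <- Inf; res$saturated <- TRUE }
    else res$t <- -0.75 * log(arg)
  } else if (model == "k80") {
    P <- mean(diff & .is_transition(a, b))
    Q <- p - P
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) { res$t <- Inf; res$saturated <- TRUE }
    else {
      res$t <- -0.5 * log(a1) - 0.25 * log(a2)
      res$kappa_hat <- if (Q > 0 && P > 0) {
        ts_d <- -0.5 * log(a1) + 0.25 * log(a2)
        tv_d <- -0.25 * log(a2)
        ts_d / tv_d
      } else NA_real_
      # delta-method SE from the multinomial (P, Q) covariance
      dP <- 1 / a1
      dQ <- 0.5 / a1 + 0.5 / a2
      vP <- P * (1 - P) / n; vQ <- Q * (1 - Q) / n; cPQ <- -P * Q / n
      res$se_t <- sqrt(max(dP^2 * vP + dQ^2 * vQ + 2 * dP * dQ * cPQ, 0))
    }
  } else {
    res <- c(res[setdiff(names(res), c("t", "kappa_hat", "se_t", "saturated"))],
             .hky_ml(a, b))
    res <- res[c("model", "t", "kappa_hat", "se_t", "p_raw",
                 "comparable_sites", "saturated")]
    res$model <- model
  }
  res
}

# pairwise maximum-likelihood HKY distance from the 4x4 site-pattern counts
.hky_ml <- function(a, b, tol = 1e-8) {
  ia <- match(a, .BASES); ib <- match(b, .BASES)
  counts <- matrix(tabulate((ia - 1L) * 4L + ib, nbins = 16L), 4, 4, byrow = TRUE)
  freqs <- (tabulate(ia, 4L) + tabulate(ib, 4L))
  freqs <- (freqs + 0.5) / sum(freqs + 0.5)   # guard against absent bases
  p <- mean(a != b)
  if (p == 0) {
    return(list(t = 0, kappa_hat = NA_real_, se_t = 0, saturated = FALSE))
  }
  t0 <- max(-0.75 * log(max(1 - 4 * p / 3, 1e-6)), 1e-4)
  nll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2])
    eig <- .hky_eigen(freqs, kappa)
    P <- .hky_pmat(eig, t)
    L <- log(pmax(freqs * P, 1e-300))
    -sum(counts * L)
  }
  fit <- optim(c(log(t0), log(2)), nll, method = "Nelder-Mead",
               control = list(reltol = tol * 1e-2, maxit = 2000))
  t_hat <- exp(fit$par[1]); kappa_hat <- exp(fit$par[2])
  se_t <- tryCatch({
    H <- optimHess(fit$par, nll)
    V <- solve(H)
    t_hat * sqrt(max(V[1, 1], 0))   # delta method from the log scale
  }, error = function(e) NA_real_)
  list(t = t_hat, kappa_hat = kappa_hat, se_t = se_t, saturated = !is.finite(t_hat))
}

# --- NG86 machinery ----------------------------------------------------------

# per-codon synonymous site count (sum over the 3 positions of the fraction of
# the 3 possible changes that preserve the amino acid; changes to stop count as
# non-synonymous)
.syn_sites_by_code <- function() {
  if (!is.null(.pkg_env$syn64)) return(.pkg_env$syn64)
  aa <- .aa_by_code()
  syn <- numeric(64)
  for (code in 0:63) {
    b <- c(code %/% 16L, (code %/% 4L) %% 4L, code %% 4L) + 1L
    if (aa[code + 1L] == "*") { syn[code + 1L] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(1:4, b[pos])) {
        nb <- b; nb[pos] <- alt
        ncode <- (nb[1] - 1L) * 16L + (nb[2] - 1L) * 4L + nb[3]
        if (aa[ncode] != "*" && aa[ncode] == aa[code + 1L]) s <- s + 1 / 3
      }
    }
    syn[code + 1L] <- s
  }
  .pkg_env$syn64 <- syn
  syn
}

.codon_code <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

# pathway-averaged synonymous/non-synonymous difference counts for one codon
# pair; pathways through stop codons are excluded (all-blocked pairs fall back
# to averaging over every ordering)
.ng86_pair_diffs <- function(c1, c2) {
  aa <- .aa_by_code()
  pos <- which(c1 != c2)
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  orders <- if (d == 1L) list(pos) else {
    perms <- list()
    idx <- seq_len(d)
    gen <- function(prefix, rest) {
      if (!length(rest)) { perms[[length(perms) + 1L]] <<- pos[prefix]; return() }
      for (r in seq_along(rest)) gen(c(prefix, rest[r]), rest[-r])
    }
    gen(integer(0), idx)
    perms
  }
  eval_path <- function(ord) {
    cur <- c1
    s <- 0; n <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- c2[p]
      a_cur <- aa[.codon_code(cur[1], cur[2], cur[3])]
      a_nxt <- aa[.codon_code(nxt[1], nxt[2], nxt[3])]
      if (a_nxt == "*") blocked <- TRUE
      if (a_cur == a_nxt) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n, blocked = as.numeric(blocked))
  }
  evals <- vapply(orders, eval_path, numeric(3))
  ok <- evals["blocked", ] == 0
  use <- if (any(ok)) evals[, ok, drop = FALSE] else evals
  c(sd = mean(use["s", ]), nd = mean(use["n", ]))
}

# 64x64 lookup tables of pathway-averaged syn/non-syn difference counts,
# built once per session (pairs involving stop codons stay NA)
.ng86_pair_tables <- function() {
  if (!is.null(.pkg_env$ng86_sd)) {
    return(list(sd = .pkg_env$ng86_sd, nd = .pkg_env$ng86_nd))
  }
  aa <- .aa_by_code()
  SD <- matrix(NA_real_, 64, 64)
  ND <- matrix(NA_real_, 64, 64)
  codon_bases <- t(vapply(0:63, function(code) {
    c(code %/% 16L, (code %/% 4L) %% 4L, code %% 4L) + 1L
  }, integer(3)))
  for (i in 1:64) {
    if (aa[i] == "*") next
    for (j in 1:64) {
      if (aa[j] == "*") next
      d <- .ng86_pair_diffs(codon_bases[i, ], codon_bases[j, ])
      SD[i, j] <- d["sd"]; ND[i, j] <- d["nd"]
    }
  }
  .pkg_env$ng86_sd <- SD; .pkg_env$ng86_nd <- ND
  list(sd = SD, nd = ND)
}

#' Nei-Gojobori (1986) dN/dS for a pairwise codon alignment
#'
#' Synonymous site fractions from the standard genetic code averaged over the
#' two sequences; pathway-averaged counting of synonymous / non-synonymous
#' differences for multi-hit codons (all orderings weighted equally, pathways
#' through stop codons excluded); Jukes-Cantor correction applied to pN and pS
#' separately. Codons containing a stop, N or gap in either sequence are
#' excluded pairwise.
#'
#' @param codon_aln A \code{\link{pairwise_alignment}} of in-frame coding
#'   sequences (length divisible by 3).
#' @return List with \code{N_sites}, \code{S_sites}, \code{pN}, \code{pS},
#'   \code{dN}, \code{dS}, \code{ratio} (NA with \code{ds_zero = TRUE} when
#'   dS = 0), \code{codons_compared}.
#' @export
ng86_dn_ds <- function(codon_aln) {
  a <- .chars(codon_aln$seq_a); b <- .chars(codon_aln$seq_b)
  if (length(a) %% 3L != 0L) stop("codon alignment length not divisible by 3")
  aa64 <- .aa_by_code()
  syn64 <- .syn_sites_by_code()
  tabs <- .ng86_pair_tables()
  nc <- length(a) %/% 3L
  ia <- matrix(match(a, .BASES), nrow = 3L)
  ib <- matrix(match(b, .BASES), nrow = 3L)
  ok_base <- colSums(is.na(ia)) == 0L & colSums(is.na(ib)) == 0L
  code_a <- rep(NA_integer_, nc); code_b <- rep(NA_integer_, nc)
  code_a[ok_base] <- .codon_code(ia[1, ok_base], ia[2, ok_base], ia[3, ok_base])
  code_b[ok_base] <- .codon_code(ib[1, ok_base], ib[2, ok_base], ib[3, ok_base])
  keep <- ok_base & aa64[code_a] != "*" & aa64[code_b] != "*"
  keep[is.na(keep)] <- FALSE
  used <- sum(keep)
  if (used == 0L) stop("no comparable codons")
  S <- sum((syn64[code_a[keep]] + syn64[code_b[keep]]) / 2)
  idx <- cbind(code_a[keep], code_b[keep])
  Sd <- sum(tabs$sd[idx]); Nd <- sum(tabs$nd[idx])
  N <- 3 * used - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) Inf else -0.75 * log(arg)
  }
  dS <- jc(pS); dN <- jc(pN)
  ds_zero <- dS == 0
  ds_saturated <- !is.finite(dS)
  ratio <- if (ds_zero) NA_real_ else unname(dN / dS)  # dN/Inf -> 0 (saturated dS)
  if (is.nan(ratio)) ratio <- NA_real_
  list(N_sites = N, S_sites = S, pN = unname(pN), pS = unname(pS),
       dN = unname(dN), dS = unname(dS), ratio = ratio,
       ds_zero = ds_zero, ds_saturated = ds_saturated, codons_compared = used)
}

#' Distance parameter table against the outgroup ortholog
#'
#' @param gm A \code{gene_matrix}.
#' @param alignments Named list (by gene) of named character vectors: gapped,
#'   equal-length sequences including the outgroup record.
#' @param model Distance model, see \code{\link{nucleotide_distance}}.
#' @return A \code{\link{parameter_table}} of distances t (absent cells NA;
#'   saturated pairs Inf).
#' @export
distance_table <- function(gm, alignments, model = "k80") {
  outg <- gm$outgroup_id
  if (is.na(outg)) stop("gene matrix has no outgroup symbiont")
  values <- matrix(NA_real_, length(gm$gene_order), length(gm$symbiont_order),
                   dimnames = list(gm$gene_order, gm$symbiont_order))
  for (g in gm$gene_order) {
    aln <- alignments[[g]]
    if (is.null(aln) || !(outg %in% names(aln))) {
      stop("missing outgroup ortholog in the alignment for gene ", g)
    }
    ref <- aln[[outg]]
    recs <- gm$records[gm$records$gene_id == g & gm$records$status != "absent", ]
    for (sym in recs$symbiont_id) {
      if (!(sym %in% names(aln))) {
        stop(sprintf("no aligned sequence for (%s, %s)", g, sym))
      }
      d <- nucleotide_distance(pairwise_alignment(aln[[sym]], ref), model)
      values[g, sym] <- d$t
    }
  }
  parameter_table(values, "distance", status = .status_matrix(gm),
                  clade_map = .clade_map(gm))
}

#' Per-gene, per-clade dN/dS from within-clade pairwise comparisons
#'
#' For each gene and clade, NG86 dN/dS is computed for every pair of intact
#' in-clade copies and averaged. Counting methods saturate on synonymous
#' sites against a distant outgroup (dS runs into the Jukes-Cantor 3/4
#' bound), so within-clade pairs -- an order of magnitude less diverged --
#' are the appropriate comparison for per-clade selection summaries.
#'
#' @inheritParams distance_table
#' @return data.frame with columns gene, clade, mean, sd, n_pairs (pairs with
#'   a defined, finite ratio; clades with fewer than 2 intact copies give NA).
#' @export
clade_dnds <- function(gm, alignments) {
  clade_map <- .clade_map(gm)
  clades <- setdiff(unique(clade_map), "outgroup")
  out <- expand.grid(gene = gm$gene_order, clade = clades,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_; out$n_pairs <- 0L
  for (i in seq_len(nrow(out))) {
    g <- out$gene[i]
    aln <- alignments[[g]]
    if (is.null(aln)) stop("missing alignment for gene ", g)
    recs <- gm$records[gm$records$gene_id == g & gm$records$status == "intact", ]
    syms <- intersect(recs$symbiont_id[recs$clade == out$clade[i]], names(aln))
    if (length(syms) < 2L) next
    prs <- utils::combn(syms, 2L)
    vals <- vapply(seq_len(ncol(prs)), function(j) {
      ng86_dn_ds(pairwise_alignment(aln[[prs[1, j]]], aln[[prs[2, j]]]))$ratio
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    out$n_pairs[i] <- length(vals)
    if (length(vals)) {
      out$mean[i] <- mean(vals)
      out$sd[i] <- if (length(vals) > 1L) sd(vals) else 0
    }
  }
  out
}

#' dN/dS parameter table for intact genes against the outgroup ortholog
#'
#' dN/dS is computed for intact records only; degraded remnants (frameshifted,
#' stop-ridden) are analysed as nucleotide distance instead.
#'
#' @inheritParams distance_table
#' @return A \code{\link{parameter_table}} of NG86 dN/dS ratios (non-intact
#'   cells NA).
#' @export
dnds_table <- function(gm, alignments) {
  outg <- gm$outgroup_id
  if (is.na(outg)) stop("gene matrix has no outgroup symbiont")
  values <- matrix(NA_real_, length(gm$gene_order), length(gm$symbiont_order),
                   dimnames = list(gm$gene_order, gm$symbiont_order))
  for (g in gm$gene_order) {
    aln <- alignments[[g]]
    if (is.null(aln) || !(outg %in% names(aln))) {
      stop("missing outgroup ortholog in the alignment for gene ", g)
    }
    ref <- aln[[outg]]
    recs <- gm$records[gm$records$gene_id == g & gm$records$status == "intact", ]
    for (sym in recs$symbiont_id) {
      if (sym == outg) next
      r <- ng86_dn_ds(pairwise_alignment(aln[[sym]], ref))
      values[g, sym] <- r$ratio
    }
  }
  parameter_table(values, "dnds", status = .status_matrix(gm),
                  clade_map = .clade_map(gm))
}
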