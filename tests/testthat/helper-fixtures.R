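# shared fixture builders; everything is generated in code (no stored data)

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# brute-force repeat oracle: mark every k-mer start position whose k-mer
# occurs at any other start position (pair enumeration, string comparison)
oracle_repeat_count <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  km <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  sum(vapply(seq_len(n), function(p) any(km[-p] == km[p]), NA))
}

# a small two-clade matrix built from in-code FASTA + metadata
tiny_gene_matrix <- function() {
  meta <- data.frame(
    symbiont_id = rep(c("Out", "S1", "S2", "S3"), each = 2),
    gene_id = rep(c("gA", "gB"), 4),
    clade = rep(c("outgroup", "I", "I", "II"), each = 2),
    status = c("intact", "intact", "intact", "degraded",
               "intact", "intact", "intact", "absent"),
    stringsAsFactors = FALSE
  )
  set.seed(42)
  seqs <- c(
    "Out|gA" = "ATGAAACCCGGGTTTTAA", "Out|gB" = "ATGACGTACGTACGTTAG",
    "S1|gA" = "ATGAAACCCGGATTTTAA", "S1|gB" = "ATGACGTACG",
    "S2|gA" = "ATGAAACCAGGGTTTTAA", "S2|gB" = "ATGACGTACGTACGATAG",
    "S3|gA" = "ATGAAACCCGGGTTATAA"
  )
  fasta <- data.frame(header = names(seqs), sequence = unname(seqs),
                      stringsAsFactors = FALSE)
  suppressWarnings(build_matrix(fasta, meta))
}

# exhaustive two-sided Mann-Whitney p by label enumeration
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n, n1)
  us <- apply(labelings, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- min(u_obs, n1 * (n - n1) - u_obs)
  hi <- max(u_obs, n1 * (n - n1) - u_obs)
  mean(us <= lo | us >= hi)
}

# independent NG86 oracle: own site counting and pathway enumeration working
# directly on codon strings and Biostrings' code table
oracle_ng86 <- function(seq1, seq2) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(codon) unname(code[codon])
  syn_sites <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (nb in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- nb
        if (translate1(alt) != "*" && translate1(alt) == translate1(codon)) {
          s <- s + 1 / 3
        }
      }
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  path_counts <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    evals <- lapply(perms(pos), function(ord) {
      cur <- c1; s <- 0; n <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (translate1(nxt) == "*") blocked <- TRUE
        if (translate1(cur) == translate1(nxt)) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n, blocked)
    })
    m <- do.call(rbind, evals)
    ok <- m[, 3] == 0
    use <- if (any(ok)) m[ok, , drop = FALSE] else m
    c(mean(use[, 1]), mean(use[, 2]))
  }
  nc <- nchar(seq1) %/% 3
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_len(nc)) {
    c1 <- substr(seq1, (i - 1) * 3 + 1, i * 3)
    c2 <- substr(seq2, (i - 1) * 3 + 1, i * 3)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (translate1(c1) == "*" || translate1(c2) == "*") next
    used <- used + 1
    S <- S + (syn_sites(c1) + syn_sites(c2)) / 2
    pc <- path_counts(c1, c2)
    Sd <- Sd + pc[1]; Nd <- Nd + pc[2]
  }
  N <- 3 * used - S
  jc <- function(p) if (1 - 4 * p / 3 <= 0) Inf else -0.75 * log(1 - 4 * p / 3)
  list(S_sites = S, N_sites = N, pS = Sd / S, pN = Nd / N,
       dS = jc(Sd / S), dN = jc(Nd / N))
}
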