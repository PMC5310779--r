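#' GC content of a DNA sequence
#'
#' Gaps (\code{-}) and \code{N} are excluded from both numerator and
#' denominator, so degraded remnants with alignment gaps are measured on their
#' counted bases only.
#'
#' @param seq DNA string over \code{A,C,G,T,N,-}.
#' @return List with \code{gc_fraction} (0-1), \code{gc_percent} (0-100),
#'   \code{n_counted}, \code{n_excluded}.
#' @examples
#' gc_content("ATGC-N")  # gc_fraction 0.5, n_excluded 2
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  .validate_dna(seq)
  ch <- .chars(seq)
  counted <- ch %in% .BASES
  n_counted <- sum(counted)
  if (n_counted == 0L) stop("no counted bases (sequence is all gaps/N)")
  gc <- sum(ch %in% c("G", "C"))
  frac <- gc / n_counted
  list(gc_fraction = frac, gc_percent = 100 * frac,
       n_counted = n_counted, n_excluded = length(ch) - n_counted)
}

#' GC-content parameter table (percent) for a gene matrix
#'
#' @param gm A \code{gene_matrix}.
#' @return A \code{\link{parameter_table}} of \code{gc_percent} values; absent
#'   cells are NA.
#' @export
gc_table <- function(gm) {
  values <- .cell_apply(gm, function(rec) gc_content(rec$sequence)$gc_percent)
  parameter_table(values, "gc", status = .status_matrix(gm),
                  clade_map = .clade_map(gm))
}
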