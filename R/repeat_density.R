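#' Sliding-window specification for repeat-density profiling
#'
#' Defaults follow the study design for short-repeat density in reduced
#' genomes: 5-mers in 200 bp windows shifted by 10 bp, moving average disabled
#' (\code{ma_span = 1}).
#'
#' @param window Window length W in bases.
#' @param shift Window shift s in bases.
#' @param k k-mer length.
#' @param ma_span Moving-average span in windows (odd; 1 = off).
#' @export
window_spec <- function(window = 200L, shift = 10L, k = 5L, ma_span = 1L) {
  window <- as.integer(window); shift <- as.integer(shift)
  k <- as.integer(k); ma_span <- as.integer(ma_span)
  if (k < 1L || k > window) stop("need 1 <= k <= window")
  if (shift < 1L) stop("shift must be >= 1")
  if (ma_span < 1L) stop("ma_span must be >= 1")
  if (ma_span %% 2L == 0L) stop("ma_span must be odd")
  structure(list(window = window, shift = shift, k = k, ma_span = ma_span),
            class = "window_spec")
}

# integer k-mer codes for an encoded sequence (ints 1..4); base-4 rolling code.
# Only used for k <= 12 (codes stay below 4^12); longer k falls back to strings.
.kmer_codes <- function(ints, k) {
  n <- length(ints) - k + 1L
  v <- ints - 1L
  code <- numeric(n)
  for (j in seq_len(k)) {
    code <- code + v[j:(j + n - 1L)] * 4^(k - j)
  }
  code
}

.kmer_keys <- function(seq, ints, k) {
  if (k <= 12L) {
    .kmer_codes(ints, k)
  } else {
    n <- nchar(seq) - k + 1L
    substring(seq, seq_len(n), seq_len(n) + k - 1L)
  }
}

# count positions whose k-mer key occurs >= 2 times (occurrence counting);
# small numeric codes go through tabulate, long k-mers through table
.count_repeated <- function(keys, nbins = NULL) {
  if (is.numeric(keys) && !is.null(nbins) && nbins <= 65536L) {
    cnt <- tabulate(as.integer(keys) + 1L, nbins = nbins)
    return(sum(cnt[cnt >= 2L]))
  }
  tb <- table(keys)
  sum(tb[tb >= 2L])
}

# tandem variant: positions with an identical adjacent (offset k) copy
.count_tandem <- function(keys, k) {
  n <- length(keys)
  if (n <= k) return(0L)
  adj <- keys[seq_len(n - k)] == keys[(k + 1L):n]
  hit <- logical(n)
  hit[seq_len(n - k)][adj] <- TRUE
  hit[(k + 1L):n][adj] <- TRUE
  sum(hit)
}

#' Count repeated k-mer occurrences in one window
#'
#' Returns the number of k-mer start positions whose k-mer occurs at one or
#' more other start positions in the same window (overlapping occurrences
#' allowed). Each repeated occurrence counts once -- occurrence counting, not
#' pair counting, so three identical copies contribute 3, not 3 pairs. With
#' \code{tandem_only = TRUE} only positions with an identical directly adjacent
#' copy (offset k) are counted, a stricter variant kept for sensitivity
#' analysis.
#'
#' @param window_seq DNA string over \code{A,C,G,T}.
#' @param k k-mer length (must not exceed the window length).
#' @param tandem_only Count only adjacent-copy repeats.
#' @return Integer count in \code{[0, W - k + 1]}.
#' @examples
#' count_window_repeats("ACGT", 2)   # 0
#' count_window_repeats("AAAAA", 2)  # 4
#' @export
count_window_repeats <- function(window_seq, k, tandem_only = FALSE) {
  k <- as.integer(k)
  if (nchar(window_seq) < k) {
    stop(sprintf("window (%d bp) shorter than k = %d", nchar(window_seq), k))
  }
  ints <- .seq_ints(window_seq, what = "window")
  keys <- .kmer_keys(toupper(window_seq), ints, k)
  nbins <- if (k <= 8L) as.integer(4^k) else NULL
  if (tandem_only) as.integer(.count_tandem(keys, k))
  else as.integer(.count_repeated(keys, nbins))
}

#' Centered moving average with truncated edges
#'
#' At the ends of the series the window is truncated to the available values
#' (so the first value of a span-3 average is the mean of the first two).
#' \code{span = 1} returns the input unchanged.
#'
#' @param values Numeric vector.
#' @param span Odd window span.
#' @export
moving_average <- function(values, span = 1L) {
  span <- as.integer(span)
  if (span < 1L) stop("span must be >= 1")
  if (span %% 2L == 0L) stop("span must be odd")
  if (span == 1L) return(as.numeric(values))
  n <- length(values)
  h <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(values[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Repeated-k-mer profile over sliding windows
#'
#' Windows start at 1, 1+s, 1+2s, ... and only full windows (start + W - 1 <=
#' length) are used. Per-window counts come from
#' \code{\link{count_window_repeats}}; the profile carries their mean, sample
#' SD (n-1 denominator), and moving average.
#'
#' @param seq Gap-free DNA string (callers strip gaps/N first).
#' @param spec A \code{\link{window_spec}}.
#' @param tandem_only Passed to \code{\link{count_window_repeats}}.
#' @return A \code{repeat_profile}: list with \code{window_starts} (1-based),
#'   \code{window_counts}, \code{mean}, \code{sd}, \code{moving_avg},
#'   \code{k}, \code{window}, \code{shift}, and \code{single_window} flag
#'   (TRUE when only one window fits, in which case sd is reported as 0).
#' @export
sliding_repeat_profile <- function(seq, spec = window_spec(), tandem_only = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  W <- spec$window; s <- spec$shift; k <- spec$k
  if (n < W) {
    stop(sprintf(paste0("sequence (%d bp) shorter than the window (%d bp); ",
                        "use the whole-sequence fallback (gene_repeat_density)"), n, W))
  }
  ints <- .seq_ints(seq)
  keys <- .kmer_keys(seq, ints, k)
  starts <- seq.int(1L, n - W + 1L, by = s)
  nbins <- if (k <= 8L) as.integer(4^k) else NULL
  counter <- if (tandem_only) function(x) .count_tandem(x, k)
             else function(x) .count_repeated(x, nbins)
  counts <- vapply(starts, function(p) {
    as.integer(counter(keys[p:(p + W - k)]))
  }, integer(1))
  single <- length(counts) == 1L
  structure(list(
    window_starts = starts,
    window_counts = counts,
    mean = mean(counts),
    sd = if (single) 0 else sd(counts),
    moving_avg = moving_average(counts, spec$ma_span),
    k = k, window = W, shift = s,
    single_window = single
  ), class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat(sprintf("repeat_profile: k=%d, W=%d, shift=%d, %d windows; mean=%.2f sd=%.2f\n",
              x$k, x$window, x$shift, length(x$window_counts), x$mean, x$sd))
  invisible(x)
}

#' Expected repeated-k-mer count for iid windows
#'
#' Analytic overlap-independence approximation
#' \eqn{m (1 - (1 - q^k)^{m-1})} with \eqn{m = W - k + 1} and
#' \eqn{q = \sum_b p_b^2}, plus a Monte-Carlo estimate from \code{reps}
#' simulated iid windows. Used to study how base composition (GC content)
#' sets the equilibrium repeat density.
#'
#' @param base_freqs Probabilities for A, C, G, T (sum to 1).
#' @param W Window length.
#' @param k k-mer length.
#' @param reps Number of Monte-Carlo windows.
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return List with \code{analytic_approx}, \code{monte_carlo_mean},
#'   \code{mc_sd}.
#' @export
expected_repeat_count <- function(base_freqs, W = 200L, k = 5L, reps = 1000L,
                                  seed = NULL) {
  if (any(base_freqs < 0)) stop("base frequencies must be non-negative")
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base frequencies must sum to 1")
  if (reps < 1L) stop("reps must be >= 1")
  m <- W - k + 1L
  q <- sum(base_freqs^2)
  analytic <- m * (1 - (1 - q^k)^(m - 1))
  if (!is.null(seed)) set.seed(seed)
  nbins <- if (k <= 8L) as.integer(4^k) else NULL
  counts <- vapply(seq_len(reps), function(i) {
    ints <- sample.int(4L, W, replace = TRUE, prob = base_freqs)
    as.integer(.count_repeated(.kmer_codes(ints, k), nbins))
  }, integer(1))
  list(analytic_approx = analytic,
       monte_carlo_mean = mean(counts),
       mc_sd = sd(counts))
}

#' Per-gene scalar repeat density
#'
#' Mean of the (moving-averaged) window counts of
#' \code{\link{sliding_repeat_profile}}; with the default \code{ma_span = 1}
#' this is the plain mean across windows. Gaps and N are stripped before
#' windowing. Sequences shorter than one window fall back to a single
#' whole-sequence window with a warning.
#'
#' @param record A one-row gene record (needs \code{sequence} and
#'   \code{status}) or a bare DNA string.
#' @param spec A \code{\link{window_spec}}.
#' @param tandem_only Passed through.
#' @return Scalar density.
#' @export
gene_repeat_density <- function(record, spec = window_spec(), tandem_only = FALSE) {
  if (is.character(record)) {
    seq <- record; status <- "intact"; label <- "sequence"
  } else {
    seq <- record$sequence; status <- record$status
    label <- paste(record$gene_id, record$symbiont_id, sep = "|")
  }
  if (identical(status, "absent")) {
    stop("cannot compute repeat density for an absent record (", label, ")")
  }
  seq <- .strip_gaps(seq)
  if (nchar(seq) < spec$window) {
    warning(sprintf("%s: %d bp after gap stripping < window %d bp; using one whole-sequence window",
                    label, nchar(seq), spec$window))
    return(as.numeric(count_window_repeats(seq, spec$k, tandem_only)))
  }
  prof <- sliding_repeat_profile(seq, spec, tandem_only)
  mean(prof$moving_avg)
}

#' Repeat-density parameter table for a gene matrix
#'
#' @param gm A \code{gene_matrix}.
#' @param spec A \code{\link{window_spec}}.
#' @param tandem_only Passed through.
#' @return A \code{\link{parameter_table}} (absent cells NA).
#' @export
repeat_table <- function(gm, spec = window_spec(), tandem_only = FALSE) {
  values <- .cell_apply(gm, function(rec) {
    suppressWarnings(gene_repeat_density(rec, spec, tandem_only))
  })
  parameter_table(values, "repeat_density", status = .status_matrix(gm),
                  clade_map = .clade_map(gm))
}

# shared helpers for the per-cell table builders -------------------------------

.status_matrix <- function(gm) {
  m <- matrix(NA_character_, length(gm$gene_order), length(gm$symbiont_order),
              dimnames = list(gm$gene_order, gm$symbiont_order))
  r <- gm$records
  m[cbind(match(r$gene_id, gm$gene_order), match(r$symbiont_id, gm$symbiont_order))] <- r$status
  m
}

.clade_map <- function(gm) {
  r <- gm$records
  map <- r$clade[!duplicated(r$symbiont_id)]
  setNames(map, r$symbiont_id[!duplicated(r$symbiont_id)])[gm$symbiont_order]
}

.cell_apply <- function(gm, fn) {
  values <- matrix(NA_real_, length(gm$gene_order), length(gm$symbiont_order),
                   dimnames = list(gm$gene_order, gm$symbiont_order))
  r <- gm$records
  for (i in seq_len(nrow(r))) {
    if (r$status[i] == "absent") next
    values[r$gene_id[i], r$symbiont_id[i]] <- fn(r[i, , drop = FALSE])
  }
  values
}
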