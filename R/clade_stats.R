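#' Per-gene, per-clade means and SDs of a parameter table
#'
#' NA-aware; the outgroup column is excluded.
#'
#' @param table A \code{\link{parameter_table}} with a \code{clade_map}.
#' @return data.frame with columns gene, clade, mean, sd, n. All-NA cells give
#'   NA with a warning.
#' @export
clade_summary <- function(table) {
  if (is.null(table$clade_map)) stop("parameter table has no clade_map")
  clades <- setdiff(unique(table$clade_map), "outgroup")
  out <- expand.grid(gene = rownames(table$values), clade = clades,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_; out$n <- 0L
  for (i in seq_len(nrow(out))) {
    syms <- names(table$clade_map)[table$clade_map == out$clade[i]]
    v <- table$values[out$gene[i], syms]
    v <- v[is.finite(v)]
    out$n[i] <- length(v)
    if (length(v) == 0L) {
      warning(sprintf("no values for gene %s in clade %s", out$gene[i], out$clade[i]))
      next
    }
    out$mean[i] <- mean(v)
    out$sd[i] <- if (length(v) > 1L) sd(v) else 0
  }
  out
}

#' Two-sample (or one-way ANOVA) test
#'
#' Dispatch to the classical tests used for clade contrasts. Mann-Whitney uses
#' the exact null distribution when \code{n1 + n2 <= 12} and there are no
#' ties, and the tie-corrected normal approximation otherwise. Degenerate
#' zero-variance inputs for the t family are flagged: identical constant
#' groups give p = 1 (statistic 0); constant groups with different means give
#' p = 0.
#'
#' @param x Numeric sample (or, for \code{method = "anova"}, a list of >= 2
#'   group samples).
#' @param y Second sample (ignored for anova when \code{x} is a list).
#' @param method \code{"welch"}, \code{"student"}, \code{"mannwhitney"} or
#'   \code{"anova"}.
#' @return List with \code{statistic}, \code{p}, \code{method},
#'   \code{degenerate} flag.
#' @export
two_sample_test <- function(x, y = NULL,
                            method = c("welch", "student", "mannwhitney", "anova")) {
  method <- match.arg(method)
  if (method == "anova") {
    groups <- if (is.list(x)) x else list(x, y)
    if (length(groups) < 2L) stop("anova needs >= 2 groups")
    vals <- unlist(groups)
    grp <- factor(rep(seq_along(groups), lengths(groups)))
    if (var(vals) == 0) {
      return(list(statistic = 0, p = 1, method = method, degenerate = TRUE))
    }
    fit <- summary(aov(vals ~ grp))[[1]]
    return(list(statistic = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
                method = method, degenerate = FALSE))
  }
  if (method == "mannwhitney") {
    if (length(x) < 1L || length(y) < 1L) stop("need >= 1 observation per group")
    if (var(c(x, y)) == 0) {        # all observations tied: no evidence either way
      return(list(statistic = length(x) * length(y) / 2, p = 1,
                  method = method, degenerate = TRUE))
    }
    exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
    w <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
    return(list(statistic = unname(w$statistic), p = w$p.value,
                method = method, degenerate = FALSE))
  }
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 observations per group")
  if (sd(x) == 0 && sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (same) 0 else Inf, p = if (same) 1 else 0,
                method = method, degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = (method == "student"))
  list(statistic = unname(tt$statistic), p = tt$p.value, method = method,
       degenerate = FALSE)
}

#' Round-robin paired t-test matrix over a gene set
#'
#' For every unordered symbiont pair, a two-sided paired t-test across the
#' shared genes of \code{gene_set} (genes NA in either member dropped
#' pairwise). Degenerate difference vectors (zero variance) give p = 0 when
#' the mean difference is nonzero and p = 1 when it is zero, both flagged.
#' Pairs sharing fewer than 2 genes give NA with a warning.
#'
#' @param table A \code{\link{parameter_table}}.
#' @param gene_set Genes over which to pair (subset of the table's genes).
#' @param include_outgroup Keep the outgroup column (default FALSE).
#' @return List with \code{p} (symmetric symbiont matrix, diagonal NA),
#'   \code{n_genes}, \code{degenerate} (logical matrix), \code{averages}
#'   (per-symbiont across-gene means over \code{gene_set}).
#' @export
round_robin_paired <- function(table, gene_set = rownames(table$values),
                               include_outgroup = FALSE) {
  bad <- setdiff(gene_set, rownames(table$values))
  if (length(bad)) stop("gene_set not in table: ", paste(bad, collapse = ", "))
  syms <- colnames(table$values)
  if (!include_outgroup && !is.null(table$clade_map)) {
    syms <- syms[table$clade_map[syms] != "outgroup"]
  }
  V <- table$values[gene_set, syms, drop = FALSE]
  V[!is.finite(V)] <- NA
  m <- length(syms)
  p <- matrix(NA_real_, m, m, dimnames = list(syms, syms))
  ng <- matrix(0L, m, m, dimnames = list(syms, syms))
  deg <- matrix(FALSE, m, m, dimnames = list(syms, syms))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      shared <- !is.na(V[, i]) & !is.na(V[, j])
      ng[i, j] <- ng[j, i] <- sum(shared)
      if (sum(shared) < 2L) {
        warning(sprintf("pair %s/%s shares < 2 genes; p = NA", syms[i], syms[j]))
        next
      }
      d <- V[shared, i] - V[shared, j]
      if (sd(d) == 0) {
        deg[i, j] <- deg[j, i] <- TRUE
        p[i, j] <- p[j, i] <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
      } else {
        p[i, j] <- p[j, i] <- t.test(V[shared, i], V[shared, j], paired = TRUE)$p.value
      }
    }
  }
  averages <- colMeans(V, na.rm = TRUE)
  list(p = p, n_genes = ng, degenerate = deg, averages = averages,
       gene_set = gene_set)
}

#' Two-halves pair matrix (all genes / intact genes)
#'
#' Mirrors the published probability-matrix layout: the lower-left half holds
#' the paired-test p-values over the full gene set, the upper-right half those
#' over the intact gene set, with the two per-symbiont average rows.
#'
#' @param table A \code{\link{parameter_table}}.
#' @param lower_genes Gene set for the lower-left half (default all genes).
#' @param upper_genes Gene set for the upper-right half (e.g. intact genes).
#' @return A \code{pair_matrix}: list with \code{symbiont_order},
#'   \code{p_lower}, \code{p_upper}, \code{avg_lower}, \code{avg_upper},
#'   \code{combined} (one matrix with the two halves merged).
#' @export
pair_matrix <- function(table, lower_genes = rownames(table$values), upper_genes) {
  lower <- round_robin_paired(table, lower_genes)
  upper <- round_robin_paired(table, upper_genes)
  syms <- rownames(lower$p)
  comb <- lower$p
  comb[upper.tri(comb)] <- upper$p[upper.tri(upper$p)]
  structure(list(symbiont_order = syms, p_lower = lower$p, p_upper = upper$p,
                 avg_lower = lower$averages, avg_upper = upper$averages,
                 combined = comb, lower_genes = lower_genes,
                 upper_genes = upper_genes), class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("pair_matrix: lower = %d genes, upper = %d genes\n",
              length(x$lower_genes), length(x$upper_genes)))
  print(signif(x$combined, digits))
  invisible(x)
}

#' Degraded/intact clade-ratio analysis
#'
#' For each gene g computes the clade ratio r_g = mean(clade I) / mean(clade
#' II), then compares the ratios of the degraded gene group against those of
#' the intact gene group with a two-sided (exact, small-n) Mann-Whitney U
#' test. For genes in \code{intact_genes} only cells with status
#' \code{"intact"} enter the clade means (so a gene degraded in a few taxa is
#' averaged over its intact copies, as in the published analysis); degraded
#' genes use every available cell.
#'
#' @param table A \code{\link{parameter_table}} with status and clade_map.
#' @param degraded_genes,intact_genes Disjoint gene sets.
#' @return List with \code{ratios} (named per gene), \code{degraded_mean},
#'   \code{degraded_sd}, \code{intact_mean}, \code{intact_sd}, \code{U},
#'   \code{p}.
#' @export
ratio_analysis <- function(table, degraded_genes, intact_genes) {
  if (!length(degraded_genes) || !length(intact_genes)) {
    stop("both gene sets must be non-empty")
  }
  if (length(intersect(degraded_genes, intact_genes))) {
    stop("degraded and intact gene sets overlap")
  }
  genes <- c(degraded_genes, intact_genes)
  bad <- setdiff(genes, rownames(table$values))
  if (length(bad)) stop("gene(s) not in table: ", paste(bad, collapse = ", "))
  ratios <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    intact_only <- g %in% intact_genes && !is.null(table$status)
    cl_mean <- function(clade) {
      syms <- names(table$clade_map)[table$clade_map == clade]
      v <- table$values[g, syms]
      if (intact_only) v <- v[table$status[g, syms] == "intact"]
      v <- v[is.finite(v)]
      if (!length(v)) stop(sprintf("no values for gene %s in clade %s", g, clade))
      mean(v)
    }
    mII <- cl_mean("II")
    if (mII == 0) stop("zero clade-II mean for gene ", g)
    ratios[g] <- cl_mean("I") / mII
  }
  rd <- ratios[degraded_genes]; ri <- ratios[intact_genes]
  test <- two_sample_test(rd, ri, method = "mannwhitney")
  list(ratios = ratios,
       degraded_mean = mean(rd), degraded_sd = sd(rd),
       intact_mean = mean(ri), intact_sd = sd(ri),
       U = test$statistic, p = test$p)
}

#' Cross-parameter ordinary least-squares regression
#'
#' Pools every (gene, symbiont) cell present in both tables as one point
#' (genes and symbionts treated as independent observations, mirroring the
#' per-gene-per-symbiont dot definition of the published regressions, even
#' though points are phylogenetically non-independent).
#'
#' @param x_table,y_table Two \code{\link{parameter_table}}s with matching
#'   gene/symbiont layout.
#' @param include_outgroup Keep outgroup cells (default FALSE).
#' @return List with \code{r} (signed Pearson), \code{R2}, \code{p} (t
#'   distribution, n - 2 df), \code{slope}, \code{intercept}, \code{n}.
#' @export
parameter_regression <- function(x_table, y_table, include_outgroup = FALSE) {
  stopifnot(identical(dim(x_table$values), dim(y_table$values)))
  X <- x_table$values; Y <- y_table$values
  if (!include_outgroup && !is.null(x_table$clade_map)) {
    keep <- names(x_table$clade_map)[x_table$clade_map != "outgroup"]
    X <- X[, keep, drop = FALSE]; Y <- Y[, keep, drop = FALSE]
  }
  ok <- is.finite(X) & is.finite(Y)
  x <- X[ok]; y <- Y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired cells for regression")
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  r <- suppressWarnings(stats::cor(x, y))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, R2 = r^2, p = p,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), n = n)
}
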