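make_table <- function(values, clades, status = NULL) {
  parameter_table(values, "distance", status = status, clade_map = clades)
}

test_that("clade summaries are NA-aware means/SDs excluding the outgroup", {
  v <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), c("O", "a", "b", "c")))
  cl <- c(O = "outgroup", a = "I", b = "I", c = "II")
  s <- clade_summary(make_table(v, cl))
  expect_true(all(s$mean == 5))
  expect_true(all(s$sd[s$n > 1] == 0))
  expect_false("outgroup" %in% s$clade)
  # hand-computed 2x4 table
  v2 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4,
               dimnames = list(c("g1", "g2"), c("O", "a", "b", "c")))
  s2 <- clade_summary(make_table(v2, cl))
  expect_equal(s2$mean[s2$gene == "g1" & s2$clade == "I"], mean(c(3, 5)))
  expect_equal(s2$sd[s2$gene == "g1" & s2$clade == "I"], sd(c(3, 5)))
  expect_equal(s2$mean[s2$gene == "g2" & s2$clade == "II"], 8)
  v2[1, c("a", "b")] <- NA
  expect_warning(s3 <- clade_summary(make_table(v2, cl)), "no values")
  expect_true(is.na(s3$mean[s3$gene == "g1" & s3$clade == "I"]))
})

test_that("two-sample tests cover the degenerate and exact branches", {
  r <- two_sample_test(c(2, 2, 2), c(2, 2, 2), "welch")
  expect_equal(r$p, 1)
  expect_equal(r$statistic, 0)
  expect_true(r$degenerate)
  r2 <- two_sample_test(c(1, 1, 1), c(5, 5, 5), "student")
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)
  m <- two_sample_test(c(1, 2, 3), c(10, 11, 12), "mannwhitney")
  expect_equal(m$p, 0.1)
  a <- two_sample_test(list(c(3, 3), c(3, 3), c(3, 3)), method = "anova")
  expect_equal(a$statistic, 0)
  expect_equal(a$p, 1)
  a2 <- two_sample_test(list(rnorm(5), rnorm(5) + 10, rnorm(5)), method = "anova")
  expect_lt(a2$p, 1)
})

test_that("welch/student match stats::t.test and MWU matches wilcox.test", {
  set.seed(61)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  expect_equal(two_sample_test(x, y, "welch")$p, t.test(x, y)$p.value)
  expect_equal(two_sample_test(x, y, "student")$p,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(two_sample_test(x, y, "mannwhitney")$p,
               wilcox.test(x, y, exact = FALSE)$p.value)
})

test_that("exact Mann-Whitney equals exhaustive label enumeration (n1,n2 <= 5)", {
  set.seed(67)
  for (n1 in 1:5) {
    for (n2 in max(n1, 2):5) {
      x <- rnorm(n1); y <- rnorm(n2)
      expect_equal(two_sample_test(x, y, "mannwhitney")$p, oracle_mwu_p(x, y),
                   tolerance = 1e-12,
                   label = sprintf("MWU n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("round-robin paired matrix is symmetric with flagged degenerate pairs", {
  v <- matrix(c(3, 5, 7, 4, 6, 8, 3, 5, 7), 3, 3,
              dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  tab <- make_table(v, c(a = "I", b = "II", c = "II"))
  rr <- round_robin_paired(tab)
  # constant shift of 1 between a and b: zero-variance differences, nonzero mean
  expect_equal(rr$p["a", "b"], 0)
  expect_true(rr$degenerate["a", "b"])
  # identical columns a and c: zero-variance, zero-mean differences
  expect_equal(rr$p["a", "c"], 1)
  expect_true(is.na(diag(rr$p))[1])
  expect_equal(rr$p, t(rr$p))
  expect_equal(unname(rr$averages["a"]), 5)
  # pairwise NA dropping against a plain t.test oracle
  v2 <- v; v2[2, "b"] <- NA
  rr2 <- round_robin_paired(make_table(v2, c(a = "I", b = "II", c = "II")))
  expect_equal(rr2$n_genes["a", "b"], 2)
  v3 <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  rr3 <- round_robin_paired(make_table(v3, c(a = "I", b = "II", c = "II")))
  expect_equal(rr3$p["a", "b"], t.test(v3[, "a"], v3[, "b"], paired = TRUE)$p.value)
})

test_that("pair matrices carry distinct lower/upper gene sets", {
  set.seed(71)
  v <- matrix(rnorm(40, 10), 4, 10,
              dimnames = list(paste0("g", 1:4),
                              c(paste0("i", 1:5), paste0("ii", 1:5))))
  cl <- setNames(rep(c("I", "II"), each = 5), colnames(v))
  tab <- make_table(v, cl)
  pm <- pair_matrix(tab, lower_genes = rownames(v), upper_genes = c("g1", "g2"))
  expect_equal(pm$combined[lower.tri(pm$combined)],
               pm$p_lower[lower.tri(pm$p_lower)])
  expect_equal(pm$combined[upper.tri(pm$combined)],
               pm$p_upper[upper.tri(pm$p_upper)])
  expect_true(all(pm$p_lower[lower.tri(pm$p_lower)] >= 0 &
                    pm$p_lower[lower.tri(pm$p_lower)] <= 1))
})

test_that("clade separation drives between-clade p below within-clade p", {
  set.seed(73)
  ng <- 10
  base <- rnorm(ng, 10, 2)
  v <- cbind(
    sapply(1:4, function(i) base * 1.5 + rnorm(ng, 0, 0.3)),   # clade I
    sapply(1:4, function(i) base + rnorm(ng, 0, 0.3))          # clade II
  )
  dimnames(v) <- list(paste0("g", 1:ng), c(paste0("i", 1:4), paste0("ii", 1:4)))
  cl <- setNames(rep(c("I", "II"), each = 4), colnames(v))
  rr <- round_robin_paired(make_table(v, cl))
  between <- rr$p[1:4, 5:8]
  within <- c(rr$p[1:4, 1:4][lower.tri(matrix(0, 4, 4))],
              rr$p[5:8, 5:8][lower.tri(matrix(0, 4, 4))])
  expect_lt(max(between), median(within))
})

test_that("ratio analysis reproduces group means and the exact MWU p", {
  v <- rbind(
    d1 = c(1.5, 1.5, 1.0, 1.0), d2 = c(1.4, 1.4, 1.0, 1.0),
    d3 = c(1.6, 1.6, 1.0, 1.0), i1 = c(1.0, 1.0, 1.0, 1.0),
    i2 = c(1.1, 1.1, 1.0, 1.0), i3 = c(0.9, 0.9, 1.0, 1.0))
  cl <- c(a = "I", b = "I", c = "II", d = "II")
  colnames(v) <- names(cl)
  tab <- make_table(v, cl)
  r <- ratio_analysis(tab, degraded_genes = c("d1", "d2", "d3"),
                      intact_genes = c("i1", "i2", "i3"))
  expect_equal(unname(r$ratios[c("d1", "d2", "d3")]), c(1.5, 1.4, 1.6))
  expect_equal(r$degraded_mean, 1.5)
  expect_equal(r$intact_mean, 1.0)
  expect_equal(r$p, 0.1)  # fully separated 3 vs 3, exact two-sided
  expect_error(ratio_analysis(tab, c("d1"), c("d1", "i1")), "overlap")
  # identical clades: all ratios 1, test cannot be significant
  v1 <- matrix(2, 4, 4, dimnames = dimnames(v[1:4, ]))
  r1 <- ratio_analysis(make_table(v1, cl), c("d1", "d2"), c("d3", "i1"))
  expect_true(all(r1$ratios == 1))
  expect_gt(r1$p, 0.05)
})

test_that("ratio analysis restricts intact-set genes to intact cells", {
  v <- rbind(g1 = c(2, 2, 1, 1), g2 = c(4, 2, 1, 1))
  cl <- c(a = "I", b = "I", c = "II", d = "II")
  colnames(v) <- names(cl)
  status <- matrix("intact", 2, 4, dimnames = dimnames(v))
  status["g2", "a"] <- "degraded"   # inflated degraded copy must be excluded
  tab <- make_table(v, cl, status = status)
  r <- ratio_analysis(tab, degraded_genes = "g1", intact_genes = "g2")
  expect_equal(unname(r$ratios["g2"]), 2)  # mean(2)/mean(1,1), not mean(4,2)
})

test_that("regression matches closed-form Pearson and handles exact fits", {
  x <- matrix(1:5, 1, 5, dimnames = list("g", paste0("s", 1:5)))
  y <- 2 * x + 1
  cl <- setNames(rep("I", 5), colnames(x))
  r <- parameter_regression(make_table(x, cl), make_table(y, cl))
  expect_equal(r$r, 1)
  expect_equal(r$R2, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  # orthogonal +-1 pattern has zero correlation
  x2 <- matrix(c(-1, 1, -1, 1), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  y2 <- matrix(c(-1, -1, 1, 1), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  cl2 <- setNames(rep("I", 4), paste0("s", 1:4))
  r2 <- parameter_regression(make_table(x2, cl2), make_table(y2, cl2))
  expect_equal(r2$r, 0)
  # seeded noisy line vs the covariance formula
  set.seed(79)
  xv <- matrix(rnorm(120), 10, 12,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  yv <- 3 * xv + matrix(rnorm(120, 0, 0.5), 10, 12)
  cl3 <- setNames(rep(c("I", "II"), 6), paste0("s", 1:12))
  r3 <- parameter_regression(make_table(xv, cl3), make_table(yv, cl3))
  expect_equal(r3$r, cov(c(xv), c(yv)) / (sd(c(xv)) * sd(c(yv))),
               tolerance = 1e-12)
  expect_equal(r3$slope, cov(c(xv), c(yv)) / var(c(xv)), tolerance = 1e-12)
  expect_equal(r3$n, 120)
  expect_error(parameter_regression(make_table(y2 * 0, cl2), make_table(y2, cl2)),
               "zero variance")
})
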