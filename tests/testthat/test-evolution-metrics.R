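test_that("pairwise masking drops gap/N columns pairwise", {
  m <- pairwise_mask(pairwise_alignment("AC-G", "ACTG"))
  expect_equal(m$comparable_sites, 3)
  expect_equal(m$seq_a, "ACG")
  m2 <- pairwise_mask(pairwise_alignment("A-C-G", "A-C-G"))
  expect_equal(m2$comparable_sites, 3)
  set.seed(13)
  a <- strsplit(random_dna(200), "")[[1]]
  b <- strsplit(random_dna(200), "")[[1]]
  a[sample(200, 30)] <- "-"; b[sample(200, 25)] <- "N"
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  m3 <- pairwise_mask(pairwise_alignment(paste(a, collapse = ""),
                                         paste(b, collapse = "")))
  expect_equal(m3$seq_a, paste(a[keep], collapse = ""))
  expect_equal(m3$seq_b, paste(b[keep], collapse = ""))
  expect_error(pairwise_mask(pairwise_alignment("---", "AAA")), "no comparable")
  expect_error(pairwise_alignment("ACGT", "ACG"), "differ in length")
})

test_that("distances vanish for identical sequences and match closed forms", {
  s <- random_dna(300)
  for (m in c("p", "jc69", "k80", "hky")) {
    expect_equal(nucleotide_distance(pairwise_alignment(s, s), m)$t, 0)
  }
  # constructed p = 0.25 pair: 75 transversion-free mismatches in 300 sites
  a <- paste(rep("A", 300), collapse = "")
  b <- paste(c(rep("G", 75), rep("A", 225)), collapse = "")
  d <- nucleotide_distance(pairwise_alignment(a, b), "jc69")
  expect_equal(d$p_raw, 0.25)
  expect_equal(d$t, -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-12)
})

test_that("JC69 and K80 agree with ape::dist.dna (independent oracle)", {
  set.seed(19)
  for (i in 1:8) {
    a <- random_dna(600, gc = runif(1, 0.3, 0.5))
    bb <- strsplit(a, "")[[1]]
    nmut <- sample(20:150, 1)
    idx <- sample(600, nmut)
    bb[idx] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    b <- paste(bb, collapse = "")
    bin <- ape::as.DNAbin(rbind(a = strsplit(tolower(a), "")[[1]],
                                b = strsplit(tolower(b), "")[[1]]))
    aln <- pairwise_alignment(a, b)
    expect_equal(nucleotide_distance(aln, "jc69")$t,
                 as.numeric(ape::dist.dna(bin, model = "JC69")), tolerance = 1e-12)
    expect_equal(nucleotide_distance(aln, "k80")$t,
                 as.numeric(ape::dist.dna(bin, model = "K80")), tolerance = 1e-12)
    expect_equal(nucleotide_distance(aln, "p")$t,
                 as.numeric(ape::dist.dna(bin, model = "raw")), tolerance = 1e-12)
  }
})

test_that("limiting behaviour: JC69 ~ p at small p; K80 -> JC69 as kappa -> 1", {
  a <- paste(rep("A", 20000), collapse = "")
  b <- paste(c("G", "C", rep("A", 19998)), collapse = "")  # p = 1e-4
  d <- nucleotide_distance(pairwise_alignment(a, b), "jc69")
  expect_lt(abs(d$t - d$p_raw), 1e-6)
  # balanced transition/transversion mix behaves like JC when P = Q/2 pattern
  set.seed(29)
  s <- random_dna(3000)
  ev <- evolve_sequence(s, 0.2, kappa = 1, gc_equilibrium = 0.5, omega = 1)
  aln <- pairwise_alignment(s, ev)
  expect_equal(nucleotide_distance(aln, "k80")$t,
               nucleotide_distance(aln, "jc69")$t, tolerance = 0.01)
})

test_that("saturated pairs are flagged with infinite distance", {
  a <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  b <- paste(rep(c("C", "G", "T", "A"), 50), collapse = "")  # p = 1
  d <- nucleotide_distance(pairwise_alignment(a, b), "jc69")
  expect_true(d$saturated)
  expect_equal(d$t, Inf)
})

test_that("HKY-ML recovers the generating distance and kappa", {
  set.seed(37)
  s <- random_dna(50000, gc = 0.4)
  ev <- evolve_sequence(s, 0.4, kappa = 4, gc_equilibrium = 0.4, omega = 1)
  d <- nucleotide_distance(pairwise_alignment(s, ev), "hky")
  expect_lt(abs(d$t - 0.4), 3 * d$se_t)
  expect_lt(abs(d$kappa_hat - 4), 1)
  # on kappa = 1 data the HKY fit collapses to JC69
  ev1 <- evolve_sequence(s, 0.3, kappa = 1, gc_equilibrium = 0.5, omega = 1)
  aln <- pairwise_alignment(s, ev1)
  dh <- nucleotide_distance(aln, "hky")
  dj <- nucleotide_distance(aln, "jc69")
  expect_lt(abs(dh$t - dj$t), 3 * dh$se_t)
  expect_lt(abs(dh$kappa_hat - 1), 0.5)
})

test_that("NG86 handles forced cases from the genetic code", {
  s <- paste(rep("ATGGCTAGC", 10), collapse = "")
  r0 <- ng86_dn_ds(pairwise_alignment(s, s))
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))
  expect_true(r0$ds_zero)
  # TTT -> TTC is Phe/Phe: purely synonymous
  r1 <- ng86_dn_ds(pairwise_alignment("TTT", "TTC"))
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  expect_equal(r1$ratio, 0)
  expect_equal(r1$N_sites + r1$S_sites, 3)
})

test_that("NG86 equals the independent pathway-enumeration oracle", {
  set.seed(43)
  for (i in 1:25) {
    root <- simulate_root_sequence(20, 0.45)
    ev <- evolve_sequence(root, runif(1, 0.05, 0.5), kappa = 2,
                          gc_equilibrium = 0.45, omega = runif(1))
    mine <- ng86_dn_ds(pairwise_alignment(root, ev))
    orc <- oracle_ng86(root, ev)
    expect_equal(mine$S_sites, orc$S_sites, tolerance = 1e-10)
    expect_equal(mine$pS, orc$pS, tolerance = 1e-10)
    expect_equal(mine$pN, orc$pN, tolerance = 1e-10)
    expect_equal(mine$dN, orc$dN, tolerance = 1e-10)
    expect_equal(mine$dS, orc$dS, tolerance = 1e-10)
  }
})

test_that("NG86 is symmetric in argument order", {
  set.seed(47)
  a <- simulate_root_sequence(50, 0.4)
  b <- evolve_sequence(a, 0.3, kappa = 2, gc_equilibrium = 0.4, omega = 0.5)
  r1 <- ng86_dn_ds(pairwise_alignment(a, b))
  r2 <- ng86_dn_ds(pairwise_alignment(b, a))
  expect_equal(r1$dN, r2$dN)
  expect_equal(r1$dS, r2$dS)
  expect_equal(r1$S_sites, r2$S_sites)
})

test_that("distance_table composes per-cell distances against the outgroup", {
  sim <- simulate_dataset(simulation_config(seed = 2))
  gm <- sim$matrix
  tab <- distance_table(gm, sim$alignments, "k80")
  expect_equal(unname(tab$values[, gm$outgroup_id]),
               rep(0, length(gm$gene_order)))
  g <- gm$gene_order[1]
  sym <- setdiff(gm$symbiont_order, gm$outgroup_id)[1]
  aln <- sim$alignments[[g]]
  direct <- nucleotide_distance(
    pairwise_alignment(aln[[sym]], aln[[gm$outgroup_id]]), "k80")$t
  expect_equal(tab$values[g, sym], direct)
  # clade I simulated faster: its per-gene distances should mostly exceed clade II
  cs <- clade_summary(tab)
  wide <- merge(cs[cs$clade == "I", c("gene", "mean")],
                cs[cs$clade == "II", c("gene", "mean")], by = "gene")
  expect_gte(sum(wide$mean.x > wide$mean.y), 9)
  broken <- sim$alignments
  names(broken[[g]])[names(broken[[g]]) == gm$outgroup_id] <- "elsewhere"
  expect_error(distance_table(gm, broken, "k80"), g)
})

test_that("dnds_table covers intact cells only", {
  sim <- simulate_dataset(simulation_config(seed = 2))
  tab <- dnds_table(sim$matrix, sim$alignments)
  st <- tab$status
  expect_true(all(is.na(tab$values[st == "degraded"])))
  intact_vals <- tab$values[, setdiff(colnames(tab$values), sim$matrix$outgroup_id)]
  expect_true(any(is.finite(intact_vals)))
  expect_true(all(intact_vals[is.finite(intact_vals)] >= 0))
})
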