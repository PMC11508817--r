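test_that("allele frequencies count non-missing haplotypes only", {
  m <- hap_mat(c("0", "1", "1", "1", ".", ".", "0", "0", "1", "0", "1", "1"))
  panel <- half_panel(m)
  fr <- allele_frequencies(m, panel)
  expect_equal(fr$freq_FOC, 0.75)       # [0,1,1,1]
  expect_equal(fr$ntot_C1, 2L)          # two missing haplotypes dropped
  expect_equal(fr$freq_C1, 0)
  expect_equal(fr$freq_C2, 0.75)
})

test_that("a population with all haplotypes missing gets the NA sentinel", {
  m <- hap_mat(c("0", "1", "1", "1", ".", ".", ".", ".", "1", "0", "1", "1"))
  panel <- half_panel(m)
  fr <- allele_frequencies(m, panel)
  expect_true(is.na(fr$freq_C1))
  expect_equal(fr$freq_FOC, 0.75)
  expect_equal(fr$freq_C2, 0.75)
})

test_that("pooled MAF is the minor pooled frequency", {
  # 0.9 in 50 haplotypes and 0.8 in 50 -> pooled alt 0.85 -> MAF 0.15
  a <- cbind(c(rep(1L, 45), rep(0L, 5), rep(1L, 40), rep(0L, 10),
               rep(1L, 45), rep(0L, 5)))
  m <- haplotype_matrix(a[1:150, , drop = FALSE], positions = 100L,
                        chrom = "chr1")
  panel <- half_panel(m)
  fr <- allele_frequencies(m, panel)
  expect_equal(fr$freq_FOC, 0.9)
  expect_equal(fr$freq_C1, 0.8)
  expect_equal(fr$maf, 1 - (45 + 40 + 45) / 150)
})

test_that("Hudson FST matches direct evaluation", {
  expect_equal(hudson_fst(1.0, 100, 0.0, 100), 1.0)
  # symmetric intermediate case evaluates to a small negative value
  expect_equal(hudson_fst(0.5, 100, 0.5, 100),
               (-2 * 0.25 / 99) / 0.5, tolerance = 1e-12)
  # PHACTR1-style frequencies, direct arithmetic oracle
  num <- (0.93 - 0.06)^2 - 0.93 * 0.07 / 115 - 0.06 * 0.94 / 69
  den <- 0.93 * 0.94 + 0.06 * 0.07
  expect_equal(hudson_fst(0.93, 116, 0.06, 70), num / den,
               tolerance = 1e-12)
  expect_equal(round(hudson_fst(0.93, 116, 0.06, 70), 4), 0.8601)
  # symmetry in the two populations
  expect_equal(hudson_fst(0.93, 116, 0.06, 70),
               hudson_fst(0.06, 70, 0.93, 116))
  # both fixed for the same allele: undefined
  expect_true(is.na(hudson_fst(0, 50, 0, 60)))
  expect_error(hudson_fst(1.2, 50, 0.5, 50), "frequencies")
})

test_that("PBS is the printed linear combination with negative clamping", {
  expect_equal(pbs(0.2, 0.2, 0.2), 0.1)
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.5, 0.4, -0.3), (0.5 + 0.4) / 2)    # clamped
  expect_equal(pbs(0.5, 0.4, -0.3, clamp_negative = FALSE), 0.6)
  expect_true(is.na(pbs(NA, 0.2, 0.1)))
  # symmetric in the two controls
  expect_equal(pbs(0.3, 0.7, 0.2), pbs(0.7, 0.3, 0.2))
})

test_that("delta DAF contrasts focal against the control mean", {
  m <- random_hap_mat(12, 5)
  panel <- half_panel(m)
  fr <- allele_frequencies(m, panel)
  fr$freq_FOC <- c(0.9, 0.5, 0.0, 0.2, 0.8)
  fr$freq_C1 <- c(0.1, 0.5, 1.0, 0.1, 0.3)
  fr$freq_C2 <- c(0.2, 0.5, 1.0, 0.3, 0.5)
  expect_equal(delta_daf(fr, panel), c(0.75, 0, -1, 0, 0.4))
  expect_equal(delta_daf(fr, panel, aggregate = "max"),
               c(0.7, 0, -1, -0.1, 0.3))
})

test_that("heterozygosity ratio is het over non-reference hom", {
  g <- c(rep("01", 10), rep("11", 5), rep("00", 3))  # genotypes of 1 sample
  a <- rbind(as.integer(substr(g, 1, 1)), as.integer(substr(g, 2, 2)))
  m <- haplotype_matrix(a, positions = seq_along(g) * 10L, chrom = "chr1")
  expect_equal(unname(heterozygosity_ratio(m)), 10 / 5)
  m0 <- hap_mat(c("0000", "0000"))
  expect_equal(unname(heterozygosity_ratio(m0)), 0)
  m_inf <- hap_mat(c("0101", "1010"))  # all het, no hom-alt
  expect_equal(unname(heterozygosity_ratio(m_inf)), Inf)
})

test_that("inbreeding coefficient is 0 at expectation and 1 when all hom", {
  # a fully homozygous sample has F = 1 by construction
  m <- hap_mat(c("0011", "0011", "0101", "1010", "0110", "1001"))
  f <- inbreeding_coefficient(m)
  expect_equal(unname(f[1]), 1)
  # random-mating simulated genotypes: F within +/- 0.05 of 0
  set.seed(31)
  n <- 60; n_site <- 2000
  p <- runif(n_site, 0.1, 0.9)
  a <- matrix(rbinom(2 * n * n_site, 1, rep(p, each = 2 * n)), nrow = 2 * n)
  mr <- haplotype_matrix(a, positions = seq_len(n_site) * 10L, chrom = "chr1")
  fr <- inbreeding_coefficient(mr)
  # the estimator's null sampling SD at 2000 sites is ~0.026, so a single
  # sample sits within +/- 0.05 of zero; the cohort mean is tighter still
  expect_lt(abs(fr[1]), 0.05)
  expect_lt(abs(mean(fr)), 0.01)
  expect_lt(sd(fr), 0.05)
})

test_that("Tajima's D agrees with the brute-force oracle", {
  # n = 4 haplotypes, 2 segregating sites, pi by enumerating all 6 pairs
  m <- hap_mat(c("0011", "0011", "0000", "0000"))
  expect_equal(tajimas_d(m), tajima_oracle(m$alleles), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(rbinom(8 * 15, 1, runif(1, 0.2, 0.8)), nrow = 8)
    keep <- colSums(a) > 0 & colSums(a) < 8
    if (sum(keep) == 0) next
    mm <- haplotype_matrix(a[, keep, drop = FALSE],
                           positions = which(keep) * 100L, chrom = "chr1")
    expect_equal(tajimas_d(mm), tajima_oracle(mm$alleles), tolerance = 1e-10)
  }
  # no segregating sites: undefined
  expect_true(is.na(tajimas_d(hap_mat(c("00", "00", "00", "00")))))
})

test_that("Tajima constants: a1 at n = 10 equals the closed form", {
  expect_equal(sweepscan:::tajima_constants(10)$a1, sum(1 / (1:9)))
  expect_equal(round(sweepscan:::tajima_constants(10)$a1, 4), 2.829)
})

test_that("r2 matches direct haplotype counting and the correlation oracle", {
  expect_equal(ld_r2(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # 8 haplotypes {00 x3, 01 x1, 10 x1, 11 x3}: r2 = 0.125^2 / 0.0625
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expect_equal(ld_r2(x, y), 0.25)
  # correlation oracle on random data with missingness
  set.seed(8)
  for (i in 1:30) {
    x <- rbinom(40, 1, 0.5); y <- rbinom(40, 1, 0.5)
    x[sample(40, 4)] <- NA; y[sample(40, 4)] <- NA
    r2 <- ld_r2(x, y)
    if (is.na(r2)) next  # monomorphic among complete haplotypes
    oracle <- cor(x, y, use = "pairwise.complete.obs")^2
    expect_equal(r2, oracle, tolerance = 1e-12)
  }
  expect_true(is.na(ld_r2(c(0, 0, 0, 0), c(0, 1, 0, 1))))
})

test_that("LD decay is 1 for duplicated columns and empty for one site", {
  one <- haplotype_matrix(matrix(rep(c(0L, 1L), 6), ncol = 1),
                          positions = 1000L, chrom = "chr1")
  panel1 <- half_panel(one)
  d1 <- ld_decay(one, panel1, "FOC", max_dist = 1e4, bin_width = 1e3)
  expect_true(all(d1$n_pairs == 0))
  # same column copied at 1..10 kb: every defined bin has mean r2 = 1
  col <- rep(c(0L, 1L), 6)
  a <- matrix(col, nrow = 12, ncol = 11)
  m <- haplotype_matrix(a, positions = c(0:10) * 1000L + 100L, chrom = "chr1")
  panel <- half_panel(m)
  d <- ld_decay(m, panel, "FOC", max_dist = 1e4, bin_width = 1e3)
  expect_true(all(d$mean_r2[d$n_pairs > 0] == 1))
  expect_gt(sum(d$n_pairs), 0)
})

test_that("mean r2 decays with distance on simulated data", {
  sim <- simulate_three_pop_sweep(
    sim_config(n_anc = 100, n_pop = 100, L = 2e5, t_split1 = 20,
               t_split2 = 10, sweep_start = 10, n_sample = 15,
               burn_in = 1000, seed = 71))
  d <- ld_decay(sim$matrix, sim$panel, "TBP", max_dist = 1e5,
                bin_width = 1e3)
  # smooth over 10 kb blocks, then require a monotone downward trend
  block <- ceiling(seq_len(nrow(d)) / 10)
  w <- tapply(d$mean_r2 * d$n_pairs, block, sum, na.rm = TRUE) /
    tapply(d$n_pairs, block, sum)
  w <- w[!is.na(w)]
  expect_gt(w[1], w[length(w)])
  expect_lt(mean(diff(w) > 0), 0.5)  # mostly decreasing
})
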