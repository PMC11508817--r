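mk_tbl <- function(pbs, ihs, xp, dd) {
  data.frame(pbs = pbs, ihs = ihs, xpehh_mean = xp, delta_daf = dd)
}

test_that("CMS follows the rank definition at the median and the top", {
  # a site at the exact median of every component, N odd
  N <- 11
  v <- seq_len(N)
  tbl <- mk_tbl(v, -v, v, v)     # ihs enters negated, keep orders aligned
  out <- cms_scores(tbl)
  med <- which(v == 6)
  expect_equal(out$u_pbs[med], 0.5)
  expect_equal(out$cms[med], -log10(0.5), tolerance = 1e-12)
  # rank-1 in all four components at N = 1000
  set.seed(3)
  N <- 1000
  tbl <- mk_tbl(rnorm(N), rnorm(N), rnorm(N), rnorm(N))
  best <- which.max(tbl$pbs)
  tbl$pbs[best] <- 99; tbl$ihs[best] <- -99
  tbl$xpehh_mean[best] <- 99; tbl$delta_daf[best] <- 99
  out <- cms_scores(tbl)
  expect_equal(out$cms[best], -log10(0.5 / 1000), tolerance = 1e-12)
})

test_that("CMS is invariant under permutation and monotone transforms", {
  set.seed(7)
  N <- 300
  tbl <- mk_tbl(rexp(N), rnorm(N), rnorm(N), runif(N, -1, 1))
  out <- cms_scores(tbl)
  perm <- sample(N)
  out_p <- cms_scores(tbl[perm, ])
  expect_equal(out_p$cms, out$cms[perm], tolerance = 1e-12)
  tbl3 <- tbl; tbl3$pbs <- tbl3$pbs^3   # strictly monotone on positives
  expect_equal(cms_scores(tbl3)$cms, out$cms, tolerance = 1e-12)
})

test_that("sites missing any component are excluded but others are ranked", {
  tbl <- mk_tbl(c(1, 2, NA, 4), c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  out <- cms_scores(tbl)
  expect_true(out$cms_excluded[3])
  expect_true(is.na(out$cms[3]))
  expect_equal(sum(!out$cms_excluded), 3)
  expect_error(cms_scores(mk_tbl(NA, 1, 1, 1)), ">= 2 sites")
})

test_that("the top-fraction threshold keeps ceiling(f N) sites plus ties", {
  cms <- c(sort(runif(995), decreasing = TRUE), rep(0.99, 0))
  cms <- runif(1000)
  cand <- threshold_top_fraction(cms, 0.005)
  expect_equal(sum(cand), 5L)
  expect_equal(attr(cand, "n_ties_extra"), 0L)
  # a 3-way tie at the boundary rank is retained in full
  cms2 <- c(rep(1, 4), rep(0.9, 3), runif(993, max = 0.5))
  cand2 <- threshold_top_fraction(cms2, 0.005)
  expect_equal(sum(cand2), 7L)
  expect_equal(attr(cand2, "n_ties_extra"), 2L)
  # fraction near 1 keeps everything
  expect_equal(sum(threshold_top_fraction(cms, 0.999999)), 1000L)
  expect_error(threshold_top_fraction(cms, 0), "fraction")
})

test_that("the enrichment filter requires strict focal dominance", {
  fr <- data.frame(freq_F = c(0.8, 0.2, 0.5, 0.9),
                   freq_A = c(0.3, 0.5, 0.5, 0.1),
                   freq_B = c(0.4, 0.1, 0.2, 0.9))
  panel <- list(focal = "F", controls = c("A", "B"))
  keep <- enrichment_filter(rep(TRUE, 4), fr, panel)
  expect_equal(keep, c(TRUE, FALSE, FALSE, FALSE))
  # non-candidates stay out regardless
  expect_equal(enrichment_filter(c(FALSE, TRUE, TRUE, TRUE), fr, panel),
               c(FALSE, FALSE, FALSE, FALSE))
})

test_that("greedy clumping joins linked candidates and seeds by CMS", {
  # focal matrix with three candidate sites: B duplicates A (r2 = 1),
  # C is independent of A (balanced orthogonal column, r2 = 0)
  colA <- c(0, 0, 0, 0, 1, 1, 1, 1)
  colC <- c(0, 0, 1, 1, 0, 0, 1, 1)
  a <- cbind(colA, colA, colC)
  m <- haplotype_matrix(a, positions = c(100000L, 300000L, 900000L),
                        chrom = "chr1")
  cand <- data.frame(chrom = "chr1", pos = c(100000L, 300000L, 900000L),
                     site_id = c("A", "B", "C"), cms = c(10, 8, 7),
                     stringsAsFactors = FALSE)
  cl <- cluster_regions(cand, m, window = 5e5, r2_max = 0.2)
  expect_equal(nrow(cl$regions), 2L)
  r1 <- cl$regions[cl$regions$peak_id == "A", ]
  expect_equal(r1$n_snvs, 2L)
  expect_equal(r1$start, 100000L)
  expect_equal(r1$end, 300000L)
  expect_equal(cl$regions$peak_id[cl$regions$n_snvs == 1], "C")
  # membership is a partition
  expect_equal(sum(cl$regions$n_snvs), nrow(cand))
  expect_equal(sort(unique(cl$members$region_id)), c(1L, 2L))
})

test_that("the window rule dominates even under perfect LD", {
  colA <- c(0, 0, 0, 0, 1, 1, 1, 1)
  a <- cbind(colA, colA)
  m <- haplotype_matrix(a, positions = c(100000L, 700000L), chrom = "chr1")
  cand <- data.frame(chrom = "chr1", pos = c(100000L, 700000L),
                     site_id = c("A", "B"), cms = c(5, 4),
                     stringsAsFactors = FALSE)
  cl <- cluster_regions(cand, m, window = 5e5, r2_max = 0.2)
  expect_equal(nrow(cl$regions), 2L)
})

test_that("a single candidate yields a single one-member region", {
  m <- haplotype_matrix(cbind(c(0, 1, 0, 1)), positions = 1000L,
                        chrom = "chr1")
  cand <- data.frame(chrom = "chr1", pos = 1000L, site_id = "X", cms = 1,
                     stringsAsFactors = FALSE)
  cl <- cluster_regions(cand, m)
  expect_equal(cl$regions$n_snvs, 1L)
  expect_equal(cl$regions$peak_id, "X")
})

test_that("peak genes are assigned within the 5 kb flank, ties by midpoint", {
  # single gene: the 5 kb flank decides assignment
  lone <- gene_model("chr1", 1000L, 2000L, "ONLY")
  reg1 <- data.frame(region_id = 1:2, chrom = "chr1",
                     peak_pos = c(2500L, 8000L), stringsAsFactors = FALSE)
  out1 <- assign_peak_gene(reg1, lone, flank = 5000)
  expect_equal(out1$gene[1], "ONLY")  # within 5 kb downstream of [1000,2000]
  expect_true(is.na(out1$gene[2]))    # > 5 kb from the gene body
  # overlapping genes: nearest body midpoint wins, deterministically
  genes <- gene_model(chrom = rep("chr1", 3),
                      start = c(1000L, 1500L, 20000L),
                      end = c(2000L, 2600L, 30000L),
                      name = c("NEAR", "FAR", "ELSEWHERE"))
  reg <- data.frame(region_id = 1:2, chrom = "chr1",
                    peak_pos = c(1700L, 2500L), stringsAsFactors = FALSE)
  out <- assign_peak_gene(reg, genes, flank = 5000)
  # peak 1700: NEAR midpoint 1500 (d = 200) beats FAR midpoint 2050 (d = 350)
  expect_equal(out$gene[1], "NEAR")
  # peak 2500: FAR midpoint 2050 (d = 450) beats NEAR (d = 1000)
  expect_equal(out$gene[2], "FAR")
})

test_that("region peaks within the window are mutually independent", {
  set.seed(53)
  sim <- simulate_three_pop_sweep(
    sim_config(n_anc = 100, n_pop = 100, L = 2e5, t_split1 = 20,
               t_split2 = 10, sweep_start = 10, n_sample = 10,
               burn_in = 1000, seed = 53))
  scan <- scan_statistics(sim$matrix, sim$panel)
  reg <- call_regions(scan, sim$matrix, sim$panel, fraction = 0.02)
  r <- reg$regions
  expect_equal(sum(r$n_snvs), nrow(reg$members))
  m_f <- subset_sites(sim$matrix,
                      samples = pop_samples(sim$panel, "TBP"))
  if (nrow(r) >= 2) {
    for (i in seq_len(nrow(r) - 1)) {
      for (j in seq(i + 1, nrow(r))) {
        if (r$chrom[i] == r$chrom[j] &&
            abs(r$peak_pos[i] - r$peak_pos[j]) <= 5e5) {
          ci <- match(paste0(r$chrom[i], ":", r$peak_pos[i]),
                      paste0(m_f$chrom, ":", m_f$positions))
          cj <- match(paste0(r$chrom[j], ":", r$peak_pos[j]),
                      paste0(m_f$chrom, ":", m_f$positions))
          r2 <- ld_r2(m_f$alleles[, ci], m_f$alleles[, cj])
          expect_true(is.na(r2) || r2 <= 0.2)
        }
      }
    }
  }
})
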