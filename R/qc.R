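#' Hardy-Weinberg exact test from genotype counts
#'
#' Two-sided exact test: conditional on the allele totals, the probability
#' of a heterozygote count h is `P(h | n, nA) proportional to
#' 2^h * n! / (nAA! * h! * naa!)`; the p-value sums the probabilities of all
#' heterozygote counts (same parity as `nA`) whose probability is less than
#' or equal to that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return the exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotyped sample")
  nA <- 2L * n_AA + n_Aa
  hs <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  # log conditional probabilities, normalized
  logp <- hs * log(2) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((2 * n - nA - hs) / 2 + 1)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Sample-level quality control
#'
#' Excludes samples with a genotype missing rate at or above `miss_max`
#' (reason `missingness`) or a heterozygosity rate more than `het_sd`
#' standard deviations from the mean heterozygosity of all samples (reason
#' `heterozygosity`). Mean and SD are computed over all samples in a single
#' pass; thresholds are applied once, with no iterative re-exclusion.
#'
#' @param m a [haplotype_matrix()] with >= 2 samples.
#' @param miss_max missing-rate threshold (exclusion when `>=`, default 0.05).
#' @param het_sd number of standard deviations for the heterozygosity band.
#' @return a data.frame (class `sample_qc_report`) with one row per sample:
#'   `sample`, `missing_rate`, `het_rate`, `excluded`, `reason`.
#' @export
sample_qc <- function(m, miss_max = 0.05, het_sd = 3) {
  if (n_samples(m) < 2L) stop("sample_qc needs >= 2 samples")
  g <- genotype_dosage(m)
  n_site <- ncol(g)
  n_miss <- rowSums(is.na(g))
  n_obs <- n_site - n_miss
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  missing_rate <- if (n_site > 0L) n_miss / n_site else rep(0, nrow(g))
  het_rate <- ifelse(n_obs > 0L, n_het / n_obs, NA_real_)
  mu <- mean(het_rate, na.rm = TRUE)
  sdev <- stats::sd(het_rate, na.rm = TRUE)
  het_out <- !is.na(het_rate) & !is.na(sdev) & sdev > 0 &
    abs(het_rate - mu) > het_sd * sdev
  reason <- character(nrow(g))
  reason[het_out] <- "heterozygosity"
  reason[missing_rate >= miss_max] <- "missingness"
  rep <- data.frame(sample = m$sample_ids, missing_rate = missing_rate,
                    het_rate = het_rate, excluded = nzchar(reason),
                    reason = reason, stringsAsFactors = FALSE)
  class(rep) <- c("sample_qc_report", "data.frame")
  rep
}

#' Site-level quality control
#'
#' Drops sites in a fixed order: monomorphic among observed haplotypes,
#' singletons (total alternate-allele count of exactly 1), genotype
#' missingness above `miss_max`, then Hardy-Weinberg exact-test p-value on
#' the pooled sample below `hwe_p`. Each site's report records the first
#' failing rule; surviving sites preserve their order.
#'
#' @param m a [haplotype_matrix()].
#' @param miss_max maximum genotype missing fraction (fail when `>`).
#' @param hwe_p Hardy-Weinberg p-value floor (fail when `<`).
#' @param hwe_mode `"pooled"` (default) tests the pooled sample;
#'   `"per_pop"` tests within each population of `panel` and fails a site
#'   when any population rejects. Pooled testing on a structured
#'   multi-population panel rejects strongly differentiated sites (the
#'   Wahlund effect) — exactly the sites a selection scan looks for — so
#'   `"per_pop"` is the appropriate mode when QC runs on the combined
#'   focal + control panel rather than on a single cohort.
#' @param panel a [population_panel()], required for `hwe_mode = "per_pop"`.
#' @return a list with `matrix` (the filtered [haplotype_matrix()]) and
#'   `report` (data.frame: `site_id`, `chrom`, `pos`, `missing_frac`,
#'   `mac`, `alt_count`, `hwe_p`, `pass`, `reason`) plus a `counts` vector
#'   of casualties per rule.
#' @export
site_qc <- function(m, miss_max = 0.05, hwe_p = 1e-6,
                    hwe_mode = c("pooled", "per_pop"), panel = NULL) {
  hwe_mode <- match.arg(hwe_mode)
  a <- m$alleles
  g <- genotype_dosage(m)
  n_obs_hap <- colSums(!is.na(a))
  alt <- colSums(a == 1L, na.rm = TRUE)
  mac <- pmin(alt, n_obs_hap - alt)
  miss_frac <- colMeans(is.na(g))
  hwe_of <- function(gm) {
    n_AA <- colSums(gm == 0L, na.rm = TRUE)
    n_Aa <- colSums(gm == 1L, na.rm = TRUE)
    n_aa <- colSums(gm == 2L, na.rm = TRUE)
    vapply(seq_len(ncol(gm)), function(j) {
      if (n_AA[j] + n_Aa[j] + n_aa[j] < 1L) return(NA_real_)
      hwe_exact_test(n_AA[j], n_Aa[j], n_aa[j])
    }, numeric(1))
  }
  if (hwe_mode == "pooled") {
    hwe <- hwe_of(g)
  } else {
    if (is.null(panel)) stop("hwe_mode = 'per_pop' needs a panel")
    per <- vapply(c(panel$focal, panel$controls), function(p) {
      hwe_of(g[pop_samples(panel, p), , drop = FALSE])
    }, numeric(ncol(g)))
    per <- matrix(per, nrow = ncol(g))
    hwe <- apply(per, 1L, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  }
  reason <- character(ncol(a))
  mono <- alt == 0L | alt == n_obs_hap
  reason[!nzchar(reason) & mono] <- "monomorphic"
  reason[!nzchar(reason) & alt == 1L] <- "singleton"
  reason[!nzchar(reason) & miss_frac > miss_max] <- "missingness"
  reason[!nzchar(reason) & !is.na(hwe) & hwe < hwe_p] <- "hwe"
  pass <- !nzchar(reason)
  report <- data.frame(site_id = m$site_id, chrom = m$chrom,
                       pos = m$positions, missing_frac = miss_frac,
                       mac = mac, alt_count = alt, hwe_p = hwe,
                       pass = pass, reason = reason,
                       stringsAsFactors = FALSE)
  counts <- c(monomorphic = sum(reason == "monomorphic"),
              singleton = sum(reason == "singleton"),
              missingness = sum(reason == "missingness"),
              hwe = sum(reason == "hwe"),
              retained = sum(pass))
  list(matrix = subset_sites(m, sites = pass), report = report,
       counts = counts)
}

#' GATK-style hard filter on variant-record annotations
#'
#' Applies the filter expression
#' `QD < 2.0 || MQ < 40 || FS > 60.0 || SOR > 3.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`: a record fails when any stated inequality holds.
#' A clause whose annotation is absent is skipped (the GATK convention), so
#' an empty annotation map passes.
#'
#' @param annotations named numeric vector or list of INFO annotations.
#' @return TRUE if the record passes, FALSE if any clause fires.
#' @export
gatk_hard_filter <- function(annotations) {
  ann <- unlist(annotations)
  rules <- list(QD = function(x) x < 2.0,
                MQ = function(x) x < 40,
                FS = function(x) x > 60.0,
                SOR = function(x) x > 3.0,
                MQRankSum = function(x) x < -12.5,
                ReadPosRankSum = function(x) x < -8.0)
  for (key in names(rules)) {
    if (!is.null(ann) && key %in% names(ann) && !is.na(ann[[key]])) {
      if (rules[[key]](as.numeric(ann[[key]]))) return(FALSE)
    }
  }
  TRUE
}
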