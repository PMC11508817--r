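#' Per-population derived-allele frequencies
#'
#' Frequencies are computed over non-missing haplotypes only. With the
#' REF = ancestral convention the alternate-allele frequency is the derived
#' allele frequency (DAF).
#'
#' @param m a [haplotype_matrix()].
#' @param panel a [population_panel()].
#' @return a data.frame (class `site_frequencies`) with one row per site:
#'   `chrom`, `pos`, `site_id`, then per population `count_<pop>`,
#'   `ntot_<pop>`, `freq_<pop>` (NA when a population has zero non-missing
#'   haplotypes at the site), pooled `maf`, and a `monomorphic` flag for
#'   sites monomorphic across all populations.
#' @export
allele_frequencies <- function(m, panel) {
  pops <- c(panel$focal, panel$controls)
  out <- data.frame(chrom = m$chrom, pos = m$positions, site_id = m$site_id,
                    stringsAsFactors = FALSE)
  tot_count <- 0
  tot_n <- 0
  for (p in pops) {
    rows <- hap_rows(m, pop_samples(panel, p))
    a <- m$alleles[rows, , drop = FALSE]
    cnt <- colSums(a == 1L, na.rm = TRUE)
    ntot <- colSums(!is.na(a))
    out[[paste0("count_", p)]] <- cnt
    out[[paste0("ntot_", p)]] <- ntot
    out[[paste0("freq_", p)]] <- ifelse(ntot > 0L, cnt / ntot, NA_real_)
    tot_count <- tot_count + cnt
    tot_n <- tot_n + ntot
  }
  pooled <- ifelse(tot_n > 0L, tot_count / tot_n, NA_real_)
  out$maf <- pmin(pooled, 1 - pooled)
  out$monomorphic <- tot_count == 0L | tot_count == tot_n
  class(out) <- c("site_frequencies", "data.frame")
  out
}

#' Hudson's FST estimator for one site
#'
#' The Bhatia et al. form:
#' `[(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
#' [p1(1-p2) + p2(1-p1)]`, with haplotype counts `n1`, `n2`. Returns NA
#' where the denominator is zero (both populations fixed for the same
#' allele). Vectorized over sites.
#'
#' @param p1,p2 allele frequencies in `[0, 1]`.
#' @param n1,n2 non-missing haplotype counts (>= 2).
#' @return FST estimates (can be negative at weakly differentiated sites).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(stats::na.omit(c(p1, p2)) < 0) || any(stats::na.omit(c(p1, p2)) > 1))
    stop("frequencies must be in [0, 1]")
  if (any(stats::na.omit(c(n1, n2)) < 2))
    stop("haplotype counts must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(is.na(den) | den == 0, NA_real_, num / den)
}

#' Population branch statistic
#'
#' `PBS = (FST(focal, c1) + FST(focal, c2) - FST(c1, c2)) / 2`. Negative
#' pairwise FST values are clamped to 0 before combination (toggleable);
#' NA inputs propagate.
#'
#' @param fst_fc1,fst_fc2 focal-vs-control pairwise FST.
#' @param fst_c1c2 control-vs-control pairwise FST.
#' @param clamp_negative clamp negative FST to 0 first (default TRUE).
#' @return the PBS value(s).
#' @export
pbs <- function(fst_fc1, fst_fc2, fst_c1c2, clamp_negative = TRUE) {
  if (clamp_negative) {
    fst_fc1 <- pmax(fst_fc1, 0)
    fst_fc2 <- pmax(fst_fc2, 0)
    fst_c1c2 <- pmax(fst_c1c2, 0)
  }
  (fst_fc1 + fst_fc2 - fst_c1c2) / 2
}

#' PBS directly from three breed allele frequencies
#'
#' Convenience composition of [hudson_fst()] and [pbs()] for worked
#' examples where only published allele frequencies and sample sizes are
#' available: pairwise Hudson FST from the three frequencies (haplotype
#' counts `2 * n_diploid`), negatives clamped to 0, then the focal branch
#' statistic.
#'
#' @param p_focal,p_c1,p_c2 allele frequencies in focal and two control
#'   populations.
#' @param n_focal,n_c1,n_c2 diploid sample sizes.
#' @return the PBS value.
#' @export
pbs_from_frequencies <- function(p_focal, n_focal, p_c1, n_c1, p_c2, n_c2) {
  pbs(hudson_fst(p_focal, 2 * n_focal, p_c1, 2 * n_c1),
      hudson_fst(p_focal, 2 * n_focal, p_c2, 2 * n_c2),
      hudson_fst(p_c1, 2 * n_c1, p_c2, 2 * n_c2))
}

#' Derived-allele frequency contrast
#'
#' `delta_daf = DAF(focal) - aggregate(DAF(controls))`, aggregated by the
#' unweighted mean (default) or the maximum across controls. Requires the
#' REF = ancestral orientation (the simulator's convention) or an
#' externally oriented frequency table.
#'
#' @param freqs a [allele_frequencies()] table.
#' @param panel the [population_panel()] used to build `freqs`.
#' @param aggregate `"mean"` (default) or `"max"` over control frequencies.
#' @return numeric vector of per-site contrasts in `[-1, 1]`.
#' @export
delta_daf <- function(freqs, panel, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  fc <- freqs[[paste0("freq_", panel$focal)]]
  if (is.null(fc))
    stop("no focal frequency column; was the table built with this panel?")
  ctrl <- sapply(panel$controls, function(p) freqs[[paste0("freq_", p)]])
  ctrl <- matrix(ctrl, nrow = nrow(freqs))
  agg <- if (aggregate == "mean") rowMeans(ctrl) else
    apply(ctrl, 1L, max)
  fc - agg
}

#' Heterozygosity ratio per sample
#'
#' Number of heterozygous genotypes over the number of non-reference
#' homozygous genotypes (the bcftools-stats convention); `Inf` when a
#' sample has no non-reference homozygote.
#'
#' @param m a [haplotype_matrix()].
#' @return named numeric vector, one value per sample.
#' @export
heterozygosity_ratio <- function(m) {
  g <- genotype_dosage(m)
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_hom_alt <- rowSums(g == 2L, na.rm = TRUE)
  ifelse(n_hom_alt > 0L, n_het / n_hom_alt,
         ifelse(n_het > 0L, Inf, 0))
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' `F = (O_hom - E_hom) / (L_used - E_hom)` where, over the sample's
#' non-missing sites with pooled frequency p and pooled non-missing allele
#' count A, `E_hom = sum(1 - 2 p (1-p) A / (A-1))` (the PLINK `--het`
#' small-sample correction).
#'
#' @param m a [haplotype_matrix()].
#' @return named numeric vector of F per sample (NA where undefined).
#' @export
inbreeding_coefficient <- function(m) {
  g <- genotype_dosage(m)
  a <- m$alleles
  A <- colSums(!is.na(a))
  p <- ifelse(A > 0L, colSums(a == 1L, na.rm = TRUE) / A, NA_real_)
  usable <- !is.na(p) & A >= 2L
  e_site <- ifelse(usable, 1 - 2 * p * (1 - p) * A / (A - 1), NA_real_)
  vapply(seq_len(nrow(g)), function(i) {
    use <- usable & !is.na(g[i, ])
    L_used <- sum(use)
    if (L_used == 0L) return(NA_real_)
    o_hom <- sum(g[i, use] != 1L)
    e_hom <- sum(e_site[use])
    if (L_used == e_hom) return(NA_real_)
    (o_hom - e_hom) / (L_used - e_hom)
  }, numeric(1)) -> f
  names(f) <- m$sample_ids
  f
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D over a window of sites
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with Tajima's (1989)
#' constants; `pi` is the mean number of pairwise differences estimated
#' from per-site frequencies with the `n/(n-1)` correction. NA when the
#' window has no segregating site.
#'
#' @param m a [haplotype_matrix()] restricted to one population (>= 4
#'   haplotypes); typically a window of sites.
#' @return Tajima's D (scalar).
#' @export
tajimas_d <- function(m) {
  a <- m$alleles
  if (nrow(a) < 4L) stop("Tajima's D needs >= 4 haplotypes")
  nh <- colSums(!is.na(a))
  cnt <- colSums(a == 1L, na.rm = TRUE)
  seg <- cnt > 0L & cnt < nh
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  p <- cnt[seg] / nh[seg]
  pi_hat <- sum(2 * p * (1 - p) * nh[seg] / (nh[seg] - 1))
  k <- tajima_constants(nrow(a))
  (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D in sliding windows for one population
#'
#' @param m a [haplotype_matrix()].
#' @param panel a [population_panel()].
#' @param pop population label to scan.
#' @param window_bp window width in bp (non-overlapping windows).
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `S`, `D`.
#' @export
tajimas_d_windows <- function(m, panel, pop, window_bp = 5e4) {
  mp <- subset_sites(m, samples = pop_samples(panel, pop))
  out <- list()
  for (cc in unique(mp$chrom)) {
    on_c <- which(mp$chrom == cc)
    pos <- mp$positions[on_c]
    win <- floor((pos - 1) / window_bp)
    for (w in unique(win)) {
      sites <- on_c[win == w]
      mw <- subset_sites(mp, sites = sites)
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = w * window_bp + 1, end = (w + 1) * window_bp,
        n_sites = length(sites),
        S = sum({
          cnt <- colSums(mw$alleles == 1L, na.rm = TRUE)
          nh <- colSums(!is.na(mw$alleles))
          cnt > 0L & cnt < nh
        }),
        D = tajimas_d(mw), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))` over
#' pairwise-complete phased haplotypes; NA when either site is monomorphic
#' among the complete haplotypes.
#'
#' @param x,y 0/1 haplotype allele vectors of equal length (NA = missing).
#' @return r-squared in `[0, 1]`, or NA.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  pA <- mean(x); pB <- mean(y)
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(NA_real_)
  pAB <- mean(x == 1L & y == 1L)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' LD decay curve for one population
#'
#' Mean r-squared over all same-chromosome site pairs whose distance falls
#' in each bin, up to `max_dist`. Pairs with undefined r-squared are
#' skipped; empty bins are reported with `n_pairs = 0`.
#'
#' @param m a [haplotype_matrix()].
#' @param panel a [population_panel()].
#' @param pop population label.
#' @param max_dist maximum pair distance in bp (default 500 kb).
#' @param bin_width bin width in bp (default 1 kb).
#' @param chunk internal block size for the vectorized pair sweep.
#' @return data.frame: `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(m, panel, pop, max_dist = 5e5, bin_width = 1e3,
                     chunk = 512L) {
  mp <- subset_sites(m, samples = pop_samples(panel, pop))
  n_bin <- ceiling(max_dist / bin_width)
  sum_r2 <- numeric(n_bin)
  n_pair <- integer(n_bin)
  for (cc in unique(mp$chrom)) {
    sel <- which(mp$chrom == cc)
    X <- mp$alleles[, sel, drop = FALSE]
    pos <- mp$positions[sel]
    storage.mode(X) <- "double"
    M <- !is.na(X)
    X0 <- X; X0[!M] <- 0
    S <- ncol(X)
    if (S < 2L) next
    for (j0 in seq(1L, S, by = chunk)) {
      j1 <- min(j0 + chunk - 1L, S)
      blk <- j0:j1
      # pairwise-complete counts and co-occurrence via cross-products
      n11 <- crossprod(X0, X0[, blk, drop = FALSE])
      nAA <- crossprod(M * 1, M[, blk, drop = FALSE] * 1)
      sA <- crossprod(X0, M[, blk, drop = FALSE] * 1)
      sB <- crossprod(M * 1, X0[, blk, drop = FALSE])
      d <- abs(outer(pos, pos[blk], "-"))
      use <- d > 0 & d <= max_dist & nAA >= 2
      # avoid double counting: site index i < j only
      idx <- outer(seq_len(S), blk, "<")
      use <- use & idx
      if (!any(use)) next
      pA <- sA[use] / nAA[use]
      pB <- sB[use] / nAA[use]
      pAB <- n11[use] / nAA[use]
      den <- pA * (1 - pA) * pB * (1 - pB)
      r2 <- ifelse(den > 0, (pAB - pA * pB)^2 / den, NA_real_)
      bin <- pmin(ceiling(d[use] / bin_width), n_bin)
      keep <- !is.na(r2)
      if (!any(keep)) next
      agg_s <- tapply(r2[keep], bin[keep], sum)
      agg_n <- tapply(r2[keep], bin[keep], length)
      bi <- as.integer(names(agg_s))
      sum_r2[bi] <- sum_r2[bi] + agg_s
      n_pair[bi] <- n_pair[bi] + agg_n
    }
  }
  data.frame(dist_lo = (seq_len(n_bin) - 1L) * bin_width,
             dist_hi = seq_len(n_bin) * bin_width,
             mean_r2 = ifelse(n_pair > 0L, sum_r2 / n_pair, NA_real_),
             n_pairs = n_pair)
}
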