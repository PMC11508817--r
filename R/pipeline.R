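#' Per-site component statistics and CMS score
#'
#' Runs the full scan on a QC-filtered haplotype matrix: per-population
#' derived allele frequencies, pairwise Hudson FST and PBS, the
#' derived-frequency contrast, the haplotype scan (iHS, XPEHH) and the
#' composite CMS score.
#'
#' @param m a [haplotype_matrix()] (after QC).
#' @param panel a [population_panel()] with exactly two controls for the
#'   PBS triplet (more controls: only the first two enter PBS).
#' @param maf_min,cutoff,max_gap,n_bins,min_bin haplotype-scan parameters,
#'   see [haplo_scan()].
#' @param abs_ihs orientation of iHS into CMS, see [cms_scores()].
#' @param delta_daf_aggregate control aggregation for [delta_daf()].
#' @return a data.frame (class `scan_table`): coordinates, per-population
#'   frequencies, `fst_focal_c1`, `fst_focal_c2`, `fst_c1_c2`, `pbs`,
#'   `delta_daf`, the [haplo_scan()] columns and the [cms_scores()]
#'   columns.
#' @export
scan_statistics <- function(m, panel, maf_min = 0.05, cutoff = 0.05,
                            max_gap = 2e5, n_bins = 50, min_bin = 20,
                            abs_ihs = FALSE,
                            delta_daf_aggregate = "mean") {
  freqs <- allele_frequencies(m, panel)
  c1 <- panel$controls[1]
  c2 <- panel$controls[2]
  f <- panel$focal
  nmin <- function(p) pmax(freqs[[paste0("ntot_", p)]], 2L)
  fst_fc1 <- hudson_fst(freqs[[paste0("freq_", f)]], nmin(f),
                        freqs[[paste0("freq_", c1)]], nmin(c1))
  fst_fc2 <- hudson_fst(freqs[[paste0("freq_", f)]], nmin(f),
                        freqs[[paste0("freq_", c2)]], nmin(c2))
  fst_c12 <- hudson_fst(freqs[[paste0("freq_", c1)]], nmin(c1),
                        freqs[[paste0("freq_", c2)]], nmin(c2))
  # two controls jointly monomorphic for the same allele: the estimator is
  # 0/0 but the populations are undifferentiated, so the control-control
  # branch is zero; without this the strongest focal-private sweeps (both
  # controls fixed ancestral) would drop out of PBS
  p1 <- freqs[[paste0("freq_", c1)]]
  p2 <- freqs[[paste0("freq_", c2)]]
  same_fixed <- !is.na(p1) & !is.na(p2) & p1 == p2 & (p1 == 0 | p1 == 1)
  fst_c12[same_fixed] <- 0
  hs <- haplo_scan(m, panel, maf_min = maf_min, cutoff = cutoff,
                   max_gap = max_gap, n_bins = n_bins, min_bin = min_bin)
  tbl <- cbind(freqs,
               data.frame(fst_focal_c1 = fst_fc1, fst_focal_c2 = fst_fc2,
                          fst_c1_c2 = fst_c12,
                          pbs = pbs(fst_fc1, fst_fc2, fst_c12),
                          delta_daf = delta_daf(freqs, panel,
                                                delta_daf_aggregate)),
               hs[, setdiff(names(hs), c("chrom", "pos", "site_id")),
                  drop = FALSE])
  tbl <- cms_scores(tbl, abs_ihs = abs_ihs)
  class(tbl) <- c("scan_table", "data.frame")
  tbl
}

#' Call independent selection regions from a scan table
#'
#' Applies the top-fraction CMS threshold, the focal-enrichment filter,
#' greedy LD clumping in the focal population, and peak-gene assignment.
#'
#' @param scan a [scan_statistics()] table.
#' @param m the [haplotype_matrix()] the scan was computed on.
#' @param panel the [population_panel()].
#' @param genes optional [gene_model()] for peak-gene assignment.
#' @param fraction top CMS fraction (default 0.005).
#' @param window clumping window in bp (default 500 kb).
#' @param r2_max LD independence threshold (default 0.2).
#' @param flank peak-gene flank in bp (default 5 kb).
#' @return a list: `regions`, `members` (see [cluster_regions()]),
#'   `candidates` (logical over scan rows), `threshold` (the CMS cut).
#' @export
call_regions <- function(scan, m, panel, genes = NULL, fraction = 0.005,
                         window = 5e5, r2_max = 0.2, flank = 5000) {
  cand <- threshold_top_fraction(scan$cms, fraction)
  cand <- enrichment_filter(cand, scan, panel)
  m_focal <- subset_sites(m, samples = pop_samples(panel, panel$focal))
  cl <- cluster_regions(scan[cand, c("chrom", "pos", "site_id", "cms")],
                        m_focal, window = window, r2_max = r2_max)
  if (!is.null(genes) && nrow(cl$regions) > 0L)
    cl$regions <- assign_peak_gene(cl$regions, genes, flank = flank)
  list(regions = cl$regions, members = cl$members, candidates = cand,
       threshold = attr(cand, "threshold"))
}

#' End-to-end sweep scan on files
#'
#' Convenience driver: parse a phased VCF and population map, run site QC,
#' compute the scan table, call regions, and optionally write the result
#' TSVs (`{prefix}.siteqc.tsv`, `{prefix}.scan.tsv`, `{prefix}.regions.tsv`,
#' `{prefix}.members.tsv`).
#'
#' @param vcf path to the phased VCF.
#' @param popmap path to the sample->population TSV.
#' @param focal,controls population labels.
#' @param genes_bed optional BED4 path of gene bodies.
#' @param out_prefix optional output path prefix; when NULL nothing is
#'   written.
#' @param run_sample_qc exclude samples failing [sample_qc()] first.
#' @param hwe_mode HWE testing mode for [site_qc()]; defaults to
#'   `"per_pop"` here because this driver always works on a structured
#'   focal + control panel, where pooled testing would reject the very
#'   differentiated sites the scan targets.
#' @param ... passed to [scan_statistics()] and [call_regions()] (matched
#'   by name).
#' @return a list: `matrix`, `panel`, `sample_qc`, `site_qc`, `scan`,
#'   `regions` (the [call_regions()] result).
#' @export
sweep_scan_files <- function(vcf, popmap, focal, controls,
                             genes_bed = NULL, out_prefix = NULL,
                             run_sample_qc = TRUE, hwe_mode = "per_pop",
                             ...) {
  dots <- list(...)
  pick <- function(f) dots[intersect(names(dots), names(formals(f)))]
  m <- parse_vcf(vcf)
  panel <- load_population_panel(popmap, focal, controls,
                                 samples = m$sample_ids)
  sqc <- NULL
  if (run_sample_qc) {
    sqc <- sample_qc(m)
    keep <- sqc$sample[!sqc$excluded]
    if (length(keep) < n_samples(m)) {
      m <- subset_sites(m, samples = keep)
      panel <- population_panel(panel$assignments[keep], panel$focal,
                                panel$controls)
    }
  }
  qc <- site_qc(m, hwe_mode = hwe_mode, panel = panel)
  scan <- do.call(scan_statistics,
                  c(list(m = qc$matrix, panel = panel),
                    pick(scan_statistics)))
  genes <- if (!is.null(genes_bed)) load_gene_bed(genes_bed) else NULL
  reg <- do.call(call_regions,
                 c(list(scan = scan, m = qc$matrix, panel = panel,
                        genes = genes), pick(call_regions)))
  if (!is.null(out_prefix)) {
    write_tsv(qc$report, paste0(out_prefix, ".siteqc.tsv"))
    if (!is.null(sqc)) write_tsv(sqc, paste0(out_prefix, ".sampleqc.tsv"))
    write_tsv(scan, paste0(out_prefix, ".scan.tsv"))
    if (nrow(reg$regions) > 0L) {
      write_tsv(reg$regions, paste0(out_prefix, ".regions.tsv"))
      write_tsv(reg$members, paste0(out_prefix, ".members.tsv"))
    }
  }
  list(matrix = qc$matrix, panel = panel, sample_qc = sqc, site_qc = qc,
       scan = scan, regions = reg)
}
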