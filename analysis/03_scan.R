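#!/usr/bin/env Rscript
# Step 3 — per-SNV selection statistics and diversity summaries.
#
# On the QC-filtered panel: per-breed derived allele frequencies, pairwise
# Hudson FST and the Tibetan-branch PBS, the derived-frequency contrast,
# iHS (focal breed, frequency-bin standardized), XPEHH against each
# control (genome-wide standardized), and the rank-based CMS composite.
# Also the per-breed diversity comparisons: heterozygosity ratio,
# inbreeding coefficient, LD decay, and windowed Tajima's D.

suppressPackageStartupMessages(library(sweepscan))

m <- parse_vcf("results/filtered.vcf")
panel <- load_population_panel("results/sim/sweep.popmap.tsv", "TBP",
                               c("YKS", "DU"), samples = m$sample_ids)

cat("Scanning", n_sites(m), "SNVs in", n_samples(m), "samples...\n")
scan <- scan_statistics(m, panel)
write_tsv(scan, "results/scan.tsv")

scored <- sum(!scan$cms_excluded)
cat("CMS scored at", scored, "SNVs;",
    sum(scan$cms_excluded), "excluded for missing components\n")
top <- scan[order(-ifelse(is.na(scan$cms), -Inf, scan$cms)), ][1:5, ]
cat("Top 5 CMS SNVs:\n")
print(top[, c("site_id", "pos", "freq_TBP", "freq_YKS", "freq_DU",
              "pbs", "ihs", "xpehh_mean", "delta_daf", "cms")],
      digits = 3, row.names = FALSE)

# per-breed diversity: the focal breed should show the higher
# heterozygosity ratio, the lower inbreeding, and the faster LD decay
# when its diversity is elevated relative to the controls
het <- heterozygosity_ratio(m)
f <- inbreeding_coefficient(m)
div <- data.frame(sample = m$sample_ids,
                  population = unname(panel$assignments[m$sample_ids]),
                  het_ratio = unname(het), inbreeding_f = unname(f))
write_tsv(div, "results/diversity.tsv")
agg <- aggregate(cbind(het_ratio, inbreeding_f) ~ population, div, median)
cat("Per-breed medians:\n")
print(agg, digits = 3, row.names = FALSE)

for (p in c(panel$focal, panel$controls)) {
  ld <- ld_decay(m, panel, p, max_dist = 2e5, bin_width = 2e3)
  write_tsv(ld, paste0("results/ld_decay_", p, ".tsv"))
}

td <- do.call(rbind, lapply(c(panel$focal, panel$controls), function(p) {
  cbind(population = p, tajimas_d_windows(m, panel, p, window_bp = 5e4))
}))
write_tsv(td, "results/tajimas_d.tsv")
cat("Mean windowed Tajima's D by breed:\n")
print(aggregate(D ~ population, td, mean), digits = 3, row.names = FALSE)
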