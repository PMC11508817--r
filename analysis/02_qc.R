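#!/usr/bin/env Rscript
# Step 2 — quality control.
#
# Sample-level QC (genotype failure rate >= 5%, heterozygosity beyond
# mean +/- 3 SD) and site-level QC (monomorphic, singletons, > 5%
# missingness, Hardy-Weinberg exact p < 1e-6). HWE runs per breed: the
# combined panel is strongly structured, and pooled testing would reject
# the differentiated sites the scan is after (Wahlund effect). Writes the
# reports and the filtered VCF under results/.

suppressPackageStartupMessages(library(sweepscan))

m <- parse_vcf("results/sim/sweep.vcf")
panel <- load_population_panel("results/sim/sweep.popmap.tsv", "TBP",
                               c("YKS", "DU"), samples = m$sample_ids)

sqc <- sample_qc(m)
write_tsv(sqc, "results/sampleqc.tsv")
cat("Sample QC:", sum(sqc$excluded), "of", nrow(sqc), "samples excluded\n")
keep <- sqc$sample[!sqc$excluded]
if (length(keep) < n_samples(m)) {
  m <- subset_sites(m, samples = keep)
  panel <- population_panel(panel$assignments[keep], panel$focal,
                            panel$controls)
}

qc <- site_qc(m, hwe_mode = "per_pop", panel = panel)
write_tsv(qc$report, "results/siteqc.tsv")
write_vcf(qc$matrix, "results/filtered.vcf", panel = panel)
cat("Site QC:", paste(names(qc$counts), qc$counts, collapse = ", "), "\n")
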