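Package: sweepscan
Title: Selective-Sweep Scans in Structured Pig Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects Darwinian positive selection in a focal population
    against two control populations from phased diploid VCFs. Implements
    sample- and site-level quality control (missingness, heterozygosity
    outliers, singleton removal, Hardy-Weinberg exact test), allele-frequency
    statistics (Hudson FST, the population branch statistic PBS, derived
    allele frequency contrasts, Tajima's D, LD decay), haplotype statistics
    (EHH, iHS, XPEHH with frequency-bin and genome-wide standardization), a
    rank-based composite-of-multiple-signals (CMS) score, LD-based clumping
    of candidate SNVs into independent selection regions with peak-gene
    assignment, and a forward Wright-Fisher three-population sweep simulator
    used to exercise the full pipeline end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
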