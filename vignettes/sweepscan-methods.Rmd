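---
title: "Detecting selective sweeps in a structured pig panel: methods and design"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps in a structured pig panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tibetan pigs live under chronic hypoxia, cold and strong UV at high
altitude, and their genomes carry the footprint of the selection that made
that possible: alleles that rose rapidly in frequency in the highland
breed but not in lowland breeds such as Yorkshire and Duroc. `sweepscan`
implements the full scan that finds such loci from a phased
multi-population VCF: quality control, allele-frequency statistics,
haplotype statistics, a composite score, and the reduction of significant
SNVs to independent genomic regions with peak genes. A forward
Wright–Fisher simulator generates a three-breed panel with a known sweep
so that every stage — and the pipeline end to end — is testable without
any external data.

## Statistics

**Hudson FST and PBS.** Pairwise differentiation uses Hudson's estimator
in the Bhatia et al. form,
$$\hat F_{ST} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2)+p_2(1-p_1)},$$
with $n$ the non-missing haplotype counts. It is a ratio-of-moments
estimator robust to unequal sample sizes — the study design here is
markedly unbalanced (58 focal vs 25 + 35 control diploids in the
published panel). The population branch statistic isolates
frequency change on the focal branch:
$$\mathrm{PBS} = \tfrac12\left(F_{ST}^{(F,C_1)} + F_{ST}^{(F,C_2)} - F_{ST}^{(C_1,C_2)}\right).$$
Negative pairwise FST estimates (small-sample noise) are clamped to zero
before combination; this is toggleable. PBS is computed per SNV, with no
window averaging, because the published worked examples report it at
single SNVs. One pipeline-level convention: when both controls are
monomorphic for the same allele the estimator of $F_{ST}^{(C_1,C_2)}$ is
0/0; two identical monomorphic samples are undifferentiated, so the
control–control branch is taken as zero. Without this, precisely the
strongest focal-private sweeps would drop out of the scan.

**EHH, iHS, XPEHH.** Extended haplotype homozygosity at distance $x$ from
a core site is the probability that two random carrier haplotypes are
identical over the whole interval, computed by incremental group
refinement ($\sum_g \binom{n_g}{2}/\binom{n}{2}$). Curves stop at the
0.05 decay cutoff, at the chromosome end, or at an inter-site gap above
200 kb (the selscan default; no additional gap penalty, mirroring
selscan's default-off gap scaling). iHH is the trapezoidal integral of
EHH over physical distance, restricted to EHH ≥ 0.05 with a final
interpolated segment down to the cutoff. iHS is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$ — large negative values mark long
derived haplotypes — standardized within 50 equal-width derived-frequency
bins (bins under 20 sites merged with neighbors), so each bin has mean 0
and SD 1 by construction. Cores need both allele classes at ≥ 2 carriers
and derived frequency in [0.05, 0.95]. XPEHH compares whole-population
iHH (allele-agnostic EHH from the core) between the focal breed and one
control, standardized genome-wide; with two controls, two XPEHH tracks
are computed and their per-site mean feeds the composite (min/max
available). Sites with any missing allele in the scanned population are
skipped during EHH extension rather than treated as homozygosity-breaking;
QC caps missingness at 5% so little information is lost.

**ΔDAF.** The derived-frequency contrast is focal frequency minus the
unweighted mean of the control frequencies. The simulator writes
REF = ancestral / ALT = derived, so orientation is direct; for real data
an explicit ancestral orientation must be supplied.

**CMS.** The composite score is deliberately rank-based: for each of the
four oriented components (PBS, −iHS, mean XPEHH, ΔDAF) a site's
fractional upper-tail rank is $u_k = (r_k - 0.5)/N$, and
$\mathrm{CMS} = \frac1K\sum_k -\log_{10} u_k$. The published pipeline
defers its composite to an earlier reference whose exact formula it does
not restate; a rank combination uses the same ingredients, is
distribution-free, and is invariant under monotone transforms of any
component. The consequence is stated plainly: absolute CMS values are
comparable only within one dataset, and the published absolute threshold
(5.66/5.67) is not reproduced — only ranks, candidate sets and regions
are. Sites missing any component (e.g. iHS-skipped near-fixed cores) are
excluded from scoring rather than imputed.

**Regions.** Candidates are the top 0.5% of CMS scores (boundary ties all
kept), filtered to SNVs whose focal frequency strictly exceeds every
control ("significantly enriched" is implemented as strict frequency
dominance; a binomial-test variant is available). Greedy LD clumping
follows: the highest-CMS unassigned candidate seeds a region and absorbs
unassigned candidates within ±500 kb at $r^2 > 0.2$ (LD measured in the
focal breed, since the scan is about focal haplotype structure); by
construction any two region peaks within the window satisfy
$r^2 \le 0.2$. A region's gene is the one whose body ±5 kb contains the
peak SNV, ties broken by nearest body midpoint. The published "1 Mb
block" phrasing is treated as descriptive of region scale; no extra 1 Mb
merge is applied.

**Quality control.** Sample QC excludes genotype failure ≥ 5% or
heterozygosity outside mean ± 3 SD (statistics over all samples, single
pass — no iterative re-exclusion scheme is defined in the source
description). Site QC drops, in order: monomorphic sites, singletons
(total alternate count exactly 1, VCFtools semantics), sites above 5%
genotype missingness, and Hardy–Weinberg exact-test failures at
$p < 10^{-6}$. The HWE exact test enumerates the conditional heterozygote
distribution $P(h \mid n, n_A) \propto 2^h n!/(n_{AA}!\,h!\,n_{aa}!)$ and
sums all configurations no more probable than the observed one (ties
included, the standard two-sided convention). HWE can be tested pooled or
per population; the pipeline default for a structured focal + control
panel is per population, because pooled testing rejects strongly
differentiated sites (the Wahlund effect) — verifiably so: the published
top SNVs, with breed frequencies like 0.93/0.33/0.06, would fail a pooled
test at the study's sample sizes by many orders of magnitude, so pooled
HWE cannot have been applied to the combined scan panel. The GATK-style
hard-filter expression (`QD < 2.0 || MQ < 40 || FS > 60.0 || SOR > 3.0 ||
MQRankSum < -12.5 || ReadPosRankSum < -8.0`) is provided as a
record-level predicate with absent annotations skipping their clause.

## The simulator and its study conditions

`simulate_three_pop_sweep()` is a forward, discrete-generation
Wright–Fisher simulator: infinite-sites mutation on a 1 Mb chromosome
(duplicate active positions re-drawn), uniform recombination with
Poisson(ρL) crossovers per gamete, viability selection with fitness
1 / 1+hs / 1+s at a single site, three populations created by two splits,
and n diploids sampled per population at the present. Default conditions:

| parameter | default | why |
|---|---|---|
| `n_anc` | 200 diploids | desk-scale ancestral size; sets equilibrium diversity cheaply |
| `burn_in` | 10·n_anc generations | diversity within ~1% of the θ = 4Nμ equilibrium |
| `n_pop` | 1000 diploids | breed-scale descendant size; keeps post-split drift moderate and preserves the non-swept allele class's haplotype diversity (at a few hundred diploids the sweep collapses the ancestral class to a handful of lineages, an artifact of tiny Ne that destroys the iHS contrast real breeds show) |
| `t_split1`, `t_split2` | 100, 50 generations | recent breed divergence; background FST at the livestock scale |
| `L`, `mu`, `rho` | 1 Mb, 7.5e-7, 5e-7 /bp/gen | a few thousand segregating SNVs in a 3 × 20 diploid sample; haplotype scales of a few kb (neutral) vs tens of kb (swept) |
| `s`, `h`, `sweep_start` | 0 (scan runs use 0.1), 0.5, 70 generations | a hard sweep from standing variation (initial frequency 0.05–0.20, nearest the chromosome centre) that reaches high but typically sub-fixation frequency — the regime where frequency and haplotype statistics both carry signal |
| `n_sample` | 20 diploids per breed | at or above the minimum control size the published design insists on |

The mutation and recombination rates are per-bp rates for a toy
chromosome, not pig genome rates: with a 200-diploid ancestor they
reproduce the *relative* scales that matter (θ per chromosome, LD decay
within tens of kb, sweep haplotypes an order of magnitude longer than
neutral ones), which is what the statistics consume.

What the simulator deliberately does not emulate: real pig demography
(bottlenecks at domestication, admixture between breeds — a symmetric
migration knob exists but defaults to 0), multiple chromosomes, variable
recombination maps, background selection, genotyping error. Passing the
end-to-end tests therefore shows the statistics and their composition
behave correctly on a clean sweep signal at desk scale; it does not
certify power on real livestock data.

Two calibration notes. First, the default conditions include a 5× size
increase at the first split; within-breed site-frequency spectra are
accordingly skewed toward rare variants and raw Tajima's D sits around
−1. The neutral calibration of Tajima's D is therefore run on the
constant-size configuration (`n_pop = n_anc`), where the statistic's null
expectation of ≈ 0 actually applies; the shift under the default
conditions is demography, not miscalibration. Second, the
site-frequency-spectrum goodness-of-fit test uses a small-L,
high-recombination configuration so that sites are effectively
independent and the chi-square's multinomial variance assumption holds.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout (VCF convention); BED input
is converted on load. Sample *i* owns haplotype rows 2i−1 and 2i, left GT
allele first. Missing alleles are `NA`; frequencies use non-missing
counts, and a population with no observed haplotype at a site gets an NA
sentinel that propagates (FST → PBS → CMS exclusion). `hudson_fst` is NA
when both populations are fixed for the same allele; `ihh` is NA when a
carrier class has fewer than two haplotypes or an integral is zero;
windows with no segregating site give NA Tajima's D; z-scoring a
zero-variance bin returns 0. The exact-test p-value includes
configurations with probability equal to the observed one, with a 1e-12
relative tolerance guarding floating-point ties. Region clumping breaks
CMS ties by first index, and gene assignment breaks midpoint ties by
start position then name, so all outputs are deterministic; the whole
pipeline is byte-reproducible for a fixed seed, which the test suite
asserts.

## Scale of the shipped analyses

The numbered scripts under `analysis/` and the heavier tests run the
default study conditions: one 1 Mb chromosome, 3 × 20 diploids, ~4000
SNVs after QC, and 20-replicate batches for the power and specificity
properties. A full simulate → QC → scan → regions pass takes a few
seconds on one core; the complete test suite runs in a few minutes.

## Known limitations

- Absolute CMS values are dataset-relative by design (see above); only
  ranks and regions are comparable with the published analysis.
- iHS is undefined at fixed or near-fixed cores, so a completed sweep is
  seen through its shoulders rather than its peak SNV; PBS and ΔDAF still
  cover the peak itself.
- The spec of the published pipeline quotes its candidate threshold
  inconsistently (top 0.5% in the methods, 0.05% in a figure caption, and
  32,499/12,998,482 ≈ 0.25% by arithmetic); the threshold here is a
  parameter with default 0.005.
- Phased input is required; nothing is phased or imputed in-package.
- Per-population HWE is the pipeline default on structured panels for the
  reasons above; the pooled mode remains available and is the bare
  `site_qc()` default.
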