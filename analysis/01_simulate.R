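#!/usr/bin/env Rscript
# Step 1 — simulate the study system.
#
# Forward Wright-Fisher simulation of one highland focal breed (TBP) and
# two lowland control breeds (YKS, DU), with a hard sweep (s = 0.1) from
# standing variation in the focal breed only. Emits the phased VCF, the
# population map, a toy gene annotation and the simulator's ground truth
# under results/sim/.

suppressPackageStartupMessages(library(sweepscan))

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(s = 0.1, seed = 42)
cat("Simulating:", cfg$n_anc, "ancestral diploids,", cfg$n_pop,
    "per breed, splits", cfg$t_split1, "/", cfg$t_split2,
    "generations ago, sweep s =", cfg$s, "from", cfg$sweep_start,
    "generations ago\n")

sim <- simulate_three_pop_sweep(cfg)
paths <- emit_dataset(sim, "results/sim/sweep")

cat("Sampled", n_samples(sim$matrix), "diploids,", n_sites(sim$matrix),
    "segregating SNVs on a", cfg$L / 1e6, "Mb chromosome\n")
cat(sprintf(
  "Swept allele at %d kb: derived frequency %.2f (TBP) vs %.2f (YKS) / %.2f (DU)\n",
  round(sim$truth$selected_pos / 1000), sim$truth$freq_TBP,
  sim$truth$freq_YKS, sim$truth$freq_DU))
cat("Files:", paste(paths, collapse = ", "), "\n")
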