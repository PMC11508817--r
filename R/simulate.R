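#' Configuration for the three-population sweep simulator
#'
#' Defaults describe the desk-scale study system: an ancestral population of
#' 200 diploids evolved to mutation-drift equilibrium (burn-in of
#' `10 * n_anc` generations; the small ancestral size buys equilibrium
#' diversity cheaply), splitting 100 generations ago into a focal highland
#' lineage and a lowland control ancestor that itself splits 50 generations
#' ago into two control breeds, each of 1000 diploids — breed-scale sizes,
#' so post-split drift stays moderate and the non-swept allele class keeps
#' its haplotype diversity, as it does in real livestock; a 1 Mb chromosome
#' with mutation and recombination rates chosen
#' to yield a few thousand segregating SNVs in a 3 x 20 diploid sample;
#' and, when `s > 0`, a hard sweep from standing variation in the focal
#' population only, timed (70 generations at s = 0.1) so the swept allele
#' reaches high but typically sub-fixation frequency at sampling — the
#' partial-sweep regime in which frequency and haplotype statistics both
#' carry signal.
#'
#' @param n_anc ancestral diploid population size.
#' @param n_pop diploid size of each descendant population.
#' @param t_split1 generations ago of the focal / control-ancestor split.
#' @param t_split2 generations ago of the control1 / control2 split
#'   (`t_split1 > t_split2 >= 0`).
#' @param L chromosome length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rho per-bp per-generation recombination rate.
#' @param s selection coefficient of the swept allele (0 = neutral).
#' @param h dominance coefficient in `[0, 1]` (fitness 1, 1+hs, 1+s).
#' @param sweep_start generations ago at which selection begins in the focal
#'   population (`<= t_split1`).
#' @param n_sample diploid samples drawn per population at the present.
#' @param seed random seed for the whole run.
#' @param burn_in burn-in generations (default `10 * n_anc`).
#' @param max_retries re-runs attempted when the selected allele is lost.
#' @param sel_freq_range frequency band of standing variation from which the
#'   selected site is drawn (nearest to `L/2`); falls back to any
#'   polymorphic site when the band is empty.
#' @param mu_post_factor multiplier on `mu` after the first split (1 keeps
#'   mutation on; 0 switches post-split mutation off, used to audit mutation
#'   bookkeeping).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_anc = 200, n_pop = 1000, t_split1 = 100,
                       t_split2 = 50, L = 1e6, mu = 7.5e-7, rho = 5e-7,
                       s = 0, h = 0.5, sweep_start = 70, n_sample = 20,
                       seed = 1, burn_in = 10L * n_anc, max_retries = 10,
                       sel_freq_range = c(0.05, 0.20), mu_post_factor = 1) {
  cfg <- list(n_anc = as.integer(n_anc), n_pop = as.integer(n_pop),
              t_split1 = as.integer(t_split1), t_split2 = as.integer(t_split2),
              L = as.integer(L), mu = mu, rho = rho, s = s, h = h,
              sweep_start = as.integer(sweep_start),
              n_sample = as.integer(n_sample), seed = as.integer(seed),
              burn_in = as.integer(burn_in),
              max_retries = as.integer(max_retries),
              sel_freq_range = sel_freq_range,
              mu_post_factor = mu_post_factor)
  if (cfg$t_split1 <= cfg$t_split2 || cfg$t_split2 < 0L)
    stop("need t_split1 > t_split2 >= 0")
  if (cfg$s < 0) stop("selection coefficient s must be >= 0")
  if (cfg$h < 0 || cfg$h > 1) stop("dominance h must be in [0, 1]")
  if (cfg$sweep_start > cfg$t_split1)
    stop("sweep_start must be <= t_split1")
  if (cfg$burn_in < 8L * cfg$n_anc)
    stop("burn_in must be >= 8 * n_anc generations")
  if (cfg$mu <= 0 || cfg$rho < 0) stop("need mu > 0 and rho >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate three diverged populations with an optional focal sweep
#'
#' Forward-in-time discrete-generation Wright-Fisher simulation with
#' infinite-sites mutation on `1..L` (active duplicate positions re-drawn)
#' and uniform crossover (count ~ Poisson(rho * L)). The emitted VCF
#' convention is REF = ancestral allele, ALT = derived allele, so derived
#' allele frequencies downstream can use REF/ALT directly. Sites
#' monomorphic in the combined sample are dropped.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `matrix` (a [haplotype_matrix()]), `panel`
#'   (a [population_panel()] with focal `TBP` and controls `YKS`, `DU`) and
#'   `truth` (data.frame: selected position/site index, `s`, `sweep_start`,
#'   per-population final derived-allele frequency in the sample, `lost`,
#'   `in_vcf`, and `attempts` used).
#' @export
simulate_three_pop_sweep <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    raw <- wf_sim_cpp(cfg$n_anc, cfg$n_pop, cfg$t_split1, cfg$t_split2,
                      cfg$L, cfg$mu, cfg$rho, cfg$s, cfg$h, cfg$sweep_start,
                      cfg$n_sample, cfg$burn_in, cfg$mu_post_factor,
                      cfg$sel_freq_range[1], cfg$sel_freq_range[2])
    lost <- cfg$s > 0 && (raw$selected_pos < 0 ||
                            is.na(raw$focal_pop_freq) ||
                            raw$focal_pop_freq == 0)
    if (!lost || attempts > cfg$max_retries) break
  }
  pops <- c("TBP", "YKS", "DU")
  samples <- paste0(rep(pops, each = cfg$n_sample), "_",
                    rep(seq_len(cfg$n_sample), times = 3L))
  m <- haplotype_matrix(raw$alleles, positions = raw$positions,
                        chrom = "chr1", sample_ids = samples)
  # drop sites monomorphic in the combined sample
  counts <- colSums(m$alleles)
  poly <- counts > 0L & counts < nrow(m$alleles)
  m <- subset_sites(m, sites = poly)
  panel <- population_panel(
    stats::setNames(rep(pops, each = cfg$n_sample), samples),
    focal = "TBP", controls = c("YKS", "DU"))
  sel_pos <- if (raw$selected_pos >= 0) raw$selected_pos else NA_integer_
  site_idx <- if (!is.na(sel_pos)) match(sel_pos, m$positions) else NA_integer_
  truth <- data.frame(
    selected_pos = sel_pos,
    selected_site = site_idx,
    init_freq = raw$sel_init_freq,
    s = cfg$s, h = cfg$h, sweep_start = cfg$sweep_start,
    freq_TBP = raw$sample_freq[1], freq_YKS = raw$sample_freq[2],
    freq_DU = raw$sample_freq[3],
    focal_pop_freq = raw$focal_pop_freq,
    lost = lost, in_vcf = !is.na(site_idx), attempts = attempts)
  list(matrix = m, panel = panel, truth = truth,
       split_positions = raw$split_positions)
}

#' Write a simulated dataset to disk
#'
#' Emits `{prefix}.vcf` (phased VCF 4.2), `{prefix}.popmap.tsv`,
#' `{prefix}.genes.bed` (toy genes tiled every 100 kb, 20 kb long, plus one
#' gene overlapping the selected site when present) and
#' `{prefix}.truth.tsv`.
#'
#' @param sim result of [simulate_three_pop_sweep()].
#' @param out_prefix output path prefix.
#' @param gene_every,gene_len tiling interval and gene length (bp).
#' @return named character vector of the four file paths, invisibly.
#' @export
emit_dataset <- function(sim, out_prefix, gene_every = 1e5, gene_len = 2e4) {
  m <- sim$matrix
  paths <- c(vcf = paste0(out_prefix, ".vcf"),
             popmap = paste0(out_prefix, ".popmap.tsv"),
             genes = paste0(out_prefix, ".genes.bed"),
             truth = paste0(out_prefix, ".truth.tsv"))
  write_vcf(m, paths[["vcf"]], panel = sim$panel)
  write_tsv(data.frame(sample = names(sim$panel$assignments),
                       population = unname(sim$panel$assignments)),
            paths[["popmap"]])
  L <- max(m$positions, 1)
  starts0 <- seq(0L, max(0L, L - as.integer(gene_len)), by = as.integer(gene_every))
  genes <- data.frame(chrom = "chr1", start0 = starts0,
                      end0 = starts0 + as.integer(gene_len),
                      name = sprintf("TOY%03d", seq_along(starts0)))
  if (!is.na(sim$truth$selected_pos)) {
    sp <- sim$truth$selected_pos
    overlaps <- genes$start0 < sp & sp <= genes$end0
    genes <- genes[!overlaps, , drop = FALSE]  # exactly one gene at the truth
    genes <- rbind(genes,
                   data.frame(chrom = "chr1",
                              start0 = max(0L, as.integer(sp - gene_len / 2)),
                              end0 = as.integer(sp + gene_len / 2),
                              name = "SWEPT1"))
    genes <- genes[order(genes$start0), , drop = FALSE]
  }
  utils::write.table(genes, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
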