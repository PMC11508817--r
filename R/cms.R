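#' Composite-of-multiple-signals score from component statistics
#'
#' Each component is oriented so that larger values mean stronger evidence
#' of a sweep in the focal population: PBS, minus iHS (long derived
#' haplotypes score high; `abs_ihs = TRUE` uses `|iHS|` instead), the
#' aggregated standardized XPEHH, and the derived-frequency contrast. For
#' component k the fractional upper-tail rank is
#' `u_k = (rank from top - 0.5) / N` over the N sites with every component
#' available, and `CMS = (1/K) * sum(-log10(u_k))`. Being rank-based, CMS
#' is invariant under strictly monotone transforms of any component, and
#' its absolute scale is comparable only within one dataset.
#'
#' @param tbl data.frame with columns `pbs`, `ihs`, `xpehh_mean`,
#'   `delta_daf` (others are carried through).
#' @param abs_ihs orient iHS by absolute value rather than by sign.
#' @return `tbl` with added columns `u_<component>` (fractional ranks),
#'   `cms` (NA at excluded sites) and `cms_excluded`.
#' @export
cms_scores <- function(tbl, abs_ihs = FALSE) {
  comp <- cbind(pbs = tbl$pbs,
                neg_ihs = if (abs_ihs) abs(tbl$ihs) else -tbl$ihs,
                xpehh_mean = tbl$xpehh_mean,
                delta_daf = tbl$delta_daf)
  scored <- stats::complete.cases(comp)
  N <- sum(scored)
  if (N < 2L) stop("need >= 2 sites with all components available")
  u <- matrix(NA_real_, nrow = nrow(comp), ncol = ncol(comp),
              dimnames = list(NULL, colnames(comp)))
  for (k in seq_len(ncol(comp))) {
    r_top <- rank(-comp[scored, k], ties.method = "average")
    u[scored, k] <- (r_top - 0.5) / N
  }
  tbl$u_pbs <- u[, "pbs"]
  tbl$u_neg_ihs <- u[, "neg_ihs"]
  tbl$u_xpehh <- u[, "xpehh_mean"]
  tbl$u_delta_daf <- u[, "delta_daf"]
  tbl$cms <- rowMeans(-log10(u))
  tbl$cms_excluded <- !scored
  tbl
}

#' Retain the top fraction of CMS scores
#'
#' Keeps the `ceiling(fraction * N)` highest-scoring sites among the N
#' scored sites; ties at the boundary are all retained (the candidate set
#' may then exceed the nominal count, recorded in attribute `n_ties_extra`).
#'
#' @param cms numeric CMS scores (NA = unscored, never a candidate).
#' @param fraction top fraction in (0, 1), default 0.005.
#' @return logical candidate vector with attributes `threshold` and
#'   `n_ties_extra`.
#' @export
threshold_top_fraction <- function(cms, fraction = 0.005) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  scored <- !is.na(cms)
  N <- sum(scored)
  k <- min(ceiling(fraction * N), N)
  thr <- sort(cms[scored], decreasing = TRUE)[k]
  cand <- !is.na(cms) & cms >= thr
  attr(cand, "threshold") <- thr
  attr(cand, "n_ties_extra") <- sum(cand) - k
  cand
}

#' Focal-enrichment filter on candidate SNVs
#'
#' Retains candidates whose focal derived/alternate allele frequency
#' strictly exceeds the frequency in every control population.
#'
#' @param candidates logical vector over sites.
#' @param freqs an [allele_frequencies()] table parallel to `candidates`.
#' @param panel the [population_panel()].
#' @return logical vector: candidate and focal-enriched.
#' @export
enrichment_filter <- function(candidates, freqs, panel) {
  fc <- freqs[[paste0("freq_", panel$focal)]]
  dominated <- rep(TRUE, length(candidates))
  for (p in panel$controls) {
    dominated <- dominated & !is.na(fc) &
      !is.na(freqs[[paste0("freq_", p)]]) &
      fc > freqs[[paste0("freq_", p)]]
  }
  candidates & dominated
}

# r2 of one site against many, in a haplotype matrix (pairwise complete)
r2_against <- function(m, seed_site, other_sites) {
  vapply(other_sites, function(j) {
    v <- ld_r2(m$alleles[, seed_site], m$alleles[, j])
    if (is.na(v)) 0 else v
  }, numeric(1))
}

#' Cluster candidate SNVs into independent selection regions
#'
#' Greedy LD clumping: the unassigned candidate with the highest CMS seeds
#' a region; every unassigned candidate on the same chromosome within
#' `window` bp of the seed with `r2(seed, site) > r2_max` (computed in the
#' focal population) joins it; repeat until all candidates are assigned.
#' The region span is the min..max member position and the peak is the
#' seed, so peaks of distinct regions within `window` of each other are in
#' low LD (`r2 <= r2_max`) by construction.
#'
#' @param cand_tbl data.frame of candidate sites with columns `chrom`,
#'   `pos`, `site_id`, `cms`.
#' @param m_focal a [haplotype_matrix()] of the focal population holding
#'   (at least) the candidate sites.
#' @param window clumping window in bp (default 500 kb).
#' @param r2_max LD threshold defining independence (default 0.2).
#' @return a list with `regions` (data.frame: `region_id`, `chrom`,
#'   `start`, `end`, `n_snvs`, `peak_id`, `peak_pos`, `peak_cms`) and
#'   `members` (data.frame: `region_id`, `site_id`, `chrom`, `pos`, `cms`).
#' @export
cluster_regions <- function(cand_tbl, m_focal, window = 5e5, r2_max = 0.2) {
  if (nrow(cand_tbl) == 0L)
    return(list(regions = data.frame(), members = data.frame()))
  key <- paste0(cand_tbl$chrom, ":", cand_tbl$pos)
  mkey <- paste0(m_focal$chrom, ":", m_focal$positions)
  col <- match(key, mkey)
  if (anyNA(col))
    stop("candidate site(s) absent from the focal haplotype matrix: ",
         paste(cand_tbl$site_id[is.na(col)], collapse = ", "))
  unassigned <- rep(TRUE, nrow(cand_tbl))
  region_of <- integer(nrow(cand_tbl))
  regions <- list()
  rid <- 0L
  while (any(unassigned)) {
    rid <- rid + 1L
    seed <- which(unassigned)[which.max(cand_tbl$cms[unassigned])]
    near <- which(unassigned & cand_tbl$chrom == cand_tbl$chrom[seed] &
                    abs(cand_tbl$pos - cand_tbl$pos[seed]) <= window)
    near <- setdiff(near, seed)
    joined <- if (length(near)) {
      near[r2_against(m_focal, col[seed], col[near]) > r2_max]
    } else integer()
    members <- c(seed, joined)
    region_of[members] <- rid
    unassigned[members] <- FALSE
    regions[[rid]] <- data.frame(
      region_id = rid, chrom = cand_tbl$chrom[seed],
      start = min(cand_tbl$pos[members]), end = max(cand_tbl$pos[members]),
      n_snvs = length(members), peak_id = cand_tbl$site_id[seed],
      peak_pos = cand_tbl$pos[seed], peak_cms = cand_tbl$cms[seed],
      stringsAsFactors = FALSE)
  }
  members <- data.frame(region_id = region_of, site_id = cand_tbl$site_id,
                        chrom = cand_tbl$chrom, pos = cand_tbl$pos,
                        cms = cand_tbl$cms, stringsAsFactors = FALSE)
  list(regions = do.call(rbind, regions), members = members)
}

#' Assign the peak gene of each selection region
#'
#' A region is annotated with the gene whose body, extended by `flank` bp
#' up- and downstream, contains the region's peak SNV. When several genes
#' qualify, the gene whose body midpoint is nearest the peak wins (ties
#' broken by start position then name, deterministically); regions with no
#' qualifying gene are reported unannotated (NA).
#'
#' @param regions the `regions` data.frame from [cluster_regions()].
#' @param genes a [gene_model()].
#' @param flank flank in bp around the gene body (default 5 kb).
#' @return `regions` with an added `gene` column.
#' @export
assign_peak_gene <- function(regions, genes, flank = 5000) {
  regions$gene <- vapply(seq_len(nrow(regions)), function(i) {
    hits <- genes[genes$chrom == regions$chrom[i] &
                    genes$start - flank <= regions$peak_pos[i] &
                    genes$end + flank >= regions$peak_pos[i], , drop = FALSE]
    if (nrow(hits) == 0L) return(NA_character_)
    mid_d <- abs((hits$start + hits$end) / 2 - regions$peak_pos[i])
    hits <- hits[order(mid_d, hits$start, hits$name), , drop = FALSE]
    hits$name[1L]
  }, character(1))
  regions
}
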