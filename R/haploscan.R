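#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at a site t away from the core is the probability that two randomly
#' drawn carrier haplotypes are identical over `[core..t]`, computed as
#' `sum C(n_g, 2) / C(n, 2)` over the sizes `n_g` of identity groups.
#' Extension stops when EHH falls below `cutoff` (the first sub-cutoff
#' point is recorded so the integral can interpolate down to the cutoff),
#' at the chromosome end, or when the gap to the next usable site exceeds
#' `max_gap`. Sites with any missing allele among the scanned population's
#' haplotypes are excluded from the extension.
#'
#' @param m a [haplotype_matrix()] restricted to the scanned population.
#' @param core site index (1-based column of `m`).
#' @param allele_class `"derived"` (allele 1), `"ancestral"` (allele 0) or
#'   `"all"` haplotypes at the core.
#' @param direction `"left"` or `"right"`.
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param max_gap maximum gap between consecutive used sites in bp.
#' @return an object of class `ehh_curve`: data.frame of `pos`, `offset`
#'   (bp, signed), `ehh` (the core row offset 0 / EHH 1 included), with
#'   attributes `truncation`, `core_pos`, `n_carriers`; NULL (undefined)
#'   when fewer than 2 carriers exist.
#' @export
ehh <- function(m, core, allele_class = c("derived", "ancestral", "all"),
                direction = c("left", "right"), cutoff = 0.05,
                max_gap = 2e5) {
  allele_class <- match.arg(allele_class)
  direction <- match.arg(direction)
  pop_rows <- seq_len(nrow(m$alleles))
  core_al <- m$alleles[, core]
  carriers <- switch(allele_class,
                     derived = pop_rows[!is.na(core_al) & core_al == 1L],
                     ancestral = pop_rows[!is.na(core_al) & core_al == 0L],
                     all = pop_rows[!is.na(core_al)])
  if (length(carriers) < 2L) return(NULL)
  on_c <- which(m$chrom == m$chrom[core])
  res <- ehh_kernel(m$alleles, m$positions, core - 1L, carriers - 1L,
                    pop_rows - 1L,
                    if (direction == "right") 1L else -1L,
                    cutoff, max_gap, min(on_c) - 1L, max(on_c) - 1L)
  pos <- c(m$positions[core], m$positions[res$site])
  curve <- data.frame(pos = pos, offset = pos - m$positions[core],
                      ehh = c(1, res$ehh))
  attr(curve, "truncation") <- res$truncation
  attr(curve, "core_pos") <- m$positions[core]
  attr(curve, "n_carriers") <- length(carriers)
  class(curve) <- c("ehh_curve", "data.frame")
  curve
}

# trapezoidal area of one directed curve over the region where EHH >= cutoff,
# with a final interpolated segment down to the cutoff
ihh_one_side <- function(curve, cutoff = 0.05) {
  if (is.null(curve)) return(NA_real_)
  d <- abs(curve$offset)
  e <- curve$ehh
  total <- 0
  for (i in seq_len(length(e) - 1L)) {
    if (e[i + 1L] >= cutoff) {
      total <- total + (d[i + 1L] - d[i]) * (e[i] + e[i + 1L]) / 2
    } else {
      # interpolate the crossing of the cutoff
      if (e[i] > cutoff) {
        x_star <- d[i] + (e[i] - cutoff) / (e[i] - e[i + 1L]) *
          (d[i + 1L] - d[i])
        total <- total + (x_star - d[i]) * (e[i] + cutoff) / 2
      }
      break
    }
  }
  total
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of the EHH curve over physical distance (bp),
#' summed over both directions, restricted to the region where
#' `EHH >= cutoff` with a final interpolated segment down to the cutoff.
#'
#' @param curve_left,curve_right [ehh()] curves from the same core and
#'   allele class (either may be NULL = undefined, giving NA).
#' @param cutoff the EHH cutoff used when the curves were computed.
#' @return iHH in bp, with attribute `gap_truncated` when either side was
#'   stopped by the max-gap rule.
#' @export
ihh <- function(curve_left, curve_right, cutoff = 0.05) {
  if (is.null(curve_left) || is.null(curve_right)) return(NA_real_)
  v <- ihh_one_side(curve_left, cutoff) + ihh_one_side(curve_right, cutoff)
  attr(v, "gap_truncated") <-
    identical(attr(curve_left, "truncation"), "max_gap") ||
    identical(attr(curve_right, "truncation"), "max_gap")
  v
}

# trapezoid integral of one raw kernel result (no curve object built)
ihh_raw_side <- function(res, core_pos, positions, cutoff) {
  d <- c(0, abs(positions[res$site] - core_pos))
  e <- c(1, res$ehh)
  total <- 0
  for (i in seq_len(length(e) - 1L)) {
    if (e[i + 1L] >= cutoff) {
      total <- total + (d[i + 1L] - d[i]) * (e[i] + e[i + 1L]) / 2
    } else {
      if (e[i] > cutoff)
        total <- total + ((e[i] - cutoff) / (e[i] - e[i + 1L]) *
                            (d[i + 1L] - d[i])) * (e[i] + cutoff) / 2
      break
    }
  }
  total
}

# fast iHH for the scan loop: kernel output integrated directly
ihh_site <- function(m, core, allele_class, cutoff, max_gap,
                     chrom_range = NULL) {
  pop_rows <- seq_len(nrow(m$alleles))
  core_al <- m$alleles[, core]
  carriers <- switch(allele_class,
                     derived = pop_rows[!is.na(core_al) & core_al == 1L],
                     ancestral = pop_rows[!is.na(core_al) & core_al == 0L],
                     all = pop_rows[!is.na(core_al)])
  if (length(carriers) < 2L) return(NA_real_)
  if (is.null(chrom_range)) {
    on_c <- which(m$chrom == m$chrom[core])
    chrom_range <- c(min(on_c), max(on_c))
  }
  lt <- ehh_kernel(m$alleles, m$positions, core - 1L, carriers - 1L,
                   pop_rows - 1L, -1L, cutoff, max_gap,
                   chrom_range[1] - 1L, chrom_range[2] - 1L)
  rt <- ehh_kernel(m$alleles, m$positions, core - 1L, carriers - 1L,
                   pop_rows - 1L, 1L, cutoff, max_gap,
                   chrom_range[1] - 1L, chrom_range[2] - 1L)
  cp <- m$positions[core]
  v <- ihh_raw_side(lt, cp, m$positions, cutoff) +
    ihh_raw_side(rt, cp, m$positions, cutoff)
  attr(v, "gap_truncated") <- lt$truncation == "max_gap" ||
    rt$truncation == "max_gap"
  v
}

#' Unstandardized iHS at one site
#'
#' `ln(iHH_ancestral / iHH_derived)`: large negative values mark
#' unusually long derived haplotypes (the selscan sign convention).
#'
#' @param m a [haplotype_matrix()] restricted to the scanned population.
#' @param core site index.
#' @param maf_min minimum derived-allele frequency distance from 0/1.
#' @param cutoff,max_gap see [ehh()].
#' @return the unstandardized log ratio with attribute `gap_truncated`,
#'   or NA when the site is outside the frequency band, either carrier
#'   class has < 2 haplotypes, or either iHH is zero.
#' @export
ihs_unstandardized <- function(m, core, maf_min = 0.05, cutoff = 0.05,
                               max_gap = 2e5) {
  al <- m$alleles[, core]
  nd <- sum(al == 1L, na.rm = TRUE)
  na_ <- sum(al == 0L, na.rm = TRUE)
  nn <- nd + na_
  if (nn == 0L || nd < 2L || na_ < 2L) return(NA_real_)
  daf <- nd / nn
  if (daf < maf_min || daf > 1 - maf_min) return(NA_real_)
  ia <- ihh_site(m, core, "ancestral", cutoff, max_gap)
  id <- ihh_site(m, core, "derived", cutoff, max_gap)
  if (is.na(ia) || is.na(id) || ia == 0 || id == 0) return(NA_real_)
  v <- log(as.numeric(ia) / as.numeric(id))
  attr(v, "gap_truncated") <- isTRUE(attr(ia, "gap_truncated")) ||
    isTRUE(attr(id, "gap_truncated"))
  v
}

#' Unstandardized XPEHH at one site
#'
#' `ln(iHH_focal / iHH_reference)` with EHH computed over ALL haplotypes at
#' the core in each population (allele-agnostic, the cross-population
#' convention). Positive values mark longer haplotypes in the focal
#' population.
#'
#' @param m_focal,m_ref [haplotype_matrix()] objects for the two
#'   populations (same sites).
#' @param core site index.
#' @param cutoff,max_gap see [ehh()].
#' @return unstandardized log ratio (NA when undefined in either
#'   population), with attribute `gap_truncated`.
#' @export
xpehh_unstandardized <- function(m_focal, m_ref, core, cutoff = 0.05,
                                 max_gap = 2e5) {
  i_f <- ihh_site(m_focal, core, "all", cutoff, max_gap)
  i_r <- ihh_site(m_ref, core, "all", cutoff, max_gap)
  if (is.na(i_f) || is.na(i_r) || i_f == 0 || i_r == 0) return(NA_real_)
  v <- log(as.numeric(i_f) / as.numeric(i_r))
  attr(v, "gap_truncated") <- isTRUE(attr(i_f, "gap_truncated")) ||
    isTRUE(attr(i_r, "gap_truncated"))
  v
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Sites are binned into `n_bins` equal-width DAF bins; bins holding fewer
#' than `min_bin` scored sites are merged with their right neighbor (left
#' for the last bin). Within each final bin the scores are z-scored, so
#' every bin has mean 0 and SD 1 over the sites used.
#'
#' @param ihs_unstd unstandardized iHS values (NA = unscored).
#' @param daf derived allele frequencies, parallel to `ihs_unstd`.
#' @param n_bins number of equal-width frequency bins (default 50).
#' @param min_bin minimum sites per bin before merging (default 20).
#' @return standardized iHS, NA where unscored.
#' @export
standardize_ihs <- function(ihs_unstd, daf, n_bins = 50, min_bin = 20) {
  out <- rep(NA_real_, length(ihs_unstd))
  ok <- !is.na(ihs_unstd) & !is.na(daf)
  if (!any(ok)) return(out)
  bin <- pmin(pmax(ceiling(daf[ok] * n_bins), 1L), n_bins)
  # merge deficient bins rightwards (last bin merges leftwards)
  repeat {
    sizes <- table(bin)
    lv <- sort(as.integer(names(sizes)))
    small <- lv[sizes[as.character(lv)] < min_bin]
    if (length(small) == 0L || length(lv) == 1L) break
    b <- small[1L]
    nxt <- lv[lv > b]
    target <- if (length(nxt)) nxt[1L] else max(lv[lv < b])
    bin[bin == b] <- target
  }
  z <- ihs_unstd[ok]
  for (b in unique(bin)) {
    in_b <- bin == b
    mu <- mean(z[in_b])
    sdev <- stats::sd(z[in_b])
    z[in_b] <- if (!is.na(sdev) && sdev > 0) (z[in_b] - mu) / sdev else 0
  }
  out[ok] <- z
  out
}

#' Standardize XPEHH genome-wide
#'
#' Single mean/SD z-scoring over all scored sites.
#'
#' @param xpehh_unstd unstandardized XPEHH values (NA = unscored).
#' @return standardized values, NA where unscored.
#' @export
standardize_xpehh <- function(xpehh_unstd) {
  ok <- !is.na(xpehh_unstd)
  out <- rep(NA_real_, length(xpehh_unstd))
  if (sum(ok) < 2L) return(out)
  mu <- mean(xpehh_unstd[ok])
  sdev <- stats::sd(xpehh_unstd[ok])
  out[ok] <- if (sdev > 0) (xpehh_unstd[ok] - mu) / sdev else 0
  out
}

#' Haplotype-based selection scan (iHS and XPEHH)
#'
#' Computes, per site: the unstandardized and bin-standardized iHS in the
#' focal population, unstandardized and genome-wide-standardized XPEHH of
#' the focal population against each control, and their per-site mean
#' (the aggregate used by the composite score).
#'
#' @param m a [haplotype_matrix()] (all populations).
#' @param panel a [population_panel()].
#' @param maf_min iHS core-site minor-frequency floor (default 0.05).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param max_gap maximum inter-site gap in bp (default 200 kb).
#' @param n_bins,min_bin iHS standardization bins, see [standardize_ihs()].
#' @param xpehh_aggregate `"mean"` (default), `"min"` or `"max"` over the
#'   per-control standardized XPEHH scores.
#' @return data.frame (class `haplo_scan`): `chrom`, `pos`, `site_id`,
#'   `daf_focal`, `ihs_unstd`, `ihs`, `xpehh_<control>_unstd`,
#'   `xpehh_<control>`, `xpehh_mean`, `flags`.
#' @export
haplo_scan <- function(m, panel, maf_min = 0.05, cutoff = 0.05,
                       max_gap = 2e5, n_bins = 50, min_bin = 20,
                       xpehh_aggregate = c("mean", "min", "max")) {
  xpehh_aggregate <- match.arg(xpehh_aggregate)
  S <- n_sites(m)
  m_f <- subset_sites(m, samples = pop_samples(panel, panel$focal))
  m_c <- lapply(panel$controls,
                function(p) subset_sites(m, samples = pop_samples(panel, p)))
  af <- m_f$alleles
  nd <- colSums(af == 1L, na.rm = TRUE)
  nn <- colSums(!is.na(af))
  daf <- ifelse(nn > 0L, nd / nn, NA_real_)
  ihs_u <- rep(NA_real_, S)
  xp_u <- matrix(NA_real_, nrow = S, ncol = length(panel$controls))
  flags <- character(S)
  ranges <- lapply(split(seq_len(S), m$chrom), range)
  for (j in seq_len(S)) {
    cr <- ranges[[m$chrom[j]]]
    fl <- character()
    # iHS in the focal population
    daf_j <- daf[j]
    if (!is.na(daf_j) && daf_j >= maf_min && daf_j <= 1 - maf_min &&
        nd[j] >= 2L && (nn[j] - nd[j]) >= 2L) {
      ia <- ihh_site(m_f, j, "ancestral", cutoff, max_gap, cr)
      id <- ihh_site(m_f, j, "derived", cutoff, max_gap, cr)
      if (!is.na(ia) && !is.na(id) && ia > 0 && id > 0) {
        ihs_u[j] <- log(as.numeric(ia) / as.numeric(id))
        if (isTRUE(attr(ia, "gap_truncated")) ||
            isTRUE(attr(id, "gap_truncated")))
          fl <- c(fl, "ihs_gap")
      } else fl <- c(fl, "ihs_skip")
    } else fl <- c(fl, "ihs_skip")
    # XPEHH against each control (focal all-haplotype iHH computed once)
    i_f <- ihh_site(m_f, j, "all", cutoff, max_gap, cr)
    for (k in seq_along(m_c)) {
      i_r <- ihh_site(m_c[[k]], j, "all", cutoff, max_gap, cr)
      if (!is.na(i_f) && !is.na(i_r) && i_f > 0 && i_r > 0) {
        xp_u[j, k] <- log(as.numeric(i_f) / as.numeric(i_r))
        if (isTRUE(attr(i_f, "gap_truncated")) ||
            isTRUE(attr(i_r, "gap_truncated")))
          fl <- c(fl, "xpehh_gap")
      } else fl <- c(fl, "xpehh_skip")
    }
    flags[j] <- paste(unique(fl), collapse = ";")
  }
  ihs_std <- standardize_ihs(ihs_u, daf, n_bins, min_bin)
  xp_std <- apply(xp_u, 2L, standardize_xpehh)
  xp_std <- matrix(xp_std, nrow = S)
  agg <- switch(xpehh_aggregate,
                mean = rowMeans(xp_std),
                min = apply(xp_std, 1L, function(r) if (anyNA(r)) NA_real_ else min(r)),
                max = apply(xp_std, 1L, function(r) if (anyNA(r)) NA_real_ else max(r)))
  out <- data.frame(chrom = m$chrom, pos = m$positions, site_id = m$site_id,
                    daf_focal = daf, ihs_unstd = ihs_u, ihs = ihs_std,
                    stringsAsFactors = FALSE)
  for (k in seq_along(panel$controls)) {
    out[[paste0("xpehh_", panel$controls[k], "_unstd")]] <- xp_u[, k]
    out[[paste0("xpehh_", panel$controls[k])]] <- xp_std[, k]
  }
  out$xpehh_mean <- agg
  out$flags <- flags
  class(out) <- c("haplo_scan", "data.frame")
  out
}
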