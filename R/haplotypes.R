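#' Phased haplotype matrix
#'
#' The central container of the pipeline: a haplotypes x sites matrix of
#' 0/1 alleles (NA = missing) together with per-site coordinates and
#' per-sample bookkeeping. Each diploid sample owns two consecutive rows,
#' left GT allele first, so sample `i` (1-based) owns rows `2i - 1` and
#' `2i`. Coordinates are 1-based inclusive (VCF convention).
#'
#' @param alleles integer matrix of 0/1/NA, rows = haplotypes, cols = sites.
#' @param positions integer vector of 1-based physical positions (bp).
#' @param chrom character vector of chromosome labels, one per site.
#' @param site_id character vector of variant identifiers; defaults to
#'   `chrom:pos` where missing.
#' @param sample_ids character vector of sample labels; `length(sample_ids)`
#'   must be `nrow(alleles) / 2`.
#' @param ref,alt reference (ancestral, by the simulator's convention) and
#'   alternate (derived) alleles per site; defaults `"A"`/`"G"`.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, chrom, site_id = NULL,
                             sample_ids = NULL, ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_site <- ncol(alleles)
  n_hap <- nrow(alleles)
  if (n_hap %% 2L != 0L)
    stop("haplotype rows must come in pairs (2 per diploid sample)")
  if (length(positions) != n_site)
    stop("positions length (", length(positions), ") != site count (", n_site, ")")
  if (length(chrom) == 1L) chrom <- rep(chrom, n_site)
  if (length(chrom) != n_site)
    stop("chrom length != site count")
  positions <- as.integer(positions)
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad))
    stop("allele entries must be 0, 1 or NA")
  for (cc in unique(chrom)) {
    p <- positions[chrom == cc]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  if (is.null(site_id)) site_id <- paste0(chrom, ":", positions)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_hap %/% 2L))
  if (length(sample_ids) != n_hap %/% 2L)
    stop("sample_ids length != half the haplotype row count")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample_ids")
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("G", n_site)
  structure(
    list(alleles = alleles, positions = positions, chrom = as.character(chrom),
         site_id = as.character(site_id), sample_ids = as.character(sample_ids),
         ref = as.character(ref), alt = as.character(alt)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$alleles), "haplotypes (",
      length(x$sample_ids), "diploid samples ) x", ncol(x$alleles),
      "sites on", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Number of sites / samples in a haplotype matrix
#' @param m a `haplotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(m) ncol(m$alleles)

#' @rdname n_sites
#' @export
n_samples <- function(m) length(m$sample_ids)

#' Haplotype row indices owned by a set of samples
#' @param m a `haplotype_matrix`.
#' @param samples sample labels.
#' @return integer vector of row indices (two consecutive per sample).
#' @export
hap_rows <- function(m, samples) {
  idx <- match(samples, m$sample_ids)
  if (anyNA(idx))
    stop("samples not in matrix: ", paste(samples[is.na(idx)], collapse = ", "))
  as.integer(rbind(2L * idx - 1L, 2L * idx))
}

#' Subset a haplotype matrix by sites and/or samples
#' @param m a `haplotype_matrix`.
#' @param sites integer or logical index over sites.
#' @param samples character labels or index over samples.
#' @return a `haplotype_matrix`.
#' @export
subset_sites <- function(m, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(m))
  if (is.logical(sites)) sites <- which(sites)
  keep_samp <- m$sample_ids
  if (!is.null(samples)) {
    keep_samp <- if (is.character(samples)) samples else m$sample_ids[samples]
  }
  rows <- hap_rows(m, keep_samp)
  haplotype_matrix(m$alleles[rows, sites, drop = FALSE],
                   positions = m$positions[sites],
                   chrom = m$chrom[sites],
                   site_id = m$site_id[sites],
                   sample_ids = keep_samp,
                   ref = m$ref[sites], alt = m$alt[sites])
}

#' Per-sample diploid genotypes (derived-allele dosage)
#'
#' Collapses haplotype pairs into 0/1/2 dosages; a genotype with either
#' haplotype missing is NA.
#'
#' @param m a `haplotype_matrix`.
#' @return integer matrix, samples x sites.
#' @export
genotype_dosage <- function(m) {
  a <- m$alleles
  odd <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE]
  evn <- a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  g <- odd + evn
  rownames(g) <- m$sample_ids
  g
}

#' Population panel: focal plus control population assignments
#'
#' @param assignments named character vector, sample label -> population.
#' @param focal label of the focal (scanned) population.
#' @param controls ordered labels of >= 2 control populations.
#' @return an object of class `population_panel`.
#' @export
population_panel <- function(assignments, focal, controls) {
  if (is.null(names(assignments)))
    stop("assignments must be a named vector (sample -> population)")
  if (anyDuplicated(names(assignments)))
    stop("duplicated sample labels in assignments: ",
         paste(unique(names(assignments)[duplicated(names(assignments))]),
               collapse = ", "))
  controls <- as.character(controls)
  if (length(controls) < 2L) stop("need >= 2 control populations")
  if (focal %in% controls) stop("focal population cannot also be a control")
  pops <- c(focal, controls)
  missing_pop <- setdiff(pops, unique(assignments))
  if (length(missing_pop))
    stop("population(s) absent from assignments: ",
         paste(missing_pop, collapse = ", "))
  sizes <- table(factor(assignments, levels = pops))
  if (any(sizes < 2L))
    stop("each population needs >= 2 samples; got ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  structure(list(assignments = assignments, focal = as.character(focal),
                 controls = controls),
            class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  sizes <- table(factor(x$assignments, levels = c(x$focal, x$controls)))
  cat("population_panel: focal", x$focal, "(", sizes[[x$focal]], ") vs",
      paste(sprintf("%s (%d)", x$controls, sizes[x$controls]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Samples belonging to one population
#' @param panel a `population_panel`.
#' @param pop population label.
#' @return character vector of sample labels.
#' @export
pop_samples <- function(panel, pop) {
  names(panel$assignments)[panel$assignments == pop]
}

#' Gene model: named genomic intervals
#'
#' Coordinates are 1-based inclusive, matching [haplotype_matrix()].
#'
#' @param chrom,start,end,name parallel vectors describing gene bodies.
#' @return an object of class `gene_model` (a data.frame).
#' @export
gene_model <- function(chrom = character(), start = integer(),
                       end = integer(), name = character()) {
  if (any(start >= end))
    stop("gene start must be < end (1-based inclusive): ",
         paste(name[start >= end], collapse = ", "))
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), name = as.character(name),
                       stringsAsFactors = FALSE),
            class = c("gene_model", "data.frame"))
}
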