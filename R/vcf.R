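#' Read a phased VCF into a haplotype matrix
#'
#' Only biallelic SNVs are retained: multiallelic records, INDELs and
#' records whose REF/ALT are not single bases are dropped and counted.
#' Missing genotypes (`./.` or `.|.`) become NA on both haplotypes.
#'
#' @param path path to a plain-text VCF 4.x file with a GT field.
#' @param require_phased if TRUE (default), any unphased genotype separator
#'   (`/`) at a non-missing genotype is an error naming sample and site.
#' @return a [haplotype_matrix()] with an attribute `dropped` giving the
#'   number of records excluded per reason
#'   (`multiallelic`, `non_snv`).
#' @export
parse_vcf <- function(path, require_phased = TRUE) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample genotype columns: ", path)
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0L) {
    return(haplotype_matrix(
      matrix(integer(), nrow = 2L * (ncol(gt) - 1L), ncol = 0L),
      positions = integer(), chrom = character(),
      sample_ids = colnames(gt)[-1L]))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- !is_multi & is_snv
  dropped <- c(multiallelic = sum(is_multi),
               non_snv = sum(!is_snv & !is_multi))
  samples <- colnames(gt)[-1L]
  # GT is the leading FORMAT field per VCF spec; strip any trailing fields
  gtm <- gt[keep, -1L, drop = FALSE]
  gtm[is.na(gtm)] <- "."  # vcfR reads fully-missing GT as NA
  gtm <- matrix(sub(":.*$", "", gtm), nrow = nrow(gtm))
  site_lab <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])
  miss <- matrix(gtm %in% c("./.", ".|.", "."), nrow = nrow(gtm))
  ok <- matrix(grepl("^[01.][|/][01.]$", gtm), nrow = nrow(gtm))
  if (any(!ok & !miss)) {
    i <- which(!ok & !miss, arr.ind = TRUE)[1L, ]
    stop("malformed GT '", gtm[i[1L], i[2L]], "' for sample ",
         samples[i[2L]], " at ", site_lab[i[1L]])
  }
  if (require_phased) {
    unph <- matrix(grepl("/", gtm, fixed = TRUE), nrow = nrow(gtm)) & !miss
    if (any(unph)) {
      i <- which(unph, arr.ind = TRUE)[1L, ]
      stop("unphased genotype for sample ", samples[i[2L]], " at ",
           site_lab[i[1L]], " (require_phased = TRUE)")
    }
  }
  left <- substr(gtm, 1L, 1L)
  right <- substr(gtm, 3L, 3L)
  to_int <- function(x) {
    x[x == "."] <- NA_character_
    x[!nzchar(x)] <- NA_character_
    suppressWarnings(as.integer(x))
  }
  S <- sum(keep)
  al <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = S)
  if (S > 0L) {
    l <- matrix(to_int(left), nrow = S)
    r <- matrix(to_int(right), nrow = S)
    l[miss] <- NA_integer_
    r[miss] <- NA_integer_
    al[seq(1L, nrow(al), 2L), ] <- t(l)
    al[seq(2L, nrow(al), 2L), ] <- t(r)
  }
  m <- haplotype_matrix(
    al,
    positions = as.integer(fix[keep, "POS"]),
    chrom = fix[keep, "CHROM"],
    site_id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                     site_lab, fix[keep, "ID"]),
    sample_ids = samples,
    ref = ref[keep], alt = alt[keep])
  attr(m, "dropped") <- dropped
  m
}

#' Write a haplotype matrix as a phased VCF 4.2
#'
#' Emits a GT-only FORMAT; missing haplotypes are written as `.`
#' within the phased separator (both missing: `.|.`).
#'
#' @param m a [haplotype_matrix()].
#' @param path output path.
#' @param panel optional [population_panel()]; when given, sample columns
#'   follow the panel's sample order (focal first, then controls).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, panel = NULL) {
  samples <- m$sample_ids
  if (!is.null(panel)) {
    ord <- unlist(lapply(c(panel$focal, panel$controls),
                         function(p) pop_samples(panel, p)))
    ord <- ord[ord %in% samples]
    if (length(ord) != length(samples))
      stop("panel does not cover every sample in the matrix")
    samples <- ord
  }
  rows <- hap_rows(m, samples)
  a <- m$alleles[rows, , drop = FALSE]
  ach <- matrix(as.character(a), nrow = nrow(a))
  ach[is.na(ach)] <- "."
  S <- n_sites(m)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (S > 0L) {
    odd <- ach[seq(1L, nrow(ach), 2L), , drop = FALSE]
    evn <- ach[seq(2L, nrow(ach), 2L), , drop = FALSE]
    gt <- matrix(paste(odd, evn, sep = "|"), nrow = nrow(odd))
    body <- apply(gt, 2L, paste, collapse = "\t")
    lines <- paste(m$chrom, m$positions, m$site_id, m$ref, m$alt,
                   ".", ".", ".", "GT", body, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Load a sample -> population map
#'
#' @param path two-column TSV with header `sample<TAB>population`.
#' @param focal focal population label.
#' @param controls character vector of >= 2 control labels.
#' @param samples optional sample labels (e.g. from a VCF) that must all be
#'   present in the map; missing ones are an error, and the returned panel
#'   is restricted to these samples (map rows for other samples are
#'   ignored).
#' @return a [population_panel()].
#' @export
load_population_panel <- function(path, focal, controls, samples = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(tab)))
    stop("population map needs columns 'sample' and 'population': ", path)
  if (anyDuplicated(tab$sample))
    stop("duplicated sample rows in population map: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  if (!focal %in% tab$population)
    stop("focal population '", focal, "' not present in ", path)
  if (!is.null(samples)) {
    absent <- setdiff(samples, tab$sample)
    if (length(absent))
      stop("samples in VCF but absent from population map: ",
           paste(absent, collapse = ", "))
    tab <- tab[tab$sample %in% samples, , drop = FALSE]
  }
  assignments <- stats::setNames(tab$population, tab$sample)
  population_panel(assignments, focal, controls)
}

#' Load gene intervals from a BED file
#'
#' BED coordinates (0-based half-open) are converted to the internal
#' 1-based inclusive convention: BED `(start, end)` becomes
#' `[start + 1, end]`.
#'
#' @param path path to a BED4+ file (chrom, start, end, name).
#' @return a [gene_model()].
#' @export
load_gene_bed <- function(path) {
  if (file.size(path) == 0L)
    return(gene_model())
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("BED must have >= 4 columns (chrom,start,end,name)")
  bad <- which(tab[[2L]] >= tab[[3L]])
  if (length(bad))
    stop("BED start >= end at line ", bad[1L], ": ",
         paste(tab[bad[1L], 1:4], collapse = " "))
  gene_model(chrom = tab[[1L]], start = tab[[2L]] + 1L, end = tab[[3L]],
             name = tab[[4L]])
}

#' Write a result table as a TSV
#'
#' All pipeline tables are written in one dialect: tab-separated, header
#' line, no quoting, no row names, NA as `NA`.
#'
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
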