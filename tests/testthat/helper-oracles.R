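# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

# haplotype matrix from a character vector of haplotype strings ("0101..")
hap_mat <- function(strings, positions = NULL, chrom = "chr1", ...) {
  a <- do.call(rbind, lapply(strings, function(s) {
    v <- strsplit(s, "")[[1]]
    ifelse(v == ".", NA_integer_, as.integer(v))
  }))
  if (is.null(positions)) positions <- seq_len(ncol(a)) * 1000L
  haplotype_matrix(a, positions = positions, chrom = chrom, ...)
}

# a valid random haplotype matrix (no missing data unless asked)
random_hap_mat <- function(n_hap, n_site, miss_prob = 0, max_pos = NULL) {
  a <- matrix(rbinom(n_hap * n_site, 1L, runif(1, 0.2, 0.8)),
              nrow = n_hap)
  if (miss_prob > 0) {
    drop <- matrix(runif(n_hap * n_site) < miss_prob, nrow = n_hap)
    a[drop] <- NA_integer_
  }
  if (is.null(max_pos)) max_pos <- n_site * 2000L
  pos <- sort(sample.int(max_pos, n_site))
  haplotype_matrix(a, positions = pos, chrom = "chr1")
}

# two-population panel over a matrix's samples, split in half
half_panel <- function(m, focal = "FOC", c1 = "C1", c2 = "C2") {
  n <- n_samples(m)
  stopifnot(n %% 3 == 0)
  pops <- rep(c(focal, c1, c2), each = n / 3)
  population_panel(stats::setNames(pops, m$sample_ids), focal, c(c1, c2))
}

# EHH by exhaustive pair counting: fraction of carrier pairs identical
# over every site between core and j (inclusive of j, exclusive of core)
ehh_oracle <- function(alleles, positions, core, carriers, direction,
                      cutoff = 0.05, max_gap = 2e5) {
  n <- length(carriers)
  span <- if (direction > 0) seq(core + 1L, ncol(alleles)) else
    rev(seq_len(core - 1L))
  out_site <- integer()
  out_ehh <- numeric()
  last_pos <- positions[core]
  # per-pair identity maintained as a boolean AND over every used site
  alive <- matrix(TRUE, n, n)
  upper <- upper.tri(alive)
  total <- n * (n - 1) / 2
  for (j in span) {
    if (any(is.na(alleles[, j]))) next
    if (abs(positions[j] - last_pos) > max_gap) break
    col <- alleles[carriers, j]
    alive <- alive & outer(col, col, "==")
    e <- sum(alive[upper]) / total
    out_site <- c(out_site, j)
    out_ehh <- c(out_ehh, e)
    last_pos <- positions[j]
    if (e < cutoff) break
  }
  list(site = out_site, ehh = out_ehh)
}

# HWE conditional distribution by direct factorial ratios
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(hs, function(h) {
    exp(h * log(2) + lfactorial(n) - lfactorial((nA - h) / 2) -
          lfactorial(h) - lfactorial((2 * n - nA - h) / 2))
  }, numeric(1))
  p <- w / sum(w)
  sum(p[p <= p[hs == n_Aa] * (1 + 1e-12)])
}

# mean pairwise differences by explicit pair enumeration
pi_oracle <- function(alleles) {
  n <- nrow(alleles)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is.na(alleles[i, ]) & !is.na(alleles[j, ])
      d <- sum(alleles[i, ok] != alleles[j, ok])
      tot <- tot + d
      np <- np + 1
    }
  }
  tot / np
}

# Tajima's D from first principles (constants written out independently)
tajima_oracle <- function(alleles) {
  n <- nrow(alleles)
  cnt <- colSums(alleles)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_ <- pi_oracle(alleles)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_ - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# write a small VCF body directly (bypasses write_vcf)
write_raw_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
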