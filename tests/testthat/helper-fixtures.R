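# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (per-record loops, per-point grids) so they stay independent of
# the vectorised implementation paths they check.

write_vcf_fixture <- function(lines, sample = "S1") {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

vcf_line <- function(pos, ref, alt, qual, fmt, smp, chrom = "chr1") {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", fmt, smp, sep = "\t")
}

# Brute-force diagnostic-site predicate: loops over every position seen
# in either donor and applies the definition record by record.
oracle_diagnostic_sites <- function(donor_o, donor_c, filters) {
  hom_allele <- function(row) {
    if (is.na(row$gt1) || is.na(row$gt2) || row$gt1 != row$gt2) return(NULL)
    toupper(row$alleles[[1]][row$gt1 + 1])
  }
  passes <- function(row, allele) {
    !is.null(allele) &&
      !is.na(row$total_depth) && row$total_depth >= filters$min_depth &&
      !is.na(row$qual) && row$qual >= filters$min_qual &&
      (!filters$require_biallelic ||
         length(row$alleles[[1]]) <= 2) &&
      (!filters$snps_only ||
         (nchar(allele) == 1 && nchar(row$ref) == 1))
  }
  key_o <- paste(donor_o$chrom, donor_o$pos)
  key_c <- paste(donor_c$chrom, donor_c$pos)
  out <- list()
  for (k in intersect(key_o, key_c)) {
    ro <- donor_o[key_o == k, ][1, ]
    rc <- donor_c[key_c == k, ][1, ]
    a_o <- hom_allele(ro)
    a_c <- hom_allele(rc)
    if (passes(ro, a_o) && passes(rc, a_c) && a_o != a_c) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ro$chrom, pos = ro$pos, allele_o = a_o, allele_c = a_c)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  res[order(res$chrom, res$pos), ]
}

# Naive grid-search maximiser of the per-site binomial mixture
# log-likelihood; evaluates the full per-site sum at every grid point.
oracle_mle_grid <- function(counts, epsilon, n_grid = 1e6) {
  n_c <- counts$n_c
  n <- counts$n_o + counts$n_c
  keep <- n > 0
  n_c <- n_c[keep]; n <- n[keep]
  p <- seq(0, 1, length.out = n_grid + 1)
  q <- p * (1 - epsilon) + (1 - p) * epsilon
  ll <- 0
  for (i in seq_along(n)) {
    ll <- ll + dbinom(n_c[i], n[i], q, log = TRUE)
  }
  p[which.max(ll)]
}

# Small classified-call fixture used by several composition tests.
mixed_calls_fixture <- function() {
  counts <- tibble::tibble(
    chrom = "chr1", pos = seq_len(20) * 10L,
    n_o = c(30L, 0L, 0L, 12L, 25L, 0L, 40L, 8L, 0L, 3L,
            0L, 50L, 1L, 0L, 20L, 15L, 0L, 6L, 0L, 0L),
    n_c = c(0L, 28L, 35L, 14L, 0L, 44L, 0L, 9L, 31L, 17L,
            0L, 0L, 1L, 26L, 22L, 0L, 38L, 7L, 12L, 55L),
    n_other = 0L
  )
  classify_sites(counts)
}
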