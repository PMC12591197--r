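# Donor-diagnostic site discovery: positions where the two donors are
# confidently homozygous for different alleles, so any chimera read at the
# site identifies its donor of origin.

#' Filters for diagnostic-site discovery
#'
#' Thresholds applied to each donor's variant record before a site is
#' accepted as diagnostic.  The defaults (10 reads, quality 30) are
#' conventional hard filters for RNA-seq genotype calls; both are exposed
#' because upstream callers differ in depth and quality scales.
#'
#' @param min_depth Minimum per-donor read depth (reads, default 10).
#' @param min_qual Minimum per-donor site quality (Phred-scaled, default
#'   30).  Records with missing `QUAL` fail this filter.
#' @param require_biallelic Drop records listing more than one alternate
#'   allele (default `TRUE`).
#' @param snps_only Keep only single-base substitutions; indels and MNPs
#'   are excluded (default `TRUE`).
#' @return A list of class `diagnostic_filters`.
#' @export
diagnostic_filters <- function(min_depth = 10, min_qual = 30,
                               require_biallelic = TRUE, snps_only = TRUE) {
  check_number(min_depth, "min_depth", min = 1, integerish = TRUE)
  check_number(min_qual, "min_qual", min = 0)
  structure(
    list(min_depth = as.integer(min_depth), min_qual = min_qual,
         require_biallelic = isTRUE(require_biallelic),
         snps_only = isTRUE(snps_only)),
    class = "diagnostic_filters"
  )
}

#' Find donor-diagnostic SNP sites
#'
#' Intersects the two donors' variant calls and keeps the sites where each
#' donor is homozygous (by its genotype field), both records pass the
#' depth/quality filters, and the two homozygous alleles differ.  Only
#' such sites make chimera allele counts donor-interpretable.  Sites with
#' a missing genotype in either donor are excluded, as are sites present
#' in only one donor's call set (absence is not assumed to mean
#' homozygous-reference; set `absent_means_homref = TRUE` for callers that
#' emit all-sites VCFs where absence does carry that meaning).
#'
#' @param donor_o,donor_c Variant tibbles from [read_vcf()] for the two
#'   donors (donor O contributes the L1 layer in the canonical chimera;
#'   donor C the L2/L3 layers).  The labels are symmetric: swapping the
#'   inputs swaps `allele_o`/`allele_c` (see [swap_donors()]).
#' @param filters A [diagnostic_filters()] object.
#' @param absent_means_homref If `TRUE`, a site present in one donor only
#'   is treated as homozygous-reference in the other donor, with that
#'   donor's depth/qual taken as passing.  Default `FALSE`.
#' @return A tibble sorted by (`chrom`, `pos`): `chrom`, `pos`,
#'   `allele_o`, `allele_c`, `qual_o`, `qual_c`, `depth_o`, `depth_c`.
#' @examples
#' sim <- simulate_chimera(sim_config(seed = 1, n_genes = 10))
#' find_diagnostic_sites(sim$donor_o, sim$donor_c)
#' @export
find_diagnostic_sites <- function(donor_o, donor_c,
                                  filters = diagnostic_filters(),
                                  absent_means_homref = FALSE) {
  check_columns(donor_o, c("chrom", "pos", "alleles", "qual", "gt1", "gt2",
                           "total_depth"), "donor_o")
  check_columns(donor_c, c("chrom", "pos", "alleles", "qual", "gt1", "gt2",
                           "total_depth"), "donor_c")
  stopifnot(inherits(filters, "diagnostic_filters"))

  o <- donor_genotype_calls(donor_o, filters, suffix = "_o")
  c_ <- donor_genotype_calls(donor_c, filters, suffix = "_c")

  if (nrow(o) > 0 && nrow(c_) > 0 &&
      length(intersect(unique(o$chrom), unique(c_$chrom))) == 0) {
    config_error("The two donor call sets share no chromosome names; are they against the same reference?")
  }

  if (absent_means_homref) {
    joined <- dplyr::full_join(o, c_, by = c("chrom", "pos"))
    # A site absent from one donor's call set (pass flag NA after the full
    # join) is taken as homozygous-reference there, with the other donor's
    # REF supplying the allele string and no depth/qual evidence to filter.
    absent_o <- is.na(joined$pass_o)
    joined$allele_o[absent_o] <- joined$ref_c[absent_o]
    joined$pass_o[absent_o] <- TRUE
    absent_c <- is.na(joined$pass_c)
    joined$allele_c[absent_c] <- joined$ref_o[absent_c]
    joined$pass_c[absent_c] <- TRUE
  } else {
    joined <- dplyr::inner_join(o, c_, by = c("chrom", "pos"))
  }

  out <- dplyr::filter(
    joined,
    !is.na(.data$allele_o), !is.na(.data$allele_c),
    .data$pass_o, .data$pass_c,
    .data$allele_o != .data$allele_c
  )
  out <- dplyr::select(out, "chrom", "pos", "allele_o", "allele_c",
                       "qual_o", "qual_c", "depth_o", "depth_c")
  dplyr::arrange(out, .data$chrom, .data$pos)
}

# Reduce one donor's variant tibble to per-site homozygous-genotype calls
# plus a pass/fail flag for the filters. The homozygous allele is looked
# up from the genotype indices, never re-derived from allele depths.
donor_genotype_calls <- function(variants, filters, suffix) {
  if (nrow(variants) > 0 && anyDuplicated(variants[c("chrom", "pos")])) {
    dup <- variants[duplicated(variants[c("chrom", "pos")]), c("chrom", "pos")]
    config_error("Donor call set has duplicate records at %s:%d.",
                 dup$chrom[1], dup$pos[1])
  }
  n_alt <- vapply(variants$alleles, length, integer(1)) - 1L
  hom <- !is.na(variants$gt1) & !is.na(variants$gt2) &
    variants$gt1 == variants$gt2
  allele <- rep(NA_character_, nrow(variants))
  allele[hom] <- purrr::map2_chr(
    variants$alleles[hom], variants$gt1[hom],
    function(a, i) toupper(a[[i + 1L]])
  )
  is_snp <- !is.na(allele) & nchar(allele) == 1 &
    nchar(variants$ref) == 1
  pass <- hom &
    !is.na(variants$total_depth) & variants$total_depth >= filters$min_depth &
    !is.na(variants$qual) & variants$qual >= filters$min_qual &
    (!filters$require_biallelic | n_alt <= 1L) &
    (!filters$snps_only | is_snp)
  out <- tibble(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    allele = allele, qual = variants$qual, depth = variants$total_depth,
    pass = pass
  )
  names(out)[3:7] <- paste0(c("ref", "allele", "qual", "depth", "pass"), suffix)
  out
}

#' Exchange donor labels in a diagnostic-site table
#'
#' Swaps the donor-O and donor-C alleles (and their qualities and depths)
#' at every site.  Applying it twice is the identity; it underpins the
#' package-wide donor-symmetry checks, since
#' `find_diagnostic_sites(c, o)` equals
#' `swap_donors(find_diagnostic_sites(o, c))`.
#'
#' @param sites A diagnostic-site tibble from [find_diagnostic_sites()].
#' @return The same tibble with `_o` and `_c` columns exchanged.
#' @export
swap_donors <- function(sites) {
  check_columns(sites, c("allele_o", "allele_c"), "sites")
  nm <- names(sites)
  is_o <- grepl("_o$", nm)
  is_c <- grepl("_c$", nm)
  nm[is_o] <- sub("_o$", "_c", nm[is_o])
  nm[is_c] <- sub("_c$", "_o", nm[is_c])
  out <- setNames(sites, nm)
  out[names(sites)]
}
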