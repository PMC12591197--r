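# Donor-of-origin analysis in chimera tissue: map chimera allelic depths
# onto the diagnostic alleles, then classify each expressed site as
# O-only, C-only, both, or uninformative.

#' Thresholds for donor-of-origin classification
#'
#' An allele is called *present* at a site only if it has both an absolute
#' read floor and a minimum fraction of the informative reads, which keeps
#' the call robust across the depth range real tissues and simulations
#' produce.  Sites dominated by third-allele reads are voided as likely
#' mismapping artifacts.
#'
#' @param min_total Minimum informative depth `n_o + n_c` (default 10).
#' @param min_allele_reads Minimum reads to call an allele present
#'   (default 3).
#' @param min_allele_frac Minimum fraction of informative reads to call an
#'   allele present (default 0.05; must be < 0.5 so both alleles can be
#'   present).
#' @param max_other_frac Maximum tolerated `n_other / (n_o + n_c +
#'   n_other)` (default 0.2); above it the site is `UNINFORMATIVE`.
#' @return A list of class `origin_thresholds`.
#' @export
origin_thresholds <- function(min_total = 10, min_allele_reads = 3,
                              min_allele_frac = 0.05, max_other_frac = 0.2) {
  check_number(min_total, "min_total", min = 1, integerish = TRUE)
  check_number(min_allele_reads, "min_allele_reads", min = 0, integerish = TRUE)
  check_number(min_allele_frac, "min_allele_frac", min = 0, max = 0.5 - 1e-12)
  check_number(max_other_frac, "max_other_frac", min = 0, max = 1)
  structure(
    list(min_total = as.integer(min_total),
         min_allele_reads = as.integer(min_allele_reads),
         min_allele_frac = min_allele_frac,
         max_other_frac = max_other_frac),
    class = "origin_thresholds"
  )
}

#' Count donor-allele reads at diagnostic sites in chimera tissue
#'
#' For every diagnostic site, looks up the chimera variant record at the
#' same position and splits its per-allele depths into reads carrying the
#' donor-O allele (`n_o`), the donor-C allele (`n_c`), and any other base
#' (`n_other`).  Diagnostic sites with no chimera record are kept with
#' all-zero counts and `observed = FALSE`, so no site is silently lost and
#' the expressed fraction of diagnostic sites stays reportable.
#'
#' @param chimera Variant tibble from [read_vcf()] for the chimera sample.
#' @param sites Diagnostic-site tibble from [find_diagnostic_sites()].
#' @param sample_id Label stored in the `sample_id` column (defaults to
#'   `"chimera"`).
#' @return A tibble with one row per diagnostic site: `chrom`, `pos`,
#'   `sample_id`, `n_o`, `n_c`, `n_other`, `observed`.
#' @examples
#' sim <- simulate_chimera(sim_config(seed = 1, n_genes = 10))
#' sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
#' count_alleles(sim$chimera, sites)
#' @export
count_alleles <- function(chimera, sites, sample_id = "chimera") {
  check_columns(chimera, c("chrom", "pos", "alleles", "allele_depths"),
                "chimera")
  check_columns(sites, c("chrom", "pos", "allele_o", "allele_c"), "sites")

  chim <- dplyr::select(chimera, "chrom", "pos", "alleles", "allele_depths",
                        "ad_missing")
  joined <- dplyr::left_join(sites, chim, by = c("chrom", "pos"))

  counts <- purrr::pmap(
    list(joined$alleles, joined$allele_depths, joined$allele_o,
         joined$allele_c, joined$ad_missing),
    function(alleles, ad, a_o, a_c, ad_missing) {
      if (is.null(alleles) || isTRUE(ad_missing) || length(ad) == 1 && is.na(ad[1])) {
        return(c(0L, 0L, 0L, FALSE))
      }
      alleles <- toupper(alleles)
      n_o <- sum(ad[alleles == a_o])
      n_c <- sum(ad[alleles == a_c])
      c(n_o, n_c, sum(ad) - n_o - n_c, TRUE)
    }
  )
  m <- do.call(rbind, counts)
  tibble(
    chrom = joined$chrom, pos = joined$pos, sample_id = sample_id,
    n_o = as.integer(m[, 1]), n_c = as.integer(m[, 2]),
    n_other = as.integer(m[, 3]), observed = as.logical(m[, 4])
  )
}

#' Classify the donor of origin of each site
#'
#' Applies the [origin_thresholds()] rules to per-site allele counts.  A
#' site is `UNINFORMATIVE` when its informative depth is below
#' `min_total` or its third-allele fraction exceeds `max_other_frac`;
#' otherwise each donor allele is tested for presence (absolute and
#' relative floors) and the site is labelled `O_ONLY`, `C_ONLY`, `BOTH`,
#' or `UNINFORMATIVE` if neither allele passes.
#'
#' @param counts Allele-count tibble from [count_alleles()] (columns
#'   `n_o`, `n_c`, `n_other`).
#' @param thresholds An [origin_thresholds()] object.
#' @return `counts` with `f_o` (`n_o / (n_o + n_c)`, `NA` at zero
#'   informative depth) and `category` (character) appended.
#' @examples
#' counts <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
#'                          n_o = c(20L, 8L), n_c = c(0L, 12L), n_other = 0L)
#' classify_sites(counts)
#' @export
classify_sites <- function(counts, thresholds = origin_thresholds()) {
  check_columns(counts, c("n_o", "n_c", "n_other"), "counts")
  stopifnot(inherits(thresholds, "origin_thresholds"))
  n_o <- counts$n_o
  n_c <- counts$n_c
  n <- n_o + n_c
  total <- n + counts$n_other
  other_frac <- ifelse(total > 0, counts$n_other / total, 0)

  present <- function(k) k >= thresholds$min_allele_reads &
    n > 0 & k / n >= thresholds$min_allele_frac
  o_present <- present(n_o)
  c_present <- present(n_c)

  category <- dplyr::case_when(
    n < thresholds$min_total ~ "UNINFORMATIVE",
    other_frac > thresholds$max_other_frac ~ "UNINFORMATIVE",
    o_present & c_present ~ "BOTH",
    o_present ~ "O_ONLY",
    c_present ~ "C_ONLY",
    .default = "UNINFORMATIVE"
  )
  dplyr::mutate(counts,
                f_o = ifelse(n > 0, n_o / n, NA_real_),
                category = category)
}

#' Tabulate origin categories
#'
#' Counts sites per origin category; the four categories are always
#' reported (zero-filled), and the counts sum to the number of input
#' sites.
#'
#' @param calls Classified tibble from [classify_sites()].
#' @return A tibble `category`, `n_sites` with one row per category in
#'   the order `O_ONLY`, `C_ONLY`, `BOTH`, `UNINFORMATIVE`.
#' @export
tabulate_origins <- function(calls) {
  check_columns(calls, "category", "calls")
  tab <- table(factor(calls$category, levels = origin_levels))
  tibble(category = origin_levels, n_sites = as.integer(tab))
}
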