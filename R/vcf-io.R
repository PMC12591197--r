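# File I/O: VCF (via vcfR), gene BED intervals, and tab-separated tables.

#' Read one sample of a VCF into a variant-site tibble
#'
#' Parses a VCF 4.x file with [vcfR::read.vcfR()] and extracts, for one
#' named sample, the fields downstream stages consume: position, alleles,
#' site quality, genotype and per-allele read depths.  Every data line
#' yields one row, in file order; nothing is silently dropped.  Records
#' without a usable allelic-depth (`AD`) field are kept with
#' `allele_depths` set to `NA` and `ad_missing = TRUE`.
#'
#' VCF positions are 1-based.  `total_depth` is the sample `DP` when the
#' caller wrote one (some callers count reads that the `AD` field filters
#' out, so `DP` can exceed `sum(AD)`); otherwise it is the sum of the
#' allele depths.  The `depth_source` column records which convention each
#' record used.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param sample Sample name; must appear in the VCF header.
#' @return A tibble with one row per VCF record:
#'   `chrom`, `pos` (1-based), `ref`, `alt` (comma-separated or `NA`),
#'   `alleles` (list of character: ref then alts), `qual`, `gt` (raw
#'   genotype string), `gt1`/`gt2` (allele indices, `NA` when missing),
#'   `allele_depths` (list of integer, one per allele), `total_depth`,
#'   `depth_source` (`"DP"`, `"AD_sum"`, or `NA`), `ad_missing`.
#' @examples
#' vcf <- system.file("extdata", "donor_o_demo.vcf", package = "chimerase")
#' read_vcf(vcf, sample = "OOO")
#' @export
read_vcf <- function(path, sample) {
  if (!file.exists(path)) {
    config_error("VCF file not found: '%s'.", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_mat <- v@gt
  samples <- colnames(gt_mat)[-1]
  if (!sample %in% samples) {
    config_error("Sample '%s' not found in '%s' (samples: %s).",
                 sample, path, paste(samples, collapse = ", "))
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(empty_variant_tbl())
  }

  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  alleles <- purrr::map2(ref, alt, function(r, a) {
    if (is.na(a) || a == ".") r else c(r, strsplit(a, ",", fixed = TRUE)[[1]])
  })
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  fmt <- fix_na_chr(gt_mat[, "FORMAT"])
  smp <- fix_na_chr(gt_mat[, sample])

  parsed <- purrr::pmap(
    list(fmt, smp, alleles, seq_len(n_rec)),
    parse_sample_field
  )

  out <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = ifelse(alt == ".", NA_character_, alt),
    alleles = alleles,
    qual = qual,
    gt = purrr::map_chr(parsed, "gt"),
    gt1 = purrr::map_int(parsed, "gt1"),
    gt2 = purrr::map_int(parsed, "gt2"),
    allele_depths = purrr::map(parsed, "ad"),
    total_depth = purrr::map_int(parsed, "dp"),
    depth_source = purrr::map_chr(parsed, "depth_source"),
    ad_missing = purrr::map_lgl(parsed, "ad_missing")
  )
  out
}

empty_variant_tbl <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), alleles = list(), qual = double(),
    gt = character(), gt1 = integer(), gt2 = integer(),
    allele_depths = list(), total_depth = integer(),
    depth_source = character(), ad_missing = logical()
  )
}

fix_na_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# Parse one FORMAT/sample pair. `rec` is the 1-based data-line index used
# in parse errors.
parse_sample_field <- function(fmt, smp, alleles, rec) {
  n_alleles <- length(alleles)
  keys <- if (nzchar(fmt)) strsplit(fmt, ":", fixed = TRUE)[[1]] else character()
  vals <- if (nzchar(smp)) strsplit(smp, ":", fixed = TRUE)[[1]] else character()
  field <- function(key) {
    i <- match(key, keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[[i]]
  }

  gt_raw <- field("GT")
  gt_idx <- parse_genotype(gt_raw)
  if (any(!is.na(gt_idx) & gt_idx >= n_alleles)) {
    parse_error("Record %d: genotype '%s' indexes allele %d but only %d allele(s) are listed.",
                rec, gt_raw, max(gt_idx, na.rm = TRUE), n_alleles)
  }

  ad_raw <- field("AD")
  if (is.na(ad_raw) || ad_raw == "." || ad_raw == "") {
    ad <- NA
    ad_missing <- TRUE
  } else {
    ad <- suppressWarnings(as.integer(strsplit(ad_raw, ",", fixed = TRUE)[[1]]))
    if (anyNA(ad)) {
      ad <- NA
      ad_missing <- TRUE
    } else if (length(ad) != n_alleles) {
      parse_error("Record %d: AD field '%s' has %d value(s) but the record lists %d allele(s).",
                  rec, ad_raw, length(ad), n_alleles)
    } else {
      ad_missing <- FALSE
    }
  }

  dp_raw <- field("DP")
  dp <- suppressWarnings(as.integer(dp_raw))
  if (!is.na(dp)) {
    depth_source <- "DP"
  } else if (!isTRUE(ad_missing)) {
    dp <- sum(ad)
    depth_source <- "AD_sum"
  } else {
    dp <- NA_integer_
    depth_source <- NA_character_
  }

  list(
    gt = if (is.na(gt_raw)) NA_character_ else gt_raw,
    gt1 = gt_idx[[1]], gt2 = gt_idx[[2]],
    ad = if (isTRUE(ad_missing)) NA else ad,
    dp = dp, depth_source = depth_source, ad_missing = isTRUE(ad_missing)
  )
}

# "0/1", "0|0", "./.", "1" -> integer allele indices (length 2, NA-padded).
parse_genotype <- function(gt) {
  if (is.na(gt) || gt == "" || gt == ".") return(c(NA_integer_, NA_integer_))
  parts <- strsplit(gt, "[/|]")[[1]]
  idx <- suppressWarnings(as.integer(parts))
  if (length(idx) == 1) idx <- c(idx, NA_integer_)
  idx[seq_len(2)]
}

#' Read gene intervals from a BED file
#'
#' Reads a BED4+ file (chrom, start, end, name, then optional score and
#' strand).  BED coordinates are 0-based half-open and are kept that way;
#' a VCF site at position `P` (1-based) overlaps an interval iff
#' `start <= P - 1 < end`.
#'
#' @param path Path to a BED file with at least four tab-separated columns.
#' @return A tibble `gene_id`, `chrom`, `start` (0-based, inclusive),
#'   `end` (0-based, exclusive), `strand` (`"+"`, `"-"` or `"."`), in file
#'   order.
#' @examples
#' bed <- system.file("extdata", "genes_demo.bed", package = "chimerase")
#' read_gene_bed(bed)
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) {
    config_error("BED file not found: '%s'.", path)
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 4)) {
    bad <- line_no[which(n_col < 4)[1]]
    parse_error("BED line %d has fewer than 4 columns.", bad)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1]]
    parse_error("BED line %d has a non-integer start or end.", bad)
  }
  if (any(start >= end)) {
    bad <- line_no[which(start >= end)[1]]
    parse_error("BED line %d has start >= end.", bad)
  }
  gene_id <- vapply(fields, `[[`, "", 4)
  if (anyDuplicated(gene_id)) {
    dup <- gene_id[duplicated(gene_id)][1]
    parse_error("Duplicate gene_id '%s' in '%s'.", dup, path)
  }
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else "."
  }, "")
  tibble(
    gene_id = gene_id,
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end,
    strand = strand
  )
}

#' Write and read tab-separated result tables
#'
#' All tabular outputs of the pipeline (diagnostic sites, allele counts,
#' origin calls, gene-layer statistics) are written as TSV with a single
#' header row, `NA` for missing values, UTF-8 and LF line endings.
#' `read_table()` is the paired reader: `read_table(write_table(x))`
#' round-trips every column, with types restored from the data.
#'
#' @param records A data frame with atomic columns only.
#' @param path Output (or input) file path.
#' @return `write_table()` returns `records` invisibly; `read_table()`
#'   returns a tibble.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_table(tibble::tibble(gene_id = "g1", n_o = 4L, f_o = 0.8), tf)
#' read_table(tf)
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    config_error("`records` must be a data frame.")
  }
  is_atomic <- vapply(records, is.atomic, logical(1))
  if (!all(is_atomic)) {
    config_error("`records` has non-atomic column(s): %s.",
                 paste(names(records)[!is_atomic], collapse = ", "))
  }
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.factor), as.character
  ))
  readr::write_tsv(records, path, na = "NA")
  invisible(records)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    config_error("Table file not found: '%s'.", path)
  }
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}
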