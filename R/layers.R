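# Gene-level layer analysis: pool allele counts over each gene's
# diagnostic sites, normalise the donor-O allele frequency by the
# tissue-level L1 fraction, classify layer-specific genes, and infer the
# chimera's layer arrangement from declared marker genes.

#' Assign diagnostic sites to genes and pool allele counts
#'
#' Maps each counted site onto the gene intervals (BED half-open
#' coordinates: a site at 1-based position `P` lies in a gene iff
#' `start <= P - 1 < end`) and sums `n_o`/`n_c` per gene.  Sites
#' overlapping more than one gene are excluded from pooling (ambiguous
#' attribution) and reported via a message; they remain valid for
#' tissue-level composition.  Genes whose sites carry zero informative
#' reads get `f_o = NA`.
#'
#' @param counts Allele-count tibble from [count_alleles()].
#' @param genes Gene-interval tibble from [read_gene_bed()].
#' @return A tibble with one row per gene that owns at least one
#'   diagnostic site: `gene_id`, `n_sites`, `n_o`, `n_c`, `f_o`.
#' @export
pool_gene_counts <- function(counts, genes) {
  check_columns(counts, c("chrom", "pos", "n_o", "n_c"), "counts")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  if (nrow(genes) == 0) {
    config_error("`genes` is empty: no intervals to pool over.")
  }

  site_gr <- GenomicRanges::GRanges(
    counts$chrom, IRanges::IRanges(start = counts$pos, width = 1)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  hit_tbl <- tibble(
    site = S4Vectors::queryHits(hits),
    gene = S4Vectors::subjectHits(hits)
  )
  per_site <- table(factor(hit_tbl$site, levels = seq_len(nrow(counts))))
  ambiguous <- which(as.integer(per_site) > 1)
  if (length(ambiguous) > 0) {
    inform(sprintf(
      "pool_gene_counts: %d site(s) overlap more than one gene and were excluded from gene pooling.",
      length(ambiguous)))
    hit_tbl <- dplyr::filter(hit_tbl, !.data$site %in% ambiguous)
  }

  pooled <- hit_tbl |>
    mutate(gene_id = genes$gene_id[.data$gene],
           n_o = counts$n_o[.data$site],
           n_c = counts$n_c[.data$site]) |>
    group_by(.data$gene_id) |>
    summarise(n_sites = dplyr::n(),
              n_o = sum(.data$n_o), n_c = sum(.data$n_c),
              .groups = "drop") |>
    mutate(f_o = ifelse(.data$n_o + .data$n_c > 0,
                        .data$n_o / (.data$n_o + .data$n_c), NA_real_))
  # keep BED file order
  pooled[order(match(pooled$gene_id, genes$gene_id)), ]
}

#' L1-normalised expression percentage
#'
#' Converts a gene's donor-O allele frequency into the percentage of its
#' expression attributable to the L1 layer, normalised by the amount of
#' L1 tissue in the sample: `pct_l1 = min(f_o / tissue_l1_fraction, 1) *
#' 100`.  A gene expressed proportionally to the L1 tissue amount scores
#' 100 only when all its expression is L1-derived; genes whose `f_o`
#' exceeds the tissue fraction are capped at 100.
#'
#' @param gene_stats Pooled gene tibble from [pool_gene_counts()].
#' @param tissue_l1_fraction The tissue-level L1 (donor-O) fraction
#'   `p_o` from the composition stage, in `(0, 1]`.
#' @return `gene_stats` with `pct_l1` appended (`NA` where `f_o` is
#'   undefined).
#' @export
pct_expression_l1 <- function(gene_stats, tissue_l1_fraction) {
  check_columns(gene_stats, "f_o", "gene_stats")
  check_number(tissue_l1_fraction, "tissue_l1_fraction", max = 1)
  if (tissue_l1_fraction <= 0) {
    estimation_error("`tissue_l1_fraction` must be > 0; a tissue with no L1 contribution has no L1 normalisation.")
  }
  mutate(gene_stats,
         pct_l1 = pmin(.data$f_o / tissue_l1_fraction, 1) * 100)
}

#' Classify genes as layer-specific
#'
#' Labels each gene by its pooled donor-O allele frequency:
#' `L1_SPECIFIC` when `f_o >= hi`, `L2L3_SPECIFIC` when `f_o <= lo`,
#' `SHARED` in between, and `UNCLASSIFIED` when the gene's pooled
#' informative depth is below `min_reads`.
#'
#' @param gene_stats Tibble with `n_o`, `n_c`, `f_o` per gene.
#' @param min_reads Minimum pooled informative reads (default 20).
#' @param hi,lo Frequency thresholds (defaults 0.95 / 0.05); `hi` must
#'   exceed `lo`.
#' @return `gene_stats` with `layer_class` appended.
#' @export
classify_gene_layer <- function(gene_stats, min_reads = 20,
                                hi = 0.95, lo = 0.05) {
  check_columns(gene_stats, c("n_o", "n_c", "f_o"), "gene_stats")
  check_number(min_reads, "min_reads", min = 0, integerish = TRUE)
  check_number(hi, "hi", min = 0, max = 1)
  check_number(lo, "lo", min = 0, max = 1)
  if (hi <= lo) {
    config_error("`hi` (%g) must be greater than `lo` (%g).", hi, lo)
  }
  mutate(gene_stats, layer_class = dplyr::case_when(
    .data$n_o + .data$n_c < min_reads | is.na(.data$f_o) ~ "UNCLASSIFIED",
    .data$f_o >= hi ~ "L1_SPECIFIC",
    .data$f_o <= lo ~ "L2L3_SPECIFIC",
    .default = "SHARED"
  ))
}

#' Full gene-level layer statistics
#'
#' Chains [pool_gene_counts()], [pct_expression_l1()] and
#' [classify_gene_layer()] into the per-gene result table.
#'
#' @inheritParams pool_gene_counts
#' @inheritParams pct_expression_l1
#' @inheritParams classify_gene_layer
#' @return A tibble `gene_id`, `n_sites`, `n_o`, `n_c`, `f_o`, `pct_l1`,
#'   `layer_class`.
#' @examples
#' sim <- simulate_chimera(sim_config(seed = 2, n_genes = 30, p_l1 = 0.25))
#' sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
#' counts <- count_alleles(sim$chimera, sites)
#' p_o <- 1 - estimate_binomial_mle(counts)$p_c
#' gene_layer_stats(counts, sim$genes, tissue_l1_fraction = p_o)
#' @export
gene_layer_stats <- function(counts, genes, tissue_l1_fraction,
                             min_reads = 20, hi = 0.95, lo = 0.05) {
  pool_gene_counts(counts, genes) |>
    pct_expression_l1(tissue_l1_fraction) |>
    classify_gene_layer(min_reads = min_reads, hi = hi, lo = lo)
}

#' Donor-of-origin calls for declared marker genes
#'
#' Pools allele counts over each marker gene's diagnostic sites and
#' applies the site-level origin rules ([classify_sites()]) to the pooled
#' counts, yielding one origin call per marker.
#'
#' @param counts Allele-count tibble from [count_alleles()].
#' @param genes Gene-interval tibble from [read_gene_bed()].
#' @param markers Tibble `gene_id`, `known_layer` (values `"L1"` or
#'   `"L2L3"`); the layer assignment is declared knowledge (e.g. PDF1 is
#'   L1-specific, SYS is L2/L3-specific), never inferred.
#' @param thresholds [origin_thresholds()] applied to the pooled counts.
#' @return A tibble `gene_id`, `known_layer`, `n_o`, `n_c`, `f_o`,
#'   `category`.
#' @export
call_marker_origins <- function(counts, genes, markers,
                                thresholds = origin_thresholds()) {
  check_columns(markers, c("gene_id", "known_layer"), "markers")
  bad <- setdiff(markers$known_layer, c("L1", "L2L3"))
  if (length(bad)) {
    config_error("Unknown marker layer label(s): %s.",
                 paste(bad, collapse = ", "))
  }
  pooled <- pool_gene_counts(counts, genes)
  joined <- dplyr::left_join(markers, pooled, by = "gene_id")
  joined <- mutate(joined,
                   n_o = dplyr::coalesce(.data$n_o, 0L),
                   n_c = dplyr::coalesce(.data$n_c, 0L),
                   n_other = 0L)
  classify_sites(joined, thresholds) |>
    dplyr::select("gene_id", "known_layer", "n_o", "n_c", "f_o", "category")
}

#' Infer the chimera's layer arrangement from marker genes
#'
#' A periclinal chimera has each meristem layer wholly derived from one
#' donor, so every L1 marker must resolve to a single donor and every
#' L2/L3 marker to the other.  Conflicting markers (including a
#' layer-specific marker called `BOTH`) yield `INCONSISTENT`; any
#' uninformative marker yields `UNDETERMINED`.
#'
#' @param marker_calls Tibble from [call_marker_origins()] (columns
#'   `gene_id`, `known_layer`, `category`).
#' @return A one-row tibble `arrangement` (`"PERICLINAL"`,
#'   `"INCONSISTENT"` or `"UNDETERMINED"`), `l1_donor`, `l2l3_donor`
#'   (`"O"`/`"C"` or `NA`), `n_markers`, plus the evidence table as a
#'   list column.
#' @examples
#' calls <- tibble::tibble(gene_id = c("PDF1", "SYS"),
#'                         known_layer = c("L1", "L2L3"),
#'                         category = c("O_ONLY", "C_ONLY"))
#' infer_structure(calls)
#' @export
infer_structure <- function(marker_calls) {
  check_columns(marker_calls, c("gene_id", "known_layer", "category"),
                "marker_calls")
  l1 <- dplyr::filter(marker_calls, .data$known_layer == "L1")
  l23 <- dplyr::filter(marker_calls, .data$known_layer == "L2L3")
  if (nrow(l1) == 0 || nrow(l23) == 0) {
    config_error("Structure inference needs at least one L1 and one L2L3 marker (got %d and %d).",
                 nrow(l1), nrow(l23))
  }

  donor_of <- function(cat) switch(cat, O_ONLY = "O", C_ONLY = "C", NA_character_)
  result <- if (any(marker_calls$category == "UNINFORMATIVE")) {
    list(arrangement = "UNDETERMINED", l1_donor = NA_character_,
         l2l3_donor = NA_character_)
  } else {
    d_l1 <- unique(vapply(l1$category, donor_of, character(1)))
    d_l23 <- unique(vapply(l23$category, donor_of, character(1)))
    if (length(d_l1) == 1 && length(d_l23) == 1 &&
        !anyNA(c(d_l1, d_l23)) && d_l1 != d_l23) {
      list(arrangement = "PERICLINAL", l1_donor = d_l1, l2l3_donor = d_l23)
    } else {
      list(arrangement = "INCONSISTENT", l1_donor = NA_character_,
           l2l3_donor = NA_character_)
    }
  }

  tibble(
    arrangement = result$arrangement,
    l1_donor = result$l1_donor,
    l2l3_donor = result$l2l3_donor,
    n_markers = nrow(marker_calls),
    evidence = list(marker_calls)
  )
}
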