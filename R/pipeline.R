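# End-to-end orchestration: diagnose -> count -> classify -> estimate ->
# layer-genes, with a machine-readable run manifest.  Every stage error
# is re-raised with the stage name; outputs are deterministic given
# identical inputs and seed.

#' Run the full chimera deconvolution pipeline
#'
#' Reads the two donor VCFs, the chimera VCF, the gene BED and the marker
#' declarations, then runs diagnostic-site discovery, allele counting,
#' origin classification, composition estimation (all three estimators,
#' bootstrap interval on the default one), gene-layer statistics and
#' marker-based structure inference.  All tables are written to
#' `out_dir` as TSV/JSON together with a run manifest recording the
#' configuration, seed and per-stage record counts.
#'
#' @param donor_o_vcf,donor_c_vcf Paths to the donor VCFs.
#' @param chimera_vcf Path to the chimera-tissue VCF.
#' @param genes_bed Path to the gene BED4+ file.
#' @param markers_tsv Path to a TSV with columns `gene_id`,
#'   `known_layer`; `NULL` skips structure inference.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and just returns the results.
#' @param donor_o_sample,donor_c_sample,chimera_sample Sample names in
#'   the respective VCFs.
#' @param filters [diagnostic_filters()] for site discovery.
#' @param thresholds [origin_thresholds()] for origin calls.
#' @param method Estimator whose `p_o` feeds the L1 normalisation and
#'   whose bootstrap interval is computed; default `"site_share"`.
#' @param epsilon Allele-miscall rate for the binomial MLE.
#' @param boot_b Bootstrap replicates (0 disables the interval).
#' @param seed Seed for the bootstrap.
#' @param min_reads,hi,lo Gene-layer classification thresholds
#'   ([classify_gene_layer()]).
#' @return Invisibly, a list with `sites`, `counts`, `calls`,
#'   `origin_summary`, `composition` (tidy tibble, all methods),
#'   `gene_stats`, `structure`, and `manifest`.
#' @examples
#' \donttest{
#' sim <- simulate_chimera(sim_config(seed = 5, n_genes = 40, p_l1 = 0.25))
#' dir <- tempfile()
#' paths <- write_simulation(sim, dir)
#' res <- run_chimera_pipeline(paths$donor_o, paths$donor_c, paths$chimera,
#'                             paths$genes, paths$markers,
#'                             out_dir = file.path(dir, "out"), seed = 1)
#' res$composition
#' }
#' @export
run_chimera_pipeline <- function(donor_o_vcf, donor_c_vcf, chimera_vcf,
                                 genes_bed, markers_tsv = NULL,
                                 out_dir = NULL,
                                 donor_o_sample = "OOO",
                                 donor_c_sample = "CCC",
                                 chimera_sample = "OCC",
                                 filters = diagnostic_filters(),
                                 thresholds = origin_thresholds(),
                                 method = c("site_share", "read_fraction",
                                            "binomial_mle"),
                                 epsilon = 0.005, boot_b = 1000, seed = 1,
                                 min_reads = 20, hi = 0.95, lo = 0.05) {
  method <- match.arg(method)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "chimerase_pipeline_error", parent = e)
    })
  }

  donor_o <- stage("read-donor-o", read_vcf(donor_o_vcf, donor_o_sample))
  donor_c <- stage("read-donor-c", read_vcf(donor_c_vcf, donor_c_sample))
  chimera <- stage("read-chimera", read_vcf(chimera_vcf, chimera_sample))
  genes <- stage("read-genes", read_gene_bed(genes_bed))

  sites <- stage("diagnose",
                 find_diagnostic_sites(donor_o, donor_c, filters))
  counts <- stage("count",
                  count_alleles(chimera, sites, sample_id = chimera_sample))
  calls <- stage("classify", classify_sites(counts, thresholds))
  origin_summary <- tabulate_origins(calls)

  composition <- stage("estimate", estimate_composition(
    counts, thresholds = thresholds, epsilon = epsilon,
    boot_b = 0, methods = c("site_share", "read_fraction", "binomial_mle")
  ))
  if (boot_b > 0) {
    ci <- stage("estimate", bootstrap_ci(
      counts, method = method, b = boot_b, seed = seed,
      epsilon = epsilon, thresholds = thresholds))
    composition$ci_low[composition$method == method] <- ci$ci_low
    composition$ci_high[composition$method == method] <- ci$ci_high
  }
  p_o <- composition$p_o[composition$method == method]

  gene_stats <- stage("layer-genes", gene_layer_stats(
    counts, genes, tissue_l1_fraction = p_o,
    min_reads = min_reads, hi = hi, lo = lo
  ))

  structure_res <- NULL
  if (!is.null(markers_tsv)) {
    markers <- stage("read-markers", read_table(markers_tsv))
    structure_res <- stage("structure", infer_structure(
      call_marker_origins(counts, genes, markers, thresholds)))
  }

  manifest <- list(
    package = "chimerase",
    version = as.character(packageVersion("chimerase")),
    inputs = list(donor_o = donor_o_vcf, donor_c = donor_c_vcf,
                  chimera = chimera_vcf, genes = genes_bed,
                  markers = markers_tsv),
    samples = list(donor_o = donor_o_sample, donor_c = donor_c_sample,
                   chimera = chimera_sample),
    config = list(
      filters = unclass(filters), thresholds = unclass(thresholds),
      method = method, epsilon = epsilon, boot_b = boot_b, seed = seed,
      min_reads = min_reads, hi = hi, lo = lo
    ),
    stage_counts = list(
      donor_o_records = nrow(donor_o), donor_c_records = nrow(donor_c),
      chimera_records = nrow(chimera), genes = nrow(genes),
      diagnostic_sites = nrow(sites), counted_sites = nrow(counts),
      classified_sites = nrow(calls),
      informative_sites = sum(calls$category != "UNINFORMATIVE"),
      genes_with_sites = nrow(gene_stats)
    )
  )

  results <- list(
    sites = sites, counts = counts, calls = calls,
    origin_summary = origin_summary, composition = composition,
    gene_stats = gene_stats, structure = structure_res,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(sites, file.path(out_dir, "diagnostic_sites.tsv"))
    write_table(counts, file.path(out_dir, "allele_counts.tsv"))
    write_table(calls, file.path(out_dir, "origin_calls.tsv"))
    write_table(origin_summary, file.path(out_dir, "origin_summary.tsv"))
    write_table(composition, file.path(out_dir, "composition.tsv"))
    write_table(gene_stats, file.path(out_dir, "gene_layer_stats.tsv"))
    jsonlite::write_json(
      composition, file.path(out_dir, "composition.json"),
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
    if (!is.null(structure_res)) {
      jsonlite::write_json(
        dplyr::select(structure_res, -"evidence"),
        file.path(out_dir, "structure.json"),
        dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(results)
}
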