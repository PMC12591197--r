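# Seeded simulator for chimeric allele-specific expression data.  It
# emulates the data-generating situation of a periclinal chimera: two
# homozygous-divergent donors; a tissue whose transcript pool mixes the
# L1 layer (donor O) at fraction p_l1 with the L2/L3 layers (donor C);
# shared genes expressed from all layers plus planted layer-specific
# genes; per-site sequencing depth and a per-read allele-miscall rate.
# Expression level enters only through site depth, which is sufficient
# because every downstream statistic is a function of allele counts.

#' Simulation configuration
#'
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param n_genes Number of regular genes (two marker genes, an
#'   L1-specific `PDF1` and an L2/L3-specific `SYS`, are always added).
#' @param sites_per_gene Diagnostic sites per gene: a single integer for
#'   a fixed count, or a length-2 vector `c(a, b)` for uniform draws.
#' @param p_l1 True fraction of the tissue transcript pool contributed by
#'   the L1 layer (donor O); the donor-C truth is `1 - p_l1`.
#' @param frac_l1_specific,frac_l2l3_specific Fractions of regular genes
#'   planted as layer-specific (expressed only from L1, resp. only from
#'   L2/L3); the remainder are shared.  Must sum to at most 1.
#' @param depth_model `"poisson"` (default) or `"nbinom"` for
#'   overdispersed depth.
#' @param depth_mean Mean informative depth per site (default 50).
#' @param nb_dispersion Negative-binomial size parameter (default 10);
#'   ignored under the Poisson model.
#' @param epsilon Per-read allele-miscall rate in `[0, 0.5)` (default
#'   0.005, a typical short-read substitution rate).
#' @param n_decoy_sites Non-diagnostic decoy sites at which the donors
#'   share a homozygous genotype (default 50); they exercise the
#'   diagnostic-site filter and must never be returned by it.
#' @param donor_depth,donor_qual Depth and site quality written into the
#'   donor genotype records (defaults 40 and 60).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 200, sites_per_gene = 3,
                       p_l1 = 0.25, frac_l1_specific = 0,
                       frac_l2l3_specific = 0,
                       depth_model = c("poisson", "nbinom"),
                       depth_mean = 50, nb_dispersion = 10,
                       epsilon = 0.005, n_decoy_sites = 50,
                       donor_depth = 40, donor_qual = 60) {
  depth_model <- match.arg(depth_model)
  check_number(seed, "seed", integerish = TRUE)
  check_number(n_genes, "n_genes", min = 1, integerish = TRUE)
  if (!length(sites_per_gene) %in% 1:2 || any(sites_per_gene < 1) ||
      any(sites_per_gene != trunc(sites_per_gene))) {
    config_error("`sites_per_gene` must be a positive integer or a length-2 integer range.")
  }
  if (length(sites_per_gene) == 2 && sites_per_gene[1] > sites_per_gene[2]) {
    config_error("`sites_per_gene` range must have a <= b.")
  }
  check_number(p_l1, "p_l1", min = 0, max = 1)
  check_number(frac_l1_specific, "frac_l1_specific", min = 0, max = 1)
  check_number(frac_l2l3_specific, "frac_l2l3_specific", min = 0, max = 1)
  if (frac_l1_specific + frac_l2l3_specific > 1) {
    config_error("`frac_l1_specific` + `frac_l2l3_specific` must be <= 1.")
  }
  check_number(depth_mean, "depth_mean", min = 1e-9)
  check_number(nb_dispersion, "nb_dispersion", min = 1e-9)
  check_number(epsilon, "epsilon", min = 0, max = 0.5 - 1e-12)
  check_number(n_decoy_sites, "n_decoy_sites", min = 0, integerish = TRUE)
  check_number(donor_depth, "donor_depth", min = 1, integerish = TRUE)
  check_number(donor_qual, "donor_qual", min = 0)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         sites_per_gene = as.integer(sites_per_gene), p_l1 = p_l1,
         frac_l1_specific = frac_l1_specific,
         frac_l2l3_specific = frac_l2l3_specific,
         depth_model = depth_model, depth_mean = depth_mean,
         nb_dispersion = nb_dispersion, epsilon = epsilon,
         n_decoy_sites = as.integer(n_decoy_sites),
         donor_depth = as.integer(donor_depth), donor_qual = donor_qual),
    class = "sim_config"
  )
}

GENE_SPAN <- 1000L   # bp per gene body
GENE_PITCH <- 2000L  # spacing between gene starts

#' Simulate a chimeric allele-specific expression dataset
#'
#' Generates donor-O and donor-C genotype call sets (homozygous-divergent
#' at every diagnostic site, identical at decoy sites), a chimera-tissue
#' call set whose allelic depths are drawn from the layer-mixture model,
#' gene intervals, marker declarations, and the ground truth.  At a site
#' of a gene with L1 expression fraction `f` (1 for L1-specific genes, 0
#' for L2/L3-specific, `p_l1` for shared) and depth `n`, the number of
#' reads from the L1 layer is `Binomial(n, f)` and each read is miscalled
#' to the other donor allele with probability `epsilon`, so the observed
#' donor-O count is marginally `Binomial(n, f(1-eps) + (1-f)eps)`.
#'
#' The returned `donor_o`, `donor_c` and `chimera` tibbles have exactly
#' the schema of [read_vcf()]; [write_simulation()] serialises the same
#' dataset to VCF/BED/TSV files that round-trip through the readers.
#'
#' @param cfg A [sim_config()] object.
#' @return A list: `config`, `donor_o`, `donor_c`, `chimera` (variant
#'   tibbles), `genes` (BED-style tibble), `markers` (`gene_id`,
#'   `known_layer`), and `truth` with `p_l1`, a per-gene table
#'   (`gene_id`, `layer_truth`, `f_true`), a per-site table (`chrom`,
#'   `pos`, `gene_id`, `f_true`, `depth`, `n_l1` pre-error, `n_o`/`n_c`
#'   observed, `expected_f_o`) and the decoy positions.
#' @examples
#' sim <- simulate_chimera(sim_config(seed = 42, n_genes = 20, p_l1 = 0.2))
#' head(sim$truth$sites)
#' @export
simulate_chimera <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_chimera_impl(cfg))
}

simulate_chimera_impl <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  n_reg <- cfg$n_genes

  # gene layout on one chromosome, markers appended after regular genes
  gene_id <- c(sprintf("gene%04d", seq_len(n_reg)), "PDF1", "SYS")
  n_gene <- n_reg + 2L
  start0 <- (seq_len(n_gene) - 1L) * GENE_PITCH
  genes <- tibble(
    gene_id = gene_id, chrom = "chr1",
    start = start0, end = start0 + GENE_SPAN, strand = "+"
  )

  # planted layer classes for regular genes; markers are layer-specific
  # by construction
  n_l1g <- round(cfg$frac_l1_specific * n_reg)
  n_l23g <- round(cfg$frac_l2l3_specific * n_reg)
  cls <- rep("SHARED", n_reg)
  specific_idx <- sample.int(n_reg, n_l1g + n_l23g)
  cls[specific_idx[seq_len(n_l1g)]] <- "L1_SPECIFIC"
  cls[specific_idx[seq_len(n_l23g) + n_l1g]] <- "L2L3_SPECIFIC"
  cls <- c(cls, "L1_SPECIFIC", "L2L3_SPECIFIC")
  f_true_gene <- c(L1_SPECIFIC = 1, L2L3_SPECIFIC = 0, SHARED = cfg$p_l1)[cls]
  gene_truth <- tibble(gene_id = gene_id, layer_truth = cls,
                       f_true = unname(f_true_gene))

  # diagnostic sites within gene bodies
  k <- if (length(cfg$sites_per_gene) == 1) {
    rep(cfg$sites_per_gene, n_gene)
  } else {
    sample(seq(cfg$sites_per_gene[1], cfg$sites_per_gene[2]), n_gene,
           replace = TRUE)
  }
  site_gene <- rep(seq_len(n_gene), k)
  offset <- unlist(lapply(k, function(ki) sort(sample.int(GENE_SPAN, ki))))
  pos <- start0[site_gene] + offset  # 1-based: offset in 1..GENE_SPAN
  n_sites <- length(pos)

  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1), ""))
  o_is_ref <- runif(n_sites) < 0.5
  allele_o <- ifelse(o_is_ref, ref, alt)
  allele_c <- ifelse(o_is_ref, alt, ref)

  # chimera counts under the layer-mixture + miscall model
  f_site <- gene_truth$f_true[site_gene]
  depth <- draw_depth(n_sites, cfg)
  n_l1 <- rbinom(n_sites, depth, f_site)
  n_o <- rbinom(n_sites, n_l1, 1 - cfg$epsilon) +
    rbinom(n_sites, depth - n_l1, cfg$epsilon)
  n_c <- depth - n_o

  # decoy sites beyond the gene region: donors share a homozygous
  # genotype (half hom-ref, half hom-alt), so they are never diagnostic
  n_dec <- cfg$n_decoy_sites
  dec_base <- n_gene * GENE_PITCH
  dec_pos <- dec_base + sort(sample.int(max(10L * n_dec, 1L), n_dec))
  dec_ref <- sample(bases, n_dec, replace = TRUE)
  dec_alt <- unname(vapply(dec_ref, function(r) sample(setdiff(bases, r), 1), ""))
  dec_homalt <- seq_len(n_dec) > n_dec / 2
  dec_depth <- draw_depth(n_dec, cfg)

  donor_o <- bind_rows(
    variant_rows(pos, ref, alt_str = alt, qual = cfg$donor_qual,
                 gt = ifelse(o_is_ref, "0/0", "1/1"),
                 ad = donor_ad(o_is_ref, cfg$donor_depth)),
    decoy_donor_rows(dec_pos, dec_ref, dec_alt, dec_homalt, cfg)
  )
  donor_c <- bind_rows(
    variant_rows(pos, ref, alt_str = alt, qual = cfg$donor_qual,
                 gt = ifelse(o_is_ref, "1/1", "0/0"),
                 ad = donor_ad(!o_is_ref, cfg$donor_depth)),
    decoy_donor_rows(dec_pos, dec_ref, dec_alt, dec_homalt, cfg)
  )

  chim_ad <- purrr::pmap(list(o_is_ref, n_o, n_c), function(oir, a, b) {
    if (oir) c(a, b) else c(b, a)
  })
  chimera <- bind_rows(
    variant_rows(pos, ref, alt_str = alt, qual = 60,
                 gt = "0/1", ad = chim_ad),
    variant_rows(dec_pos, dec_ref,
                 alt_str = ifelse(dec_homalt, dec_alt, NA_character_),
                 qual = 60,
                 gt = ifelse(dec_homalt, "1/1", "0/0"),
                 ad = purrr::map2(dec_homalt, dec_depth, function(ha, d) {
                   if (ha) c(0L, d) else d
                 }))
  )

  site_truth <- tibble(
    chrom = "chr1", pos = pos, gene_id = gene_id[site_gene],
    f_true = f_site, depth = depth, n_l1 = n_l1,
    n_o = n_o, n_c = n_c,
    expected_f_o = f_site * (1 - cfg$epsilon) + (1 - f_site) * cfg$epsilon
  )

  list(
    config = cfg,
    donor_o = donor_o, donor_c = donor_c, chimera = chimera,
    genes = genes,
    markers = tibble(gene_id = c("PDF1", "SYS"),
                     known_layer = c("L1", "L2L3")),
    truth = list(
      p_l1 = cfg$p_l1, p_c = 1 - cfg$p_l1,
      genes = gene_truth, sites = site_truth,
      decoys = tibble(chrom = "chr1", pos = dec_pos)
    )
  )
}

draw_depth <- function(n, cfg) {
  if (n == 0) return(integer())
  if (cfg$depth_model == "poisson") {
    rpois(n, cfg$depth_mean)
  } else {
    rnbinom(n, size = cfg$nb_dispersion, mu = cfg$depth_mean)
  }
}

donor_ad <- function(carries_ref, depth) {
  purrr::map(carries_ref, function(cr) {
    if (cr) c(depth, 0L) else c(0L, depth)
  })
}

# Build read_vcf()-schema rows from parallel vectors; `ad` is a list of
# integer depth vectors matching the allele list of each record.
variant_rows <- function(pos, ref, alt_str, qual, gt, ad) {
  n <- length(pos)
  if (n == 0) return(empty_variant_tbl())
  if (length(gt) == 1) gt <- rep(gt, n)
  if (length(qual) == 1) qual <- rep(qual, n)
  alleles <- purrr::map2(ref, alt_str, function(r, a) {
    if (is.na(a)) r else c(r, a)
  })
  gt_idx <- purrr::map(gt, parse_genotype)
  ad <- purrr::map(ad, as.integer)
  tibble(
    chrom = "chr1", pos = as.integer(pos), ref = ref,
    alt = ifelse(is.na(alt_str), NA_character_, alt_str),
    alleles = alleles, qual = as.numeric(qual), gt = gt,
    gt1 = purrr::map_int(gt_idx, 1), gt2 = purrr::map_int(gt_idx, 2),
    allele_depths = ad,
    total_depth = purrr::map_int(ad, sum),
    depth_source = "DP", ad_missing = FALSE
  )
}

decoy_donor_rows <- function(pos, ref, alt, homalt, cfg) {
  variant_rows(
    pos, ref,
    alt_str = ifelse(homalt, alt, NA_character_),
    qual = cfg$donor_qual,
    gt = ifelse(homalt, "1/1", "0/0"),
    ad = purrr::map2(homalt, rep(cfg$donor_depth, length(pos)),
                     function(ha, d) if (ha) c(0L, d) else d)
  )
}

#' Serialise a simulated dataset to standard files
#'
#' Writes `donor_o.vcf`, `donor_c.vcf`, `chimera.vcf` (VCF 4.2 with
#' GT:AD:DP), `genes.bed` (BED6), `markers.tsv`, and the truth tables
#' `truth_sites.tsv` / `truth_genes.tsv` into `dir`.  Outputs are
#' byte-identical across runs with the same seed, and round-trip through
#' [read_vcf()] / [read_gene_bed()] to the in-memory tibbles.
#'
#' @param sim Result of [simulate_chimera()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    donor_o = file.path(dir, "donor_o.vcf"),
    donor_c = file.path(dir, "donor_c.vcf"),
    chimera = file.path(dir, "chimera.vcf"),
    genes = file.path(dir, "genes.bed"),
    markers = file.path(dir, "markers.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  write_vcf_tbl(sim$donor_o, "OOO", paths$donor_o)
  write_vcf_tbl(sim$donor_c, "CCC", paths$donor_c)
  write_vcf_tbl(sim$chimera, "OCC", paths$chimera)
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t0\t%s", sim$genes$chrom, sim$genes$start,
            sim$genes$end, sim$genes$gene_id, sim$genes$strand),
    paths$genes
  )
  write_table(sim$markers, paths$markers)
  write_table(sim$truth$sites, paths$truth_sites)
  write_table(sim$truth$genes, paths$truth_genes)
  invisible(paths)
}

# Minimal single-sample VCF 4.2 writer for simulator output.
write_vcf_tbl <- function(variants, sample, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=chimerase-simulator",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT:AD:DP\t%s:%s:%d",
    variants$chrom, variants$pos, variants$ref,
    ifelse(is.na(variants$alt), ".", variants$alt),
    format_qual(variants$qual), variants$gt,
    vapply(variants$allele_depths, paste, "", collapse = ","),
    variants$total_depth
  )
  readr::write_lines(c(header, body), path)
}

format_qual <- function(q) {
  ifelse(is.na(q), ".",
         ifelse(q == trunc(q), sprintf("%d", as.integer(q)),
                sprintf("%g", q)))
}

#' Self-consistency check of simulator outputs
#'
#' Re-derives the diagnostic sites from the simulated donor call sets,
#' recomputes per-site allele counts from the chimera call set, and
#' compares them with the simulator's recorded truth; also asserts that
#' no decoy site is ever diagnostic.
#'
#' @param sim Result of [simulate_chimera()].
#' @param filters [diagnostic_filters()] used for the re-derivation; the
#'   defaults pass every planted site.
#' @return A list: `ok` (logical), `n_sites_checked`,
#'   `missing_sites`/`extra_sites` (planted vs re-derived differences),
#'   `count_mismatches` (tibble naming any site whose recomputed counts
#'   differ from truth), `diagnostic_decoys` (decoy positions wrongly
#'   called diagnostic).
#' @export
truth_check <- function(sim, filters = diagnostic_filters()) {
  found <- find_diagnostic_sites(sim$donor_o, sim$donor_c, filters)
  truth_sites <- sim$truth$sites

  key <- function(d) paste(d$chrom, d$pos)
  missing_sites <- truth_sites[!key(truth_sites) %in% key(found),
                               c("chrom", "pos")]
  extra_sites <- found[!key(found) %in% key(truth_sites), c("chrom", "pos")]
  diagnostic_decoys <- sim$truth$decoys[
    key(sim$truth$decoys) %in% key(found), , drop = FALSE]

  counts <- count_alleles(sim$chimera, found)
  cmp <- dplyr::inner_join(
    counts, truth_sites,
    by = c("chrom", "pos"), suffix = c("_obs", "_truth")
  )
  count_mismatches <- dplyr::filter(
    cmp, .data$n_o_obs != .data$n_o_truth | .data$n_c_obs != .data$n_c_truth
  )
  ok <- nrow(missing_sites) == 0 && nrow(extra_sites) == 0 &&
    nrow(diagnostic_decoys) == 0 && nrow(count_mismatches) == 0
  list(
    ok = ok, n_sites_checked = nrow(cmp),
    missing_sites = as_tibble(missing_sites),
    extra_sites = as_tibble(extra_sites),
    count_mismatches = as_tibble(count_mismatches),
    diagnostic_decoys = as_tibble(diagnostic_decoys)
  )
}
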