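test_that("pool_gene_counts sums allele reads over each gene's sites", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(0L, 1000L), end = c(1000L, 2000L),
                          strand = "+")
  counts <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 900L, 1500L),
    n_o = c(5L, 5L, 0L), n_c = c(5L, 5L, 0L), n_other = 0L)
  pooled <- pool_gene_counts(counts, genes)
  expect_equal(pooled$gene_id, c("gA", "gB"))
  expect_equal(pooled$n_o[1], 10L)
  expect_equal(pooled$n_c[1], 10L)
  expect_equal(pooled$f_o[1], 0.5)
  expect_equal(pooled$n_sites, c(2L, 1L))
  # gene whose only site has zero coverage: f_o missing
  expect_true(is.na(pooled$f_o[2]))
  expect_equal(classify_gene_layer(pooled)$layer_class[2], "UNCLASSIFIED")
})

test_that("half-open BED coordinates decide site-gene overlap", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1",
                          start = 100L, end = 200L, strand = "+")
  # 1-based positions 101..200 are inside; 100 and 201 are not
  counts <- tibble::tibble(chrom = "chr1", pos = c(100L, 101L, 200L, 201L),
                           n_o = 1L, n_c = 1L, n_other = 0L)
  pooled <- pool_gene_counts(counts, genes)
  expect_equal(pooled$n_sites, 2L)
})

test_that("sites overlapping more than one gene are excluded from pooling", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(0L, 50L), end = c(100L, 150L),
                          strand = "+")
  counts <- tibble::tibble(chrom = "chr1", pos = c(60L, 120L),
                           n_o = c(10L, 4L), n_c = c(0L, 6L), n_other = 0L)
  expect_message(pooled <- pool_gene_counts(counts, genes), "excluded")
  expect_equal(pooled$gene_id, "g2")  # only the unambiguous site pooled
  expect_equal(pooled$n_o, 4L)
  expect_error(pool_gene_counts(counts, genes[0, ]),
               class = "chimerase_config_error")
})

test_that("pooled counts on simulated data equal the simulator truth sums", {
  sim <- simulate_chimera(sim_config(seed = 71, n_genes = 200,
                                     frac_l1_specific = 0.1,
                                     frac_l2l3_specific = 0.1))
  sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
  counts <- count_alleles(sim$chimera, sites)
  pooled <- pool_gene_counts(counts, sim$genes)
  truth <- sim$truth$sites |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(n_o = sum(n_o), n_c = sum(n_c), .groups = "drop")
  joined <- dplyr::inner_join(pooled, truth, by = "gene_id",
                              suffix = c("_obs", "_truth"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$n_o_obs, joined$n_o_truth)
  expect_equal(joined$n_c_obs, joined$n_c_truth)
})

test_that("pct_expression_l1 normalises f_o by the tissue L1 fraction with a cap", {
  gs <- tibble::tibble(f_o = c(0.25, 0, 0.5, NA))
  out <- pct_expression_l1(gs, tissue_l1_fraction = 0.25)
  expect_equal(out$pct_l1, c(100, 0, 100, NA))  # equal, zero, capped, missing
  half <- pct_expression_l1(tibble::tibble(f_o = 0.2), 0.4)
  expect_equal(half$pct_l1, 50)
  expect_error(pct_expression_l1(gs, 0), class = "chimerase_estimation_error")
})

test_that("pct_l1 is monotone in f_o and antitone in the tissue fraction until the cap", {
  f <- seq(0, 1, by = 0.05)
  p1 <- pct_expression_l1(tibble::tibble(f_o = f), 0.5)$pct_l1
  expect_true(all(diff(p1) >= 0))
  fracs <- c(0.2, 0.4, 0.6, 0.8, 1)
  p2 <- vapply(fracs,
               function(x) pct_expression_l1(tibble::tibble(f_o = 0.15), x)$pct_l1,
               numeric(1))
  expect_true(all(diff(p2) <= 0))
})

test_that("classify_gene_layer applies the frequency and depth thresholds", {
  gs <- tibble::tibble(
    n_o = c(50L, 30L, 0L, 5L, 96L),
    n_c = c(0L, 30L, 40L, 5L, 4L)
  )
  gs$f_o <- ifelse(gs$n_o + gs$n_c > 0, gs$n_o / (gs$n_o + gs$n_c), NA)
  out <- classify_gene_layer(gs)
  expect_equal(out$layer_class,
               c("L1_SPECIFIC", "SHARED", "L2L3_SPECIFIC",
                 "UNCLASSIFIED",  # 10 reads < min_reads
                 "L1_SPECIFIC")) # f_o = 0.96 >= 0.95
  expect_error(classify_gene_layer(gs, hi = 0.4, lo = 0.5),
               class = "chimerase_config_error")
})

test_that("gene layer classes partition the genes and swap with the donors", {
  sim <- simulate_chimera(sim_config(seed = 81, n_genes = 150, p_l1 = 0.25,
                                     frac_l1_specific = 0.1,
                                     frac_l2l3_specific = 0.1))
  sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
  counts <- count_alleles(sim$chimera, sites)
  stats <- gene_layer_stats(counts, sim$genes, tissue_l1_fraction = 0.25)
  expect_equal(nrow(stats), length(unique(sim$truth$sites$gene_id)))
  expect_true(all(stats$layer_class %in%
                    c("L1_SPECIFIC", "L2L3_SPECIFIC", "SHARED", "UNCLASSIFIED")))
  expect_true(all(stats$pct_l1 >= 0 & stats$pct_l1 <= 100, na.rm = TRUE))

  swapped <- dplyr::rename(counts, n_o = "n_c", n_c = "n_o")
  sw_stats <- gene_layer_stats(swapped, sim$genes, tissue_l1_fraction = 0.75)
  tab <- table(factor(stats$layer_class,
                      c("L1_SPECIFIC", "L2L3_SPECIFIC", "SHARED", "UNCLASSIFIED")))
  sw_tab <- table(factor(sw_stats$layer_class,
                         c("L2L3_SPECIFIC", "L1_SPECIFIC", "SHARED", "UNCLASSIFIED")))
  expect_equal(as.integer(tab), as.integer(sw_tab))
})

test_that("infer_structure resolves the periclinal arrangement from markers", {
  calls <- tibble::tibble(gene_id = c("PDF1", "SYS"),
                          known_layer = c("L1", "L2L3"),
                          category = c("O_ONLY", "C_ONLY"))
  res <- infer_structure(calls)
  expect_equal(res$arrangement, "PERICLINAL")
  expect_equal(res$l1_donor, "O")
  expect_equal(res$l2l3_donor, "C")

  conflicting <- calls
  conflicting$category <- c("C_ONLY", "C_ONLY")
  expect_equal(infer_structure(conflicting)$arrangement, "INCONSISTENT")

  uninf <- calls
  uninf$category <- c("UNINFORMATIVE", "C_ONLY")
  expect_equal(infer_structure(uninf)$arrangement, "UNDETERMINED")

  both <- calls
  both$category <- c("BOTH", "C_ONLY")
  expect_equal(infer_structure(both)$arrangement, "INCONSISTENT")

  expect_error(infer_structure(calls[calls$known_layer == "L1", ]),
               class = "chimerase_config_error")
})

test_that("call_marker_origins pools marker sites and applies the origin rules", {
  sim <- simulate_chimera(sim_config(seed = 91, n_genes = 30, p_l1 = 0.25))
  sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
  counts <- count_alleles(sim$chimera, sites)
  mc <- call_marker_origins(counts, sim$genes, sim$markers)
  expect_equal(mc$gene_id, c("PDF1", "SYS"))
  expect_equal(mc$category, c("O_ONLY", "C_ONLY"))
  bad <- tibble::tibble(gene_id = "PDF1", known_layer = "L4")
  expect_error(call_marker_origins(counts, sim$genes, bad),
               class = "chimerase_config_error")
})
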