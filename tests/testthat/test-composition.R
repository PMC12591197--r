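test_that("site_share counts C-resolving sites with fractional BOTH contributions", {
  calls <- tibble::tibble(
    category = c("C_ONLY", "C_ONLY", "C_ONLY", "O_ONLY"),
    f_o = c(0, 0, 0, 1)
  )
  expect_equal(estimate_site_share(calls)$p_c, 0.75)

  one_both <- tibble::tibble(category = "BOTH", f_o = 0.5)
  expect_equal(estimate_site_share(one_both)$p_c, 0.5)

  with_uninf <- dplyr::bind_rows(
    calls, tibble::tibble(category = "UNINFORMATIVE", f_o = NA_real_))
  est <- estimate_site_share(with_uninf)
  expect_equal(est$p_c, 0.75)  # UNINFORMATIVE excluded
  expect_equal(est$n_sites_used, 4L)
})

test_that("site_share on mixed calls equals a hand enumeration over the list", {
  calls <- mixed_calls_fixture()
  est <- estimate_site_share(calls)
  # enumeration oracle: loop over every call and accumulate
  num <- 0; den <- 0
  for (i in seq_len(nrow(calls))) {
    cat_i <- calls$category[i]
    if (cat_i == "UNINFORMATIVE") next
    den <- den + 1
    num <- num + switch(cat_i, C_ONLY = 1, O_ONLY = 0, BOTH = 1 - calls$f_o[i])
  }
  expect_equal(est$p_c, num / den)
  expect_equal(est$n_sites_used, den)
})

test_that("read_fraction is the pooled donor-C read fraction", {
  all_c <- tibble::tibble(n_o = c(0L, 0L), n_c = c(10L, 25L))
  expect_equal(estimate_read_fraction(all_c)$p_c, 1)
  even <- tibble::tibble(n_o = 10L, n_c = 10L)
  expect_equal(estimate_read_fraction(even)$p_c, 0.5)
  three <- tibble::tibble(n_o = c(9L, 8L, 10L), n_c = c(1L, 2L, 0L))
  expect_equal(estimate_read_fraction(three)$p_c, 0.1)
})

test_that("estimators raise explicit estimation errors on empty evidence", {
  no_inf <- tibble::tibble(category = "UNINFORMATIVE", f_o = NA_real_)
  expect_error(estimate_site_share(no_inf),
               class = "chimerase_estimation_error")
  zero <- tibble::tibble(n_o = 0L, n_c = 0L)
  expect_error(estimate_read_fraction(zero),
               class = "chimerase_estimation_error")
  expect_error(estimate_binomial_mle(zero),
               class = "chimerase_estimation_error")
  expect_error(estimate_binomial_mle(tibble::tibble(n_o = 1L, n_c = 1L),
                                     epsilon = 0.6),
               class = "chimerase_config_error")
})

test_that("binomial MLE at epsilon = 0 is exactly the pooled allele fraction", {
  counts <- tibble::tibble(n_o = c(1L, 2L, 0L), n_c = c(9L, 8L, 10L))
  est <- estimate_binomial_mle(counts, epsilon = 0)
  expect_identical(est$p_c, 27 / 30)
  # epsilon-consistency with the read-fraction estimator
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- rpois(40, 30)
      nc <- rbinom(40, n, runif(1))
    })
    cts <- tibble::tibble(n_o = n - nc, n_c = nc)
    expect_equal(estimate_binomial_mle(cts, 0)$p_c,
                 estimate_read_fraction(cts)$p_c, tolerance = 1e-9)
  }
})

test_that("binomial MLE matches an independent grid-search oracle", {
  counts <- tibble::tibble(n_o = c(1L, 2L, 0L), n_c = c(9L, 8L, 10L))
  est <- estimate_binomial_mle(counts, epsilon = 0.05)
  oracle <- oracle_mle_grid(counts, 0.05, n_grid = 1e5)
  expect_equal(est$p_c, oracle, tolerance = 1e-4)
  # likelihood sanity: reported maximum dominates a coarse grid
  grid <- seq(0, 1, by = 0.001)
  q <- grid * 0.95 + (1 - grid) * 0.05
  ll <- vapply(q, function(qi) sum(dbinom(counts$n_c, counts$n_o + counts$n_c,
                                          qi, log = TRUE)), numeric(1))
  expect_gte(est$loglik, max(ll) - 1e-9)
})

test_that("symmetric counts give p_c = 1/2 for any epsilon", {
  counts <- tibble::tibble(n_o = c(10L, 25L, 7L), n_c = c(10L, 25L, 7L))
  for (eps in c(0, 0.005, 0.1, 0.3)) {
    expect_equal(estimate_binomial_mle(counts, eps)$p_c, 0.5,
                 tolerance = 1e-7)
  }
})

test_that("bootstrap intervals are reproducible from the seed and degenerate fixtures collapse", {
  counts <- tibble::tibble(chrom = "chr1", pos = 1:12 * 10L,
                           n_o = rep(c(9L, 2L, 30L), 4),
                           n_c = rep(c(1L, 20L, 15L), 4), n_other = 0L)
  a <- bootstrap_ci(counts, "read_fraction", b = 200, seed = 7)
  b <- bootstrap_ci(counts, "read_fraction", b = 200, seed = 7)
  expect_identical(a, b)
  c_ <- bootstrap_ci(counts, "read_fraction", b = 200, seed = 8)
  expect_false(identical(a$ci_low, c_$ci_low))

  same <- tibble::tibble(chrom = "chr1", pos = 1:5 * 10L,
                         n_o = 0L, n_c = 50L, n_other = 0L)
  ci <- bootstrap_ci(same, "read_fraction", b = 50, seed = 1)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))

  expect_error(bootstrap_ci(counts, "read_fraction", b = 0),
               class = "chimerase_config_error")
  expect_error(bootstrap_ci(counts[1, ], "read_fraction", b = 10),
               class = "chimerase_estimation_error")
})

test_that("bootstrap percentiles approach the exact n = 3 resampling distribution", {
  counts <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                           n_o = c(9L, 5L, 0L), n_c = c(1L, 5L, 10L),
                           n_other = 0L)
  # full enumeration oracle: all 27 equally likely ordered resamples
  idx <- expand.grid(1:3, 1:3, 1:3)
  exact <- apply(idx, 1, function(ix) {
    d <- counts[unlist(ix), ]
    sum(d$n_c) / sum(d$n_o + d$n_c)
  })
  # discrete-distribution quantiles: each of the 27 outcomes has mass
  # 1/27 > 2.5%, so the interval endpoints are the extreme attainable
  # estimator values themselves
  exact_ci <- unname(quantile(exact, c(0.025, 0.975), type = 1))
  ci <- bootstrap_ci(counts, "read_fraction", b = 4000, seed = 5)
  # endpoints must be attainable estimator values near the exact bounds
  expect_true(all(c(ci$ci_low, ci$ci_high) >= min(exact) - 1e-12))
  expect_true(all(c(ci$ci_low, ci$ci_high) <= max(exact) + 1e-12))
  expect_equal(ci$ci_low, exact_ci[1], tolerance = 0.05)
  expect_equal(ci$ci_high, exact_ci[2], tolerance = 0.05)
})

test_that("degenerate resamples are redrawn and counted", {
  counts <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                           n_o = c(5L, 0L), n_c = c(15L, 0L), n_other = 0L)
  ci <- suppressMessages(
    bootstrap_ci(counts, "read_fraction", b = 300, seed = 2))
  # resamples drawing the uncovered site twice must have been redrawn
  expect_gt(ci$n_redrawn, 0)
  expect_true(ci$ci_low >= 0 && ci$ci_high <= 1)
})

test_that("relabeling donors maps every estimator's p_c to 1 - p_c", {
  sim <- simulate_chimera(sim_config(seed = 51, n_genes = 60, p_l1 = 0.3))
  sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
  counts <- count_alleles(sim$chimera, sites)
  swapped <- dplyr::rename(counts, n_o = "n_c", n_c = "n_o")
  expect_equal(estimate_read_fraction(swapped)$p_c,
               1 - estimate_read_fraction(counts)$p_c, tolerance = 1e-12)
  expect_equal(estimate_binomial_mle(swapped, 0.01)$p_c,
               1 - estimate_binomial_mle(counts, 0.01)$p_c, tolerance = 1e-7)
  expect_equal(estimate_site_share(classify_sites(swapped))$p_c,
               1 - estimate_site_share(classify_sites(counts))$p_c,
               tolerance = 1e-12)
})

test_that("estimate_composition reports all methods tidily with optional intervals", {
  sim <- simulate_chimera(sim_config(seed = 61, n_genes = 40, p_l1 = 0.25))
  sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
  counts <- count_alleles(sim$chimera, sites)
  res <- estimate_composition(counts, boot_b = 100, seed = 9)
  expect_equal(res$method, c("site_share", "read_fraction", "binomial_mle"))
  expect_true(all(res$p_c >= 0 & res$p_c <= 1))
  expect_equal(res$p_o + res$p_c, rep(1, 3))
  expect_true(all(res$ci_low <= res$p_c & res$p_c <= res$ci_high))
})

test_that("tidy, glance and autoplot work on composition estimates", {
  counts <- tibble::tibble(n_o = c(5L, 2L), n_c = c(15L, 18L))
  est <- estimate_binomial_mle(counts, epsilon = 0.01)
  td <- tidy(est)
  expect_equal(td$method, "binomial_mle")
  expect_equal(td$p_o, 1 - td$p_c)
  gl <- glance(est)
  expect_true(is.finite(gl$loglik))
  expect_equal(gl$epsilon, 0.01)
  expect_s3_class(autoplot(est), "ggplot")
  expect_output(print(est), "binomial_mle")
})
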