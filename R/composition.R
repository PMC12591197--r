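# Tissue-level donor mixture estimation.  The quantity of interest is
# p_c, the fraction of a tissue's informative transcript pool contributed
# by donor C (the L2/L3 layers); p_o = 1 - p_c is the L1 (donor O)
# contribution.  Three estimators are provided because published chimera
# proportions do not always say whether they are SNP-count shares or
# read-weighted fractions:
#
#   site_share    - share of informative sites resolving to donor C, with
#                   BOTH sites contributing fractionally (1 - f_o)
#   read_fraction - pooled donor-C read fraction over all sites
#   binomial_mle  - maximum likelihood under n_c ~ Binomial(n, q(p)) with
#                   q(p) = p(1 - eps) + (1 - p) eps, correcting the read
#                   fraction for the allele-miscall rate eps

new_composition_estimate <- function(p_c, method, n_sites_used,
                                     ci_low = NA_real_, ci_high = NA_real_,
                                     loglik = NA_real_, epsilon = NA_real_,
                                     boot = NULL) {
  structure(
    list(p_c = p_c, p_o = 1 - p_c, method = method,
         n_sites_used = n_sites_used, ci_low = ci_low, ci_high = ci_high,
         loglik = loglik, epsilon = epsilon, boot = boot),
    class = "composition_estimate"
  )
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat(sprintf("<composition_estimate: %s>\n", x$method))
  cat(sprintf("  p_C (donor C / L2,L3) = %.4f   p_O (donor O / L1) = %.4f\n",
              x$p_c, x$p_o))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap CI [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  }
  cat(sprintf("  sites used: %d", x$n_sites_used))
  if (!is.na(x$loglik)) cat(sprintf("   log-likelihood: %.3f (epsilon = %g)",
                                    x$loglik, x$epsilon))
  cat("\n")
  invisible(x)
}

#' Estimate donor composition as a share of informative sites
#'
#' The donor-C proportion is the fraction of informative sites (`O_ONLY`,
#' `C_ONLY`, `BOTH`) resolving to donor C, with `BOTH` sites contributing
#' their donor-C read fraction `1 - f_o` rather than a flat half, so
#' deeply covered shared sites inform the estimate.  `UNINFORMATIVE`
#' sites are excluded.
#'
#' @param calls Classified origin calls from [classify_sites()].
#' @return A `composition_estimate` object (see [tidy.composition_estimate()]).
#' @export
estimate_site_share <- function(calls) {
  check_columns(calls, c("category", "f_o"), "calls")
  informative <- calls$category %in% c("O_ONLY", "C_ONLY", "BOTH")
  n_inf <- sum(informative)
  if (n_inf == 0) {
    estimation_error("No informative sites: every call is UNINFORMATIVE.")
  }
  contrib <- sum(calls$category == "C_ONLY") +
    sum(1 - calls$f_o[calls$category == "BOTH"])
  new_composition_estimate(contrib / n_inf, "site_share", n_inf)
}

#' Estimate donor composition as a pooled read fraction
#'
#' The donor-C proportion is the total count of donor-C reads over the
#' total informative reads, pooled across all sites.  Deep sites weigh
#' more; third-allele reads never contribute.
#'
#' @param counts Allele-count tibble from [count_alleles()] (columns
#'   `n_o`, `n_c`).
#' @return A `composition_estimate` object.
#' @export
estimate_read_fraction <- function(counts) {
  check_columns(counts, c("n_o", "n_c"), "counts")
  s_c <- sum(as.numeric(counts$n_c))
  s <- s_c + sum(as.numeric(counts$n_o))
  if (s == 0) {
    estimation_error("No informative reads at any site.")
  }
  new_composition_estimate(s_c / s, "read_fraction",
                           sum(counts$n_o + counts$n_c > 0))
}

#' Error-aware binomial maximum-likelihood mixture estimate
#'
#' Models the donor-C read count at site *i* as
#' \eqn{n_{C,i} \sim \mathrm{Binomial}(n_i, q(p))} with
#' \eqn{q(p) = p(1-\epsilon) + (1-p)\epsilon}, where \eqn{p} is the
#' donor-C fraction of the transcript pool and \eqn{\epsilon} the
#' per-read allele-miscall rate.  The likelihood is maximised over
#' \eqn{p \in [0,1]} by a 1001-point coarse grid followed by bracketed
#' one-dimensional refinement, locating the maximiser to an absolute
#' tolerance well below 1e-6.  At \eqn{\epsilon = 0} the closed-form
#' maximiser \eqn{\hat p = \sum n_C / \sum n} is returned exactly.
#'
#' This model applies to tissues whose diagnostic sites all share the
#' mixture fraction (shared genes); layer-specific genes violate it and
#' should be analysed with [gene_layer_stats()].
#'
#' @param counts Allele-count tibble (columns `n_o`, `n_c`).
#' @param epsilon Allele-miscall rate in `[0, 0.5)`; default 0.005, a
#'   typical short-read substitution error rate.
#' @return A `composition_estimate` with `loglik` (maximised
#'   log-likelihood) and `epsilon` recorded.
#' @examples
#' counts <- tibble::tibble(n_o = c(1L, 2L, 0L), n_c = c(9L, 8L, 10L))
#' estimate_binomial_mle(counts, epsilon = 0)   # pooled fraction 0.9
#' @export
estimate_binomial_mle <- function(counts, epsilon = 0.005) {
  check_columns(counts, c("n_o", "n_c"), "counts")
  check_number(epsilon, "epsilon", min = 0)
  if (epsilon >= 0.5) {
    config_error("`epsilon` must be < 0.5 (got %g): beyond that the allele labels are no longer identifiable.", epsilon)
  }
  n_c <- as.numeric(counts$n_c)
  n <- n_c + as.numeric(counts$n_o)
  keep <- n > 0
  if (!any(keep)) {
    estimation_error("All sites have zero informative depth.")
  }
  n_c <- n_c[keep]
  n <- n[keep]

  # The per-site binomial log-likelihoods share the success probability
  # q(p), so the likelihood factorises through the pooled sufficient
  # statistics S_c = sum(n_c), S = sum(n); the lchoose term is constant
  # in p and computed once.
  s_c <- sum(n_c)
  s <- sum(n)
  const <- sum(lchoose(n, n_c))
  # vectorised over p; the 0 * log(0) cases are dropped analytically
  loglik_p <- function(p) {
    q <- p * (1 - epsilon) + (1 - p) * epsilon
    t_c <- if (s_c > 0) s_c * log(q) else 0
    t_o <- if (s > s_c) (s - s_c) * log1p(-q) else 0
    const + t_c + t_o
  }

  if (epsilon == 0) {
    p_hat <- s_c / s
  } else {
    grid <- seq(0, 1, length.out = 1001)
    ll <- loglik_p(grid)
    i <- which.max(ll)
    lower <- grid[max(i - 1L, 1L)]
    upper <- grid[min(i + 1L, length(grid))]
    opt <- optimize(loglik_p, lower = lower, upper = upper,
                    maximum = TRUE, tol = 1e-9)
    p_hat <- opt$maximum
    # keep grid point if refinement did not improve (flat boundary case)
    if (ll[i] > opt$objective) p_hat <- grid[i]
    p_hat <- min(max(p_hat, 0), 1)
  }

  new_composition_estimate(p_hat, "binomial_mle", sum(keep),
                           loglik = loglik_p(p_hat), epsilon = epsilon)
}

#' Bootstrap percentile confidence interval for a composition estimate
#'
#' Resamples sites with replacement `b` times, re-applies the chosen
#' estimator to each resample, and returns the percentile interval of the
#' resampled estimates.  Degenerate resamples (zero informative reads or
#' sites) are redrawn and the number of redraws reported.  Reproducible
#' given `seed`.
#'
#' @param counts Allele-count tibble from [count_alleles()].
#' @param method One of `"binomial_mle"`, `"read_fraction"`,
#'   `"site_share"`.
#' @param b Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param epsilon Miscall rate passed to the binomial MLE.
#' @param thresholds [origin_thresholds()] used to re-classify each
#'   resample when `method = "site_share"`.
#' @return A tibble `ci_low`, `ci_high`, `method`, `b`, `level`,
#'   `n_redrawn`, `seed`.
#' @export
bootstrap_ci <- function(counts, method = c("binomial_mle", "read_fraction",
                                            "site_share"),
                         b = 1000, level = 0.95, seed = NULL,
                         epsilon = 0.005,
                         thresholds = origin_thresholds()) {
  method <- match.arg(method)
  check_columns(counts, c("n_o", "n_c"), "counts")
  check_number(b, "b", min = 1, integerish = TRUE)
  check_number(level, "level", min = 0, max = 1)
  n_sites <- nrow(counts)
  if (n_sites < 2) {
    estimation_error("Bootstrap needs at least 2 sites, got %d.", n_sites)
  }

  estimator <- switch(
    method,
    binomial_mle = function(d) estimate_binomial_mle(d, epsilon)$p_c,
    read_fraction = function(d) estimate_read_fraction(d)$p_c,
    site_share = function(d) estimate_site_share(classify_sites(d, thresholds))$p_c
  )

  run <- function() {
    reps <- numeric(b)
    redrawn <- 0L
    for (i in seq_len(b)) {
      repeat {
        idx <- sample.int(n_sites, n_sites, replace = TRUE)
        p <- tryCatch(estimator(counts[idx, , drop = FALSE]),
                      chimerase_estimation_error = function(e) NA_real_)
        if (!is.na(p)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * b) {
          estimation_error("Bootstrap cannot find non-degenerate resamples; are nearly all sites uncovered?")
        }
      }
      reps[i] <- p
    }
    list(reps = reps, redrawn = redrawn)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  alpha <- (1 - level) / 2
  ci <- unname(quantile(res$reps, c(alpha, 1 - alpha), type = 7))
  if (res$redrawn > 0) {
    inform(sprintf("bootstrap_ci: %d degenerate resample(s) redrawn.",
                   res$redrawn))
  }
  tibble(ci_low = ci[1], ci_high = ci[2], method = method,
         b = as.integer(b), level = level, n_redrawn = res$redrawn,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Estimate donor composition by all methods
#'
#' Convenience wrapper running [estimate_site_share()],
#' [estimate_read_fraction()] and [estimate_binomial_mle()] on the same
#' classified counts and returning one tidy row per method, optionally
#' with bootstrap confidence intervals.
#'
#' @param counts Allele-count tibble from [count_alleles()].
#' @param thresholds [origin_thresholds()] for classification.
#' @param epsilon Miscall rate for the binomial MLE.
#' @param boot_b Bootstrap replicates per method (0 = no intervals).
#' @param level Confidence level for the intervals.
#' @param seed Seed for the bootstrap.
#' @param methods Which estimators to run.
#' @return A tibble with columns `method`, `p_c`, `p_o`, `ci_low`,
#'   `ci_high`, `n_sites_used`, `loglik`, `epsilon`.
#' @examples
#' sim <- simulate_chimera(sim_config(seed = 7, n_genes = 40, p_l1 = 0.25))
#' sites <- find_diagnostic_sites(sim$donor_o, sim$donor_c)
#' counts <- count_alleles(sim$chimera, sites)
#' estimate_composition(counts)
#' @export
estimate_composition <- function(counts, thresholds = origin_thresholds(),
                                 epsilon = 0.005, boot_b = 0, level = 0.95,
                                 seed = NULL,
                                 methods = c("site_share", "read_fraction",
                                             "binomial_mle")) {
  methods <- match.arg(methods, several.ok = TRUE)
  calls <- classify_sites(counts, thresholds)
  ests <- purrr::map(methods, function(m) {
    est <- switch(m,
      site_share = estimate_site_share(calls),
      read_fraction = estimate_read_fraction(counts),
      binomial_mle = estimate_binomial_mle(counts, epsilon)
    )
    if (boot_b > 0) {
      ci <- bootstrap_ci(counts, method = m, b = boot_b, level = level,
                         seed = seed, epsilon = epsilon,
                         thresholds = thresholds)
      est$ci_low <- ci$ci_low
      est$ci_high <- ci$ci_high
    }
    est
  })
  dplyr::bind_rows(purrr::map(ests, tidy_composition_row))
}

tidy_composition_row <- function(x) {
  tibble(
    method = x$method, p_c = x$p_c, p_o = x$p_o,
    ci_low = x$ci_low, ci_high = x$ci_high,
    n_sites_used = x$n_sites_used, loglik = x$loglik, epsilon = x$epsilon
  )
}
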