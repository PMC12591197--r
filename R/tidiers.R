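# broom-style accessors for fitted composition estimates.

#' Tidy a composition estimate
#'
#' @param x A `composition_estimate` from [estimate_site_share()],
#'   [estimate_read_fraction()] or [estimate_binomial_mle()].
#' @param ... Unused.
#' @return A one-row tibble: `method`, `p_c`, `p_o`, `ci_low`, `ci_high`,
#'   `n_sites_used`.
#' @method tidy composition_estimate
#' @export
tidy.composition_estimate <- function(x, ...) {
  tibble(
    method = x$method, p_c = x$p_c, p_o = x$p_o,
    ci_low = x$ci_low, ci_high = x$ci_high,
    n_sites_used = x$n_sites_used
  )
}

#' Glance at a composition estimate
#'
#' @inheritParams tidy.composition_estimate
#' @return A one-row tibble: `method`, `n_sites_used`, `loglik`,
#'   `epsilon`.
#' @method glance composition_estimate
#' @export
glance.composition_estimate <- function(x, ...) {
  tibble(
    method = x$method, n_sites_used = x$n_sites_used,
    loglik = x$loglik, epsilon = x$epsilon
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
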