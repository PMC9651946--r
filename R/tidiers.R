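#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a saccade group comparison
#'
#' One row per test (Wilcoxon rank sum, Welch t) with statistic and
#' p-value.
#'
#' @param x A `saccade_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble with columns `metric`, `test`, `statistic`, `p_value`.
#' @method tidy saccade_comparison
#' @export
tidy.saccade_comparison <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    test = c("wilcoxon_rank_sum", "t_test"),
    statistic = c(unname(x$wilcoxon$statistic), unname(x$t_test$statistic)),
    p_value = c(x$wilcoxon$p.value, x$t_test$p.value))
}

#' @rdname tidy.saccade_comparison
#' @return For `glance()`: a one-row tibble with `metric`, `median_ratio`,
#'   `n_a`, `n_b`, and both p-values.
#' @method glance saccade_comparison
#' @export
glance.saccade_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, median_ratio = x$median_ratio,
                 n_a = x$n_a, n_b = x$n_b,
                 p_wilcoxon = x$wilcoxon$p.value,
                 p_t_test = x$t_test$p.value)
}

#' Tidy a post-saccade exponential decay fit
#'
#' @param x A `decay_fit` from [fit_decay_tau()].
#' @param ... Unused.
#' @return A one-row tibble with `tau_s`, `theta0_deg`, `theta_inf_deg`,
#'   `r_squared`, `reliable`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(tau_s = x$tau, theta0_deg = x$theta0,
                 theta_inf_deg = x$theta_inf,
                 r_squared = x$r_squared, reliable = x$reliable)
}
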