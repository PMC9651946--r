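#' Detect saccades by velocity threshold with hysteresis
#'
#' Events are seeded where the absolute angular velocity (centered finite
#' differences) crosses `vel_threshold` and extended in both directions
#' until it falls below `hysteresis * vel_threshold`. Events separated by
#' less than `min_interval` are merged. Amplitude is the displacement from
#' onset to offset; peak velocity is the largest absolute velocity within
#' the event.
#'
#' @param data Tibble with `time_s` and one angle column (deg).
#' @param vel_threshold Detection threshold (deg/s), default 100 for head
#'   saccades.
#' @param min_interval Minimum separation between events (s); closer events
#'   are merged.
#' @param hysteresis Fraction of `vel_threshold` at which the event
#'   boundaries are placed (default 0.25).
#' @param value Optional column name.
#' @return Tibble of class `saccade_tbl`: `onset_s`, `offset_s`,
#'   `duration_s`, `amplitude_deg`, `peak_velocity_dps`, `direction`.
#' @export
detect_saccades <- function(data, vel_threshold = 100, min_interval = 0.1,
                            hysteresis = 0.25, value = NULL) {
  if (vel_threshold <= 0) rlang::abort("`vel_threshold` must be positive.")
  sr <- infer_sample_rate(data)
  col <- if (is.null(value)) first_value_col(data) else value
  x <- data[[col]]
  vel <- fd_velocity(x, sr)
  noise_sd <- stats::mad(vel)
  if (vel_threshold < 3 * noise_sd) {
    rlang::warn(sprintf(
      "vel_threshold (%g deg/s) is below 3x the velocity-noise SD (%g deg/s); expect false positives.",
      vel_threshold, noise_sd))
  }
  above <- abs(vel) > vel_threshold
  if (!any(above)) return(empty_saccade_tbl())
  low <- abs(vel) > hysteresis * vel_threshold
  # contiguous runs above the hysteresis level that contain a threshold crossing
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(r$values), function(i) {
    r$values[i] && any(above[starts[i]:ends[i]])
  }, logical(1))
  on <- starts[keep]; off <- ends[keep]
  # merge events closer than min_interval
  if (length(on) > 1L) {
    gap <- (on[-1] - off[-length(off)]) / sr
    merge <- gap < min_interval
    keep_idx <- which(!c(FALSE, merge))
    grp <- cumsum(!c(FALSE, merge))
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  t <- data$time_s
  ev <- lapply(seq_along(on), function(i) {
    seg <- on[i]:off[i]
    ipk <- seg[which.max(abs(vel[seg]))]
    amp <- x[off[i]] - x[on[i]]
    tibble::tibble(
      onset_s = t[on[i]], offset_s = t[off[i]],
      duration_s = t[off[i]] - t[on[i]],
      amplitude_deg = abs(amp),
      peak_velocity_dps = abs(vel[ipk]),
      direction = sign(vel[ipk]))
  })
  out <- dplyr::bind_rows(ev)
  class(out) <- c("saccade_tbl", class(out))
  out
}

empty_saccade_tbl <- function() {
  out <- tibble::tibble(onset_s = numeric(0), offset_s = numeric(0),
                        duration_s = numeric(0), amplitude_deg = numeric(0),
                        peak_velocity_dps = numeric(0), direction = numeric(0))
  class(out) <- c("saccade_tbl", class(out))
  out
}

#' Fit the post-saccade damping time constant
#'
#' Nonlinear least squares of `theta(t) = theta0 * exp(-t/tau) + theta_inf`
#' on a window starting at the event offset, with a log-linear
#' initialization. Fits with R-squared below 0.5 (or a degenerate,
#' non-decaying window) are marked unreliable.
#'
#' @param data Tibble with `time_s` and the angle column used for detection.
#' @param event One row of a `saccade_tbl` (list or single-row tibble with
#'   `offset_s`).
#' @param window Fit window length after the offset (s), default 1.
#' @param value Optional column name.
#' @return List with `tau` (s), `r_squared`, `reliable` (logical), and the
#'   fitted `theta0`, `theta_inf`.
#' @export
fit_decay_tau <- function(data, event, window = 1, value = NULL) {
  sr <- infer_sample_rate(data)
  col <- if (is.null(value)) first_value_col(data) else value
  t0 <- event$offset_s
  idx <- which(data$time_s >= t0 & data$time_s <= t0 + window)
  if (!length(idx) || max(data$time_s) < t0 + window - 1 / sr) {
    rlang::abort("fit window is truncated by the end of the trial.")
  }
  tt <- data$time_s[idx] - t0
  y <- data[[col]][idx]
  unreliable <- function() list(tau = NA_real_, r_squared = NA_real_,
                                reliable = FALSE, theta0 = NA_real_,
                                theta_inf = NA_real_)
  if (stats::sd(y) < .Machine$double.eps^0.5) return(unreliable())
  # log-linear initialization on the de-offset magnitude
  y_inf0 <- mean(utils::tail(y, max(3L, length(y) %/% 10L)))
  z <- y - y_inf0
  s0 <- sign(z[1])
  if (s0 == 0) s0 <- 1
  pos <- which(s0 * z > .Machine$double.eps^0.5)
  tau0 <- if (length(pos) >= 3L) {
    cf <- stats::lm.fit(cbind(1, tt[pos]), log(s0 * z[pos]))$coefficients
    if (is.finite(cf[[2]]) && cf[[2]] < 0) -1 / cf[[2]] else window / 3
  } else window / 3
  tau0 <- min(max(tau0, 0.01), 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ theta0 * exp(-tt / tau) + theta_inf,
      start = list(theta0 = z[1], tau = tau0, theta_inf = y_inf0),
      lower = c(-Inf, 1e-4, -Inf), upper = c(Inf, 100, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unreliable())
  cf <- stats::coef(fit)
  resid <- y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  out <- list(tau = unname(cf[["tau"]]), r_squared = r2,
              reliable = is.finite(r2) && r2 >= 0.5,
              theta0 = unname(cf[["theta0"]]),
              theta_inf = unname(cf[["theta_inf"]]))
  class(out) <- "decay_fit"
  out
}

#' Detect saccades and fit damping constants across a set of trials
#'
#' Convenience wrapper: runs [detect_saccades()] on every trial, then
#' [fit_decay_tau()] on each event whose fit window fits inside the trial
#' and contains no other event.
#'
#' @param trials List of tibbles (`time_s` + angle column).
#' @param vel_threshold,min_interval,hysteresis Passed to
#'   [detect_saccades()].
#' @param window Passed to [fit_decay_tau()].
#' @return A `saccade_tbl` with added columns `trial`, `tau_s`, `r2`.
#' @export
analyze_saccade_trials <- function(trials, vel_threshold = 100,
                                   min_interval = 0.1, hysteresis = 0.25,
                                   window = 1) {
  out <- purrr::imap(trials, function(tr, k) {
    ev <- detect_saccades(tr, vel_threshold, min_interval, hysteresis)
    if (!nrow(ev)) return(NULL)
    ev$trial <- as.integer(k)
    ev$tau_s <- NA_real_
    ev$r2 <- NA_real_
    for (i in seq_len(nrow(ev))) {
      # skip events whose window is truncated or contains the next event
      if (ev$offset_s[i] + window > max(tr$time_s)) next
      if (i < nrow(ev) && ev$onset_s[i + 1] < ev$offset_s[i] + window) next
      fit <- tryCatch(fit_decay_tau(tr, ev[i, ], window = window),
                      error = function(e) NULL)
      if (!is.null(fit) && isTRUE(fit$reliable)) {
        ev$tau_s[i] <- fit$tau
        ev$r2[i] <- fit$r_squared
      }
    }
    ev
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty_saccade_tbl())
  class(res) <- c("saccade_tbl", class(res))
  res
}

#' Summary statistics of saccade kinematics
#'
#' Count, mean, median, and SD for each kinematic metric, pooled over all
#' events and (when a `fly_id` column is present) also per animal with the
#' per-animal means then averaged.
#'
#' @param events A `saccade_tbl` (optionally with a `fly_id` column).
#' @return Tibble with columns `metric`, `level` (`"pooled"` or
#'   `"per_fly"`), `n`, `mean`, `median`, `sd`.
#' @export
saccade_population_stats <- function(events) {
  if (!nrow(events)) rlang::abort("no events to summarize.")
  metrics <- intersect(c("amplitude_deg", "peak_velocity_dps",
                         "duration_s", "tau_s"), names(events))
  pooled <- purrr::map_dfr(metrics, function(m) {
    v <- events[[m]][is.finite(events[[m]])]
    tibble::tibble(metric = m, level = "pooled", n = length(v),
                   mean = mean(v), median = stats::median(v),
                   sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  if (!"fly_id" %in% names(events)) return(pooled)
  per_fly <- purrr::map_dfr(metrics, function(m) {
    mm <- tapply(events[[m]], events$fly_id,
                 function(v) mean(v[is.finite(v)], na.rm = TRUE))
    mm <- mm[is.finite(mm)]
    tibble::tibble(metric = m, level = "per_fly", n = length(mm),
                   mean = mean(mm), median = stats::median(mm),
                   sd = if (length(mm) > 1) stats::sd(mm) else 0)
  })
  dplyr::bind_rows(pooled, per_fly)
}

#' Compare a saccade metric between two groups
#'
#' Two-sided Wilcoxon rank-sum and Welch two-sample t-test on the chosen
#' metric, plus the ratio of group medians (a robust effect size for
#' strongly skewed quantities such as the damping time constant).
#'
#' @param group_a,group_b `saccade_tbl`s.
#' @param metric Column name to compare (e.g. `"tau_s"`).
#' @return Object of class `saccade_comparison`: a list with `metric`,
#'   `wilcoxon` and `t_test` (both `htest`), `median_ratio`
#'   (median(a)/median(b)), `n_a`, `n_b`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
compare_groups <- function(group_a, group_b, metric) {
  for (g in list(group_a, group_b)) {
    if (!nrow(g)) rlang::abort("both groups must be non-empty.")
    if (!metric %in% names(g)) {
      rlang::abort(sprintf("metric '%s' is absent from the events.", metric))
    }
  }
  a <- group_a[[metric]][is.finite(group_a[[metric]])]
  b <- group_b[[metric]][is.finite(group_b[[metric]])]
  if (!length(a) || !length(b)) {
    rlang::abort(sprintf("metric '%s' has no finite values in one group.", metric))
  }
  structure(
    list(metric = metric,
         wilcoxon = stats::wilcox.test(a, b, exact = FALSE),
         t_test = stats::t.test(a, b),
         median_ratio = stats::median(a) / stats::median(b),
         n_a = length(a), n_b = length(b)),
    class = "saccade_comparison")
}

#' @export
print.saccade_comparison <- function(x, ...) {
  cat("<saccade_comparison>", x$metric, " n =", x$n_a, "vs", x$n_b, "\n")
  cat("  Wilcoxon rank sum p =", format.pval(x$wilcoxon$p.value), "\n")
  cat("  Welch t-test p =", format.pval(x$t_test$p.value), "\n")
  cat("  median ratio (a/b) =", signif(x$median_ratio, 4), "\n")
  invisible(x)
}

#' Compare variances of two displacement samples
#'
#' Two-sided F-test on the variances of pooled angular-displacement samples
#' (e.g. the distribution of head excursions under two feedback
#' conditions).
#'
#' @param displacements_a,displacements_b Numeric vectors (deg).
#' @return The `htest` from [stats::var.test()].
#' @export
compare_variances <- function(displacements_a, displacements_b) {
  if (!length(displacements_a) || !length(displacements_b)) {
    rlang::abort("both samples must be non-empty.")
  }
  if (stats::var(displacements_a) == 0 || stats::var(displacements_b) == 0) {
    rlang::abort("zero variance in one of the samples.")
  }
  stats::var.test(displacements_a, displacements_b)
}
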