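#' Bode-style plot of a frequency-response function
#'
#' Gain, phase, and (when present) compensation error against frequency on
#' a log axis, with ribbons for across-animal dispersion when the table
#' carries `gain_sd` / `phase_sd_deg` columns.
#'
#' @param object A `fly_frf` tibble.
#' @param stim_only Plot only stimulus-frequency rows (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fly_frf
#' @export
autoplot.fly_frf <- function(object, stim_only = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (stim_only && "is_stim" %in% names(df) && any(df$is_stim)) {
    df <- df[df$is_stim, ]
  }
  long <- dplyr::bind_rows(
    tibble::tibble(freq_hz = df$freq_hz, panel = "gain", value = df$gain,
                   sd = if ("gain_sd" %in% names(df)) df$gain_sd else NA_real_),
    tibble::tibble(freq_hz = df$freq_hz, panel = "phase (deg)",
                   value = df$phase_deg,
                   sd = if ("phase_sd_deg" %in% names(df)) df$phase_sd_deg else NA_real_),
    if ("comp_err" %in% names(df)) {
      tibble::tibble(freq_hz = df$freq_hz, panel = "compensation error",
                     value = df$comp_err,
                     sd = if ("comp_err_sd" %in% names(df)) df$comp_err_sd else NA_real_)
    })
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL) +
    ggplot2::theme_minimal()
  if (any(is.finite(long$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      alpha = 0.2, colour = NA)
  }
  p
}

#' Plot the angle traces of a trial
#'
#' @param trial A `fly_trial` tibble.
#' @param cols Which angle columns to draw.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, cols = c("stimulus_deg", "body_deg", "head_deg")) {
  cols <- intersect(cols, names(trial))
  long <- tidyr::pivot_longer(tibble::as_tibble(trial)[, c("time_s", cols)],
                              -"time_s", names_to = "signal",
                              values_to = "angle_deg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$angle_deg,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Histograms of saccade kinematics
#'
#' @param object A `saccade_tbl`.
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @method autoplot saccade_tbl
#' @export
autoplot.saccade_tbl <- function(object, ...) {
  metrics <- intersect(c("amplitude_deg", "peak_velocity_dps",
                         "duration_s", "tau_s"), names(object))
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, metrics],
                              dplyr::everything(),
                              names_to = "metric", values_to = "value")
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}
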