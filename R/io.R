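#' Trial files: CSV with a JSON sidecar
#'
#' A trial is stored as a CSV with columns `time_s, stimulus_deg, body_deg,
#' head_deg` (values written with 15 significant digits, so a write/read
#' round trip is lossless well beyond 9 digits) plus an optional JSON
#' sidecar of the same basename carrying the perturbation spec, the
#' simulation config, and — for synthetic trials — the generating loop
#' components in zero-pole-gain + delay form.
#'
#' @name trial_io
NULL

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a trial to disk
#'
#' @param trial A `fly_trial` tibble (see [simulate_trial()]) or any tibble
#'   with `time_s`, `stimulus_deg`, `head_deg` and optionally `body_deg`.
#' @param path Output CSV path; the JSON sidecar goes next to it.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  cols <- intersect(c("time_s", "stimulus_deg", "body_deg", "head_deg"),
                    names(trial))
  df <- as.data.frame(trial)[, cols]
  df[] <- lapply(df, function(v) format(v, digits = 15, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list()
  spec <- attr(trial, "spec")
  if (!is.null(spec)) {
    side$spec <- list(kind = spec$kind, frequencies_hz = spec$frequencies,
                      amplitudes_deg = spec$amplitudes,
                      phases_rad = spec$phases, v_norm = spec$v_norm,
                      duration_s = spec$duration,
                      sample_rate_hz = spec$sample_rate, seed = spec$seed)
  }
  config <- attr(trial, "config")
  if (!is.null(config)) side$config <- unclass(config)
  truth <- attr(trial, "truth")
  if (!is.null(truth)) {
    side$truth <- lapply(unclass(truth), tf_to_list)
  }
  if (length(side)) {
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trial from disk
#'
#' Enforces a uniform, monotone time base (tolerance 1e-6 s). Runs of
#' missing values shorter than 0.1 s are linearly interpolated (with a
#' message reporting the count); longer gaps are rejected. A file without a
#' `body_deg` column parses as a body-fixed trial with zero body angle.
#'
#' @param path CSV path written by [write_trial()] (sidecar optional).
#' @return A `fly_trial` tibble.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "head_deg") %in% names(df))) {
    rlang::abort("trial CSV needs at least `time_s` and `head_deg` columns.")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6)) {
    rlang::abort("`time_s` is not uniformly increasing (tolerance 1e-6 s).")
  }
  sr <- 1 / dt[1]
  max_gap <- as.integer(ceiling(0.1 * sr))
  n_interp <- 0L
  for (col in setdiff(names(df), "time_s")) {
    bad <- !is.finite(df[[col]])
    if (!any(bad)) next
    r <- rle(bad)
    if (any(r$values & r$lengths > max_gap)) {
      rlang::abort(sprintf("column '%s' has a missing-value run longer than 0.1 s.", col))
    }
    n_interp <- n_interp + sum(bad)
    df[[col]] <- stats::approx(df$time_s[!bad], df[[col]][!bad],
                               xout = df$time_s, rule = 2)$y
  }
  if (n_interp > 0) {
    rlang::inform(sprintf("interpolated %d missing sample(s) across gaps < 0.1 s.", n_interp))
  }
  mode <- "body_free"
  if (!"body_deg" %in% names(df)) {
    df$body_deg <- 0
    mode <- "body_fixed"
  }
  if (!"stimulus_deg" %in% names(df)) df$stimulus_deg <- 0
  out <- tibble::as_tibble(df)
  out$error_deg <- out$stimulus_deg - out$head_deg - out$body_deg
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$spec)) attr(out, "spec") <- meta$spec
    if (!is.null(meta$config)) {
      attr(out, "config") <- meta$config
      if (!is.null(meta$config$mode)) mode <- meta$config$mode
    }
    if (!is.null(meta$truth)) {
      attr(out, "truth") <- tryCatch({
        tl <- lapply(meta$truth[c("C_head_V", "C_head_M", "C_body_V",
                                  "C_body_M", "P_head", "P_body")],
                     tf_from_list)
        do.call(loop_components, tl)
      }, error = function(e) meta$truth)
    }
  }
  attr(out, "mode") <- mode
  class(out) <- c("fly_trial", class(out))
  out
}

#' Write a frequency-response table to CSV
#'
#' Columns: `freq_hz, gain, gain_sd, phase_deg, phase_sd_deg, comp_err,
#' comp_err_sd, coherence, n_flies` (missing dispersion columns are written
#' as `NA`).
#'
#' @param fr A `fly_frf` tibble.
#' @param path Output path.
#' @param stim_only Write only the stimulus-frequency rows (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_frf_csv <- function(fr, path, stim_only = TRUE) {
  df <- as.data.frame(fr)
  if (stim_only && "is_stim" %in% names(df)) df <- df[df$is_stim, ]
  pick <- function(col, default = NA_real_) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  eps <- if ("comp_err" %in% names(df)) df$comp_err else Mod((1 + 0i) - df$response)
  out <- data.frame(
    freq_hz = df$freq_hz, gain = df$gain, gain_sd = pick("gain_sd"),
    phase_deg = df$phase_deg, phase_sd_deg = pick("phase_sd_deg"),
    comp_err = eps, comp_err_sd = pick("comp_err_sd"),
    coherence = pick("coherence"),
    n_flies = pick("n_flies", attr(fr, "n_flies") %||% 1L))
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
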