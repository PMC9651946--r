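#' Non-parametric frequency-domain system identification
#'
#' Spectra are evaluated on a fine grid (default 0-50 Hz in 0.05 Hz steps)
#' with a chirp-z transform; frequency-response functions are complex ratios
#' of output to input spectra; dispersion across animals uses circular
#' statistics for phase.
#'
#' @name sysid
NULL

default_grid <- function() seq(0, 50, by = 0.05)

#' Detrend and low-pass filter a signal
#'
#' Removes a least-squares linear trend and applies a zero-phase
#' (forward-backward) 2nd-order Butterworth low-pass at `cutoff` to every
#' non-time column. Zero-phase filtering leaves the timing (phase) of the
#' passband untouched, which matters because phase is a primary output of
#' the identification.
#'
#' @param data Tibble with `time_s` and one or more angle columns (deg).
#' @param cutoff Low-pass cutoff (Hz), default 40.
#' @return Tibble of the same shape.
#' @export
preprocess <- function(data, cutoff = 40) {
  sr <- infer_sample_rate(data)
  if (sr <= 2 * cutoff) {
    rlang::abort(sprintf(
      "sample rate (%g Hz) must exceed twice the %g Hz cutoff.", sr, cutoff))
  }
  if (nrow(data) < sr) rlang::abort("need at least 1 s of data.")
  lp <- signal::butter(2, cutoff / (sr / 2), type = "low")
  out <- data
  for (col in setdiff(names(data), "time_s")) {
    x <- data[[col]]
    trend <- stats::lm.fit(cbind(1, seq_along(x)), x)$fitted.values
    out[[col]] <- as.numeric(signal::filtfilt(lp, x - trend))
  }
  out
}

# Bluestein chirp-z transform: X_k = sum_n x[n] * a^(-n) * w^(n*k),
# k = 0..m-1, computed with three FFTs.
czt_bluestein <- function(x, m, w, a) {
  n <- length(x)
  k2 <- (seq_len(max(n, m)) - 1)^2 / 2
  wk2_n <- w^(k2[seq_len(n)])
  wk2_m <- w^(k2[seq_len(m)])
  y <- x * a^(-(seq_len(n) - 1)) * wk2_n
  L <- 2^ceiling(log2(n + m - 1))
  v <- complex(length.out = L)
  v[seq_len(m)] <- w^(-k2[seq_len(m)])
  if (n > 1) v[L - seq_len(n - 1) + 1] <- w^(-k2[2:n])
  g <- stats::fft(stats::fft(c(y, complex(length.out = L - n))) * stats::fft(v),
                  inverse = TRUE) / L
  g[seq_len(m)] * wk2_m
}

#' Chirp-z spectrum on an arbitrary frequency grid
#'
#' Amplitude-normalized complex spectrum evaluated at
#' `seq(f_lo, f_hi, by = df)` using Bluestein's chirp-z algorithm. The
#' normalization and phase convention are chosen so that a unit-amplitude
#' sine `sin(2 pi f t + phi)` at a grid frequency returns magnitude 1 and
#' phase `phi` at that bin.
#'
#' @param data Tibble with `time_s` and one value column, or a numeric
#'   vector (then `sample_rate` is required).
#' @param f_lo,f_hi,df Grid limits and step (Hz); defaults 0, 50, 0.05.
#' @param value Optional column name.
#' @param sample_rate Required when `data` is a bare numeric vector.
#' @return Tibble with `freq_hz`, `spectrum` (complex), `amplitude`,
#'   `phase_deg`.
#' @examples
#' sp <- czt_spectrum(single_sine(2.1, v_norm = 2.1 * 2 * pi, duration = 20))
#' sp$amplitude[sp$freq_hz == 2.1] # ~ 1
#' @export
czt_spectrum <- function(data, f_lo = 0, f_hi = 50, df = 0.05,
                         value = NULL, sample_rate = NULL) {
  if (df <= 0) rlang::abort("`df` must be positive.")
  if (f_hi <= f_lo) rlang::abort("`f_hi` must exceed `f_lo`.")
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(sample_rate)) {
      rlang::abort("`sample_rate` is required for a bare numeric vector.")
    }
    x <- data; sr <- sample_rate
  } else {
    sr <- infer_sample_rate(data)
    col <- if (is.null(value)) first_value_col(data) else value
    x <- data[[col]]
  }
  n <- length(x)
  m <- as.integer(round((f_hi - f_lo) / df)) + 1L
  a <- exp(2i * pi * f_lo / sr)
  w <- exp(-2i * pi * df / sr)
  raw <- czt_bluestein(as.complex(x), m, w, a)
  spec <- 1i * 2 / n * raw # sine-referenced normalization
  tibble::tibble(
    freq_hz = f_lo + df * (seq_len(m) - 1),
    spectrum = spec,
    amplitude = Mod(spec),
    phase_deg = wrap_deg(Arg(spec) * 180 / pi)
  )
}

wrap_deg <- function(ph) {
  out <- (ph + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

snap_to_grid <- function(freqs, grid, tol = 1e-6) {
  idx <- vapply(freqs, function(f) {
    i <- which.min(abs(grid - f))
    if (abs(grid[i] - f) > tol) {
      rlang::abort(sprintf("frequency %g Hz is not on the analysis grid.", f))
    }
    i
  }, integer(1))
  idx
}

new_frf <- function(freq_hz, response, is_stim, valid, n_flies = 1L) {
  out <- tibble::tibble(
    freq_hz = freq_hz,
    response = response,
    gain = Mod(response),
    phase_deg = wrap_deg(Arg(response) * 180 / pi),
    is_stim = is_stim,
    valid = valid
  )
  attr(out, "n_flies") <- n_flies
  class(out) <- c("fly_frf", class(out))
  out
}

#' Frequency-response function between two signals
#'
#' Divides the chirp-z spectrum of the output by that of the input on the
#' full grid. Values at the stimulus frequencies (`is_stim`) are the ones
#' carried into averages and the decomposition algebra; the rest of the grid
#' is retained for diagnostics. Grid points where the input magnitude falls
#' below `input_floor` are flagged `valid = FALSE` rather than divided.
#'
#' @param input,output Tibbles with `time_s` and one value column each
#'   (typically [preprocess()]ed), equal length and rate.
#' @param stim_freqs Stimulus frequencies (Hz); must lie on the grid.
#' @param f_lo,f_hi,df Analysis grid (Hz).
#' @param input_floor Minimum input amplitude for a valid ratio.
#' @param input_value,output_value Optional column names.
#' @return A `fly_frf` tibble: `freq_hz`, `response` (complex), `gain`,
#'   `phase_deg`, `is_stim`, `valid`.
#' @export
frf <- function(input, output, stim_freqs,
                f_lo = 0, f_hi = 50, df = 0.05, input_floor = 1e-8,
                input_value = NULL, output_value = NULL) {
  if (nrow(input) != nrow(output)) {
    rlang::abort("`input` and `output` must have equal length.")
  }
  if (abs(infer_sample_rate(input) - infer_sample_rate(output)) > 1e-9) {
    rlang::abort("`input` and `output` must share one sample rate.")
  }
  si <- czt_spectrum(input, f_lo, f_hi, df, value = input_value)
  so <- czt_spectrum(output, f_lo, f_hi, df, value = output_value)
  grid <- si$freq_hz
  is_stim <- rep(FALSE, length(grid))
  is_stim[snap_to_grid(stim_freqs, grid)] <- TRUE
  valid <- Mod(si$spectrum) >= input_floor
  resp <- so$spectrum / si$spectrum
  resp[!valid] <- NA_complex_
  new_frf(grid, resp, is_stim, valid)
}

#' Compensation error of a closed-loop transform
#'
#' Distance on the complex plane between the transform and perfect
#' compensation `1 + 0i` (gain 1, phase 0): `epsilon = |(1 + 0i) - X|`.
#' Zero means ideal compensation, one means the response has no effect on
#' performance, values above one indicate a deleterious response.
#'
#' @param fr A `fly_frf` tibble (from [frf()] or [average_across_flies()]).
#' @return Tibble with `freq_hz`, `comp_err`.
#' @examples
#' compensation_error(new_frf(1, 1 + 0i, TRUE, TRUE))$comp_err # 0
#' @export
compensation_error <- function(fr) {
  stopifnot(inherits(fr, "fly_frf"))
  tibble::tibble(freq_hz = fr$freq_hz,
                 comp_err = Mod((1 + 0i) - fr$response))
}

#' Magnitude-squared coherence across trials
#'
#' Coherence between input and output at the stimulus frequencies, using
#' trial-averaged cross- and auto-spectra:
#' `|mean(conj(X) Y)|^2 / (mean(|X|^2) mean(|Y|^2))`. Averaging across
#' trials provides the spectral averaging that makes the estimate
#' informative; a single trial is rejected because its coherence is
#' identically one.
#'
#' @param inputs,outputs Lists of tibbles (`time_s` + value column), one per
#'   trial, equal lengths.
#' @param stim_freqs Frequencies (Hz) at which to evaluate.
#' @return Tibble with `freq_hz`, `coherence` in `[0, 1]`.
#' @export
coherence <- function(inputs, outputs, stim_freqs) {
  if (length(inputs) != length(outputs)) {
    rlang::abort("`inputs` and `outputs` must have one trial each, pairwise.")
  }
  if (length(inputs) < 2L) {
    rlang::abort("coherence needs at least 2 trials (one trial is degenerate at 1).")
  }
  spec_at <- function(d) {
    sr <- infer_sample_rate(d)
    x <- d[[first_value_col(d)]]
    n <- length(x)
    ex <- exp(-2i * pi * outer(stim_freqs, (seq_len(n) - 1) / sr))
    as.vector(ex %*% x) * 2i / n
  }
  X <- vapply(inputs, spec_at, complex(length(stim_freqs)))
  Y <- vapply(outputs, spec_at, complex(length(stim_freqs)))
  X <- matrix(X, nrow = length(stim_freqs))
  Y <- matrix(Y, nrow = length(stim_freqs))
  Sxy <- rowMeans(Conj(X) * Y)
  Sxx <- rowMeans(Mod(X)^2)
  Syy <- rowMeans(Mod(Y)^2)
  tibble::tibble(freq_hz = stim_freqs,
                 coherence = Mod(Sxy)^2 / (Sxx * Syy))
}

#' Least-squares spectral analysis (single-frequency sinusoid fit)
#'
#' Ordinary least squares of `a sin(2 pi f t) + b cos(2 pi f t) + c` on the
#' samples not excluded by `exclude_mask`. Because the fit uses only the
#' retained samples, it recovers the amplitude of a sinusoid whose clipped
#' (saturated) portions have been masked out.
#'
#' @param data Tibble with `time_s` and one value column.
#' @param f Frequency (Hz).
#' @param exclude_mask Logical vector, `TRUE` = drop the sample. `NULL`
#'   keeps everything.
#' @param value Optional column name.
#' @return List with `amplitude`, `phase_deg` (sine convention), `offset`.
#' @export
lssa_fit <- function(data, f, exclude_mask = NULL, value = NULL) {
  col <- if (is.null(value)) first_value_col(data) else value
  t <- data$time_s
  x <- data[[col]]
  keep <- if (is.null(exclude_mask)) rep(TRUE, length(x)) else !exclude_mask
  stopifnot(length(keep) == length(x))
  if (sum(keep) < 10L || diff(range(t[keep])) < 1 / f) {
    rlang::abort("too few unmasked samples (need >= 10 spanning >= 1 cycle).")
  }
  X <- cbind(sin(2 * pi * f * t[keep]), cos(2 * pi * f * t[keep]), 1)
  cf <- stats::lm.fit(X, x[keep])$coefficients
  list(amplitude = sqrt(cf[[1]]^2 + cf[[2]]^2),
       phase_deg = wrap_deg(atan2(cf[[2]], cf[[1]]) * 180 / pi),
       offset = cf[[3]])
}

#' Saturation-corrected gain factor for a clipped head response
#'
#' When the head rides at its anatomical limit, the chirp-z amplitude
#' underestimates the response the neck would have produced. This routine
#' masks the saturated portion of the trace (samples near the limit where
#' the velocity is near zero), refits the sinusoid by [lssa_fit()] on the
#' remaining data, and returns the ratio of the corrected to the
#' uncorrected amplitude. The factor applies to gain only; phase is left
#' untouched.
#'
#' @param data Tibble with `time_s` and the head angle column.
#' @param f Stimulus frequency (Hz).
#' @param limit Neck-joint limit (deg).
#' @param vel_floor Absolute velocity (deg/s) below which a near-limit
#'   sample counts as saturated. Default 0.15 * 2 pi f * limit (15% of the
#'   peak velocity an unclipped sinusoid at the limit would reach).
#' @param value Optional column name.
#' @return List with `factor` (corrected / uncorrected amplitude), `mask`
#'   (logical, `TRUE` = saturated sample), `amplitude_corrected`,
#'   `amplitude_raw`.
#' @export
saturation_correct <- function(data, f, limit, vel_floor = NULL,
                               value = NULL) {
  if (limit <= 0) rlang::abort("`limit` must be positive.")
  col <- if (is.null(value)) first_value_col(data) else value
  sr <- infer_sample_rate(data)
  x <- data[[col]]
  if (is.null(vel_floor)) vel_floor <- 0.15 * 2 * pi * f * limit
  vel <- fd_velocity(x, sr)
  mask <- abs(x) > 0.95 * limit & abs(vel) < vel_floor
  if (mean(mask) > 0.9) {
    rlang::abort("more than 90% of samples are saturated; response unrecoverable.")
  }
  sp <- czt_spectrum(data, f_lo = f, f_hi = f + 1, df = 1, value = col)
  amp_raw <- sp$amplitude[1]
  fit <- lssa_fit(data, f, exclude_mask = mask, value = col)
  list(factor = fit$amplitude / amp_raw, mask = mask,
       amplitude_corrected = fit$amplitude, amplitude_raw = amp_raw)
}

# --- circular statistics (degrees) ------------------------------------------

circ_mean_deg <- function(deg) {
  wrap_deg(Arg(mean(exp(1i * deg * pi / 180))) * 180 / pi)
}

circ_sd_deg <- function(deg) {
  rbar <- Mod(mean(exp(1i * deg * pi / 180)))
  rbar <- min(rbar, 1)
  sqrt(-2 * log(max(rbar, .Machine$double.eps))) * 180 / pi
}

#' Average frequency-response functions across animals
#'
#' Per-frequency arithmetic mean and sample SD of gain and compensation
#' error, and circular mean and circular SD of phase. Gain and phase are
#' averaged directly (not the complex values), matching how dispersion is
#' usually reported for behavioral transforms; set `complex_mean = TRUE` to
#' also attach the mean of the complex values as a diagnostic column.
#'
#' @param frs List of `fly_frf` tibbles on one common grid (one per animal).
#' @param complex_mean Attach the complex average as column `response_cplx`.
#' @return A `fly_frf` tibble with columns `freq_hz`, `response` (rebuilt
#'   from mean gain and circular-mean phase), `gain`, `gain_sd`,
#'   `phase_deg`, `phase_sd_deg`, `comp_err`, `comp_err_sd`, `is_stim`,
#'   `valid`, `n_flies`.
#' @export
average_across_flies <- function(frs, complex_mean = FALSE) {
  stopifnot(length(frs) >= 1L)
  grid <- frs[[1]]$freq_hz
  for (fr in frs) {
    if (!isTRUE(all.equal(fr$freq_hz, grid))) {
      rlang::abort("all frequency-response functions must share one grid.")
    }
  }
  gain <- sapply(frs, function(f) f$gain)
  phase <- sapply(frs, function(f) f$phase_deg)
  eps <- sapply(frs, function(f) Mod((1 + 0i) - f$response))
  valid <- Reduce(`&`, lapply(frs, function(f) f$valid))
  gain <- matrix(gain, nrow = length(grid))
  phase <- matrix(phase, nrow = length(grid))
  eps <- matrix(eps, nrow = length(grid))
  mgain <- rowMeans(gain)
  mphase <- apply(phase, 1, circ_mean_deg)
  out <- new_frf(grid, mgain * exp(1i * mphase * pi / 180),
                 frs[[1]]$is_stim, valid, n_flies = length(frs))
  out$gain_sd <- apply(gain, 1, stats::sd)
  out$phase_sd_deg <- apply(phase, 1, circ_sd_deg)
  out$comp_err <- rowMeans(eps)
  out$comp_err_sd <- apply(eps, 1, stats::sd)
  out$n_flies <- length(frs)
  if (complex_mean) {
    cm <- Reduce(`+`, lapply(frs, function(f) f$response)) / length(frs)
    out$response_cplx <- cm
  }
  out
}

#' Monte Carlo uncertainty propagation through a decomposition formula
#'
#' The decomposition formulas combine transforms measured in different
#' groups of animals, so their dispersions cannot be pooled analytically.
#' This routine draws per-frequency gain (normal) and phase (wrapped
#' normal) independently for each input transform, pushes each draw through
#' the expression, and summarizes the output draws by mean gain/phase and
#' their dispersions.
#'
#' @param inputs Named list of averaged `fly_frf` tibbles carrying
#'   `gain_sd` and `phase_sd_deg` columns.
#' @param expression Either a function taking a named list of complex
#'   vectors (one per input, same names) and returning a complex vector, or
#'   one of the registered decomposition tags (see
#'   [decompose_expressions()]).
#' @param n_draws Number of Monte Carlo draws (>= 100).
#' @param seed Integer seed.
#' @return A `fly_frf` tibble with `gain_sd`, `phase_sd_deg`, `comp_err`,
#'   `comp_err_sd` estimated from the draws.
#' @export
propagate_uncertainty <- function(inputs, expression, n_draws = 1000,
                                  seed = 1L) {
  if (n_draws < 100) rlang::abort("`n_draws` must be at least 100.")
  if (is.character(expression)) {
    expression <- decompose_expressions()[[match.arg(
      expression, names(decompose_expressions()))]]
  }
  stopifnot(is.function(expression))
  grid <- inputs[[1]]$freq_hz
  nf <- length(grid)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draws <- matrix(NA_complex_, nrow = nf, ncol = n_draws)
  for (d in seq_len(n_draws)) {
    sampled <- lapply(inputs, function(fr) {
      gsd <- if ("gain_sd" %in% names(fr)) fr$gain_sd else 0
      psd <- if ("phase_sd_deg" %in% names(fr)) fr$phase_sd_deg else 0
      g <- pmax(fr$gain + stats::rnorm(nf) * gsd, 0)
      p <- fr$phase_deg + stats::rnorm(nf) * psd
      g * exp(1i * p * pi / 180)
    })
    draws[, d] <- expression(sampled)
  }
  gains <- Mod(draws)
  phases <- Arg(draws) * 180 / pi
  eps <- Mod((1 + 0i) - draws)
  mphase <- apply(phases, 1, circ_mean_deg)
  out <- new_frf(grid, rowMeans(gains) * exp(1i * mphase * pi / 180),
                 inputs[[1]]$is_stim, inputs[[1]]$valid,
                 n_flies = attr(inputs[[1]], "n_flies"))
  out$gain_sd <- apply(gains, 1, stats::sd)
  out$phase_sd_deg <- apply(phases, 1, circ_sd_deg)
  out$comp_err <- rowMeans(eps)
  out$comp_err_sd <- apply(eps, 1, stats::sd)
  out
}
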