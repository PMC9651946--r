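#' Velocity-normalized visual perturbations
#'
#' The stimuli are rotations of a wide-field grating whose angular position
#' follows either a single sinusoid or a sum of nine sinusoids. Component
#' amplitudes are chosen so that the peak angular *velocity* of every
#' component equals `v_norm`: `A_i = v_norm / (2 * pi * f_i)`. This keeps the
#' retinal-slip speed comparable across frequencies.
#'
#' @name perturbations
NULL

# canonical single-sine battery (Hz)
stimulus_battery_freqs <- c(0.7, 1, 1.5, 2.1, 3.5, 5.3, 10.6)

#' Default sum-of-sines frequency set
#'
#' Nine approximately logarithmically spaced frequencies between 0.35 and
#' 13.7 Hz, snapped to the 0.05 Hz analysis grid and adjusted minimally so
#' that no frequency is an integer multiple of another (which would let the
#' harmonics of one component contaminate the response at another).
#'
#' @return Numeric vector of nine frequencies in Hz.
#' @export
default_sos_freqs <- function() {
  c(0.35, 0.55, 0.90, 1.45, 2.25, 3.45, 5.45, 8.65, 13.70)
}

check_sos_freqs <- function(freqs, grid_hz = 0.05, tol = 1e-9) {
  if (length(freqs) != 9L) {
    rlang::abort("sum-of-sines perturbations use exactly nine frequency components.")
  }
  if (any(freqs <= 0)) rlang::abort("frequencies must be positive.")
  off <- abs(freqs / grid_hz - round(freqs / grid_hz)) > tol
  if (any(off)) {
    rlang::abort(paste0("frequencies not on the ", grid_hz, " Hz grid: ",
                        paste(freqs[off], collapse = ", ")))
  }
  fs <- sort(freqs)
  for (i in seq_along(fs)) {
    for (j in seq_len(i - 1L)) {
      r <- fs[i] / fs[j]
      if (abs(r - round(r)) < tol) {
        rlang::abort(sprintf(
          "harmonically related frequency pair: %g Hz is %dx %g Hz",
          fs[i], round(r), fs[j]))
      }
    }
  }
  invisible(freqs)
}

#' Perturbation specification
#'
#' @param kind `"single_sine"` or `"sum_of_sines"`.
#' @param frequencies Component frequencies (Hz).
#' @param v_norm Peak angular velocity of every component (deg/s).
#' @param phases Component phases (rad).
#' @param duration Signal duration (s).
#' @param sample_rate Sampling rate (Hz).
#' @param seed Integer seed used for phase randomization (or `NA`).
#' @return A list of class `perturbation_spec` with the component amplitudes
#'   `amplitudes = v_norm / (2 * pi * frequencies)` filled in.
#' @export
perturbation_spec <- function(kind, frequencies, v_norm, phases = NULL,
                              duration = 20, sample_rate = 100, seed = NA) {
  kind <- match.arg(kind, c("single_sine", "sum_of_sines"))
  if (any(frequencies <= 0)) rlang::abort("frequencies must be positive.")
  if (kind == "single_sine" && length(frequencies) != 1L) {
    rlang::abort("single_sine perturbations have exactly one component.")
  }
  if (kind == "sum_of_sines") check_sos_freqs(frequencies)
  if (is.null(phases)) phases <- rep(0, length(frequencies))
  stopifnot(length(phases) == length(frequencies))
  if (v_norm < 0) rlang::abort("`v_norm` must be non-negative.")
  if (sample_rate <= 0) rlang::abort("`sample_rate` must be positive.")
  if (duration <= 0) rlang::abort("`duration` must be positive.")
  structure(
    list(kind = kind, frequencies = as.numeric(frequencies),
         amplitudes = v_norm / (2 * pi * as.numeric(frequencies)),
         phases = as.numeric(phases), v_norm = v_norm,
         duration = duration, sample_rate = sample_rate, seed = seed),
    class = "perturbation_spec"
  )
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("<perturbation_spec>", x$kind, "\n")
  cat("  freqs (Hz):", paste(signif(x$frequencies, 4), collapse = ", "), "\n")
  cat("  v_norm:", x$v_norm, "deg/s  duration:", x$duration,
      "s  rate:", x$sample_rate, "Hz\n")
  invisible(x)
}

spec_time <- function(spec) {
  seq(0, spec$duration - 1 / spec$sample_rate, by = 1 / spec$sample_rate)
}

spec_signal <- function(spec, t = spec_time(spec)) {
  v <- numeric(length(t))
  for (i in seq_along(spec$frequencies)) {
    v <- v + spec$amplitudes[i] *
      sin(2 * pi * spec$frequencies[i] * t + spec$phases[i])
  }
  v
}

stimulus_tbl <- function(spec) {
  t <- spec_time(spec)
  out <- tibble::tibble(time_s = t, stimulus_deg = spec_signal(spec, t))
  attr(out, "spec") <- spec
  out
}

#' Single-sine perturbation with velocity normalization
#'
#' Builds `R(t) = (v_norm / (2 pi f)) * sin(2 pi f t)`, whose peak angular
#' velocity is exactly `v_norm`.
#'
#' @param f Frequency (Hz), positive.
#' @param v_norm Peak angular velocity (deg/s); default 250 matches the
#'   standard single-sine battery.
#' @param duration Duration (s); must cover at least one full cycle.
#' @param sample_rate Sampling rate (Hz).
#' @return Tibble with columns `time_s`, `stimulus_deg`; the
#'   [perturbation_spec()] is attached as attribute `"spec"`.
#' @examples
#' stim <- single_sine(1, v_norm = 250, duration = 10)
#' max(stim$stimulus_deg) # ~ 250 / (2 * pi) = 39.79 deg
#' @export
single_sine <- function(f, v_norm = 250, duration = 10, sample_rate = 100) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0) {
    rlang::abort("`f` must be a single positive frequency in Hz.")
  }
  if (sample_rate <= 0) rlang::abort("`sample_rate` must be positive.")
  if (duration < 1 / f) {
    rlang::abort("`duration` must cover at least one full cycle of `f`.")
  }
  spec <- perturbation_spec("single_sine", f, v_norm,
                            duration = duration, sample_rate = sample_rate)
  stimulus_tbl(spec)
}

#' Sum-of-sines perturbation with velocity normalization
#'
#' Builds `R(t) = sum_i (v_norm / (2 pi f_i)) * sin(2 pi f_i t + phi_i)` with
#' nine components and reproducibly randomized phases.
#'
#' @param v_norm Per-component peak angular velocity (deg/s). The standard
#'   battery uses 42, 70, and 95 deg/s.
#' @param frequencies Nine frequencies on the 0.05 Hz grid, none an integer
#'   multiple of another; defaults to [default_sos_freqs()].
#' @param duration Duration (s), default 20.
#' @param sample_rate Sampling rate (Hz).
#' @param seed Integer seed for the phase draw (uniform on `[0, 2 pi)`).
#' @return Tibble with `time_s`, `stimulus_deg` and the [perturbation_spec()]
#'   attached as attribute `"spec"`.
#' @export
sum_of_sines <- function(v_norm, frequencies = default_sos_freqs(),
                         duration = 20, sample_rate = 100, seed = 1L) {
  check_sos_freqs(frequencies)
  phases <- local_runif(seed, length(frequencies)) * 2 * pi
  spec <- perturbation_spec("sum_of_sines", frequencies, v_norm,
                            phases = phases, duration = duration,
                            sample_rate = sample_rate, seed = seed)
  stimulus_tbl(spec)
}

# draw n uniforms from a private RNG stream without touching the global seed
local_runif <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::runif(n)
}

first_value_col <- function(data) {
  nm <- setdiff(names(data), "time_s")
  if (!length(nm)) rlang::abort("no value column found.")
  nm[[1]]
}

infer_sample_rate <- function(data) {
  if (!"time_s" %in% names(data)) rlang::abort("`data` needs a `time_s` column.")
  dt <- diff(data$time_s)
  if (any(abs(dt - dt[1]) > 1e-6)) rlang::abort("`time_s` is not uniformly sampled.")
  1 / dt[1]
}

# centered finite-difference velocity, forward/backward at the edges (deg/s)
fd_velocity <- function(values, sample_rate) {
  n <- length(values)
  if (n < 3L) rlang::abort("need at least 3 samples to differentiate.")
  v <- numeric(n)
  v[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) * sample_rate / 2
  v[1] <- (values[2] - values[1]) * sample_rate
  v[n] <- (values[n] - values[n - 1]) * sample_rate
  v
}

#' Mean absolute angular speed of a trajectory
#'
#' Time average of `|d theta / dt|` using centered finite differences. For a
#' single sinusoid with peak velocity `v_norm` this converges to
#' `(2 / pi) * v_norm`.
#'
#' @param data Tibble with `time_s` and one angle column (deg), e.g. the
#'   output of [single_sine()].
#' @param value Optional name of the angle column; defaults to the first
#'   non-time column.
#' @return Mean absolute speed in deg/s.
#' @examples
#' mean_abs_speed(single_sine(1, v_norm = 250)) # ~ 2/pi * 250 = 159.2
#' @export
mean_abs_speed <- function(data, value = NULL) {
  sr <- infer_sample_rate(data)
  col <- if (is.null(value)) first_value_col(data) else value
  mean(abs(fd_velocity(data[[col]], sr)))
}

#' Mean temporal frequency of a moving grating
#'
#' The mean rate at which grating periods sweep past a point on the retina:
#' mean absolute speed divided by the spatial wavelength.
#'
#' @inheritParams mean_abs_speed
#' @param wavelength Spatial wavelength of the grating in degrees
#'   (default 30, the display grating).
#' @return Mean temporal frequency in Hz.
#' @examples
#' mean_temporal_frequency(single_sine(1, v_norm = 250)) # ~ 5.3 Hz
#' @export
mean_temporal_frequency <- function(data, wavelength = 30, value = NULL) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0) {
    rlang::abort("`wavelength` must be a single positive number of degrees.")
  }
  mean_abs_speed(data, value = value) / wavelength
}
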