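#' Parameters for the synthetic saccade generator
#'
#' Saccades are modeled as smooth single-peaked velocity pulses (a squared
#' sine profile) with amplitude and duration drawn per event, followed by an
#' exponential return of the head towards the neutral position. The return
#' time constant differs by condition: with the body free to move,
#' mechanosensory feedback brakes the head quickly (`tau_free`); with the
#' body fixed, the return is much slower (`tau_fixed`).
#'
#' @param amp_mean,amp_sd Mean and SD of saccade amplitude (deg); draws are
#'   truncated to `[amp_min, head_limit]`, keeping every event's peak
#'   velocity (`2 * amplitude / duration`) above the standard 100 deg/s
#'   detection threshold.
#' @param amp_min Smallest injected amplitude (deg).
#' @param dur_mean,dur_sd Mean and SD of saccade duration (s); draws are
#'   truncated to `[0.04, 0.10]` s so that saccades last well under 200 ms.
#' @param rate Mean saccade rate (events/s) used for the inter-saccade
#'   interval draw (exponential, floored at `min_isi`).
#' @param min_isi Minimum inter-saccade interval (s).
#' @param tau_free,tau_fixed Post-saccade damping time constants (s) for the
#'   body-free and body-fixed conditions.
#' @param noise_sd SD (deg) of smooth inter-saccade fixation noise.
#' @param trial_duration Trial length (s).
#' @param sample_rate Sampling rate (Hz).
#' @param head_limit Neck-joint limit (deg); amplitude draws beyond it are
#'   clipped and counted.
#' @return A list of class `saccade_gen_params`.
#' @export
saccade_gen_params <- function(amp_mean = 8, amp_sd = 2, amp_min = 6,
                               dur_mean = 0.07, dur_sd = 0.015,
                               rate = 0.8, min_isi = 1.1,
                               tau_free = 0.1, tau_fixed = 0.8,
                               noise_sd = 0.1,
                               trial_duration = 10, sample_rate = 100,
                               head_limit = 15) {
  stopifnot(amp_mean > 0, dur_mean > 0, rate > 0,
            tau_free > 0, tau_fixed > 0, trial_duration > 0)
  structure(as.list(environment()), class = "saccade_gen_params")
}

# cumulative displacement of a squared-sine velocity pulse, u in [0, 1]
saccade_rise <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Generate synthetic saccade trials with ground truth
#'
#' Builds head-angle traces containing injected saccades on top of smooth
#' fixation noise. Each saccade displaces the head by its amplitude over its
#' duration (squared-sine velocity profile, peak velocity
#' `2 * amplitude / duration`) and then decays exponentially back with the
#' condition's time constant.
#'
#' @param params A [saccade_gen_params()] object.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param condition `"body_free"` or `"body_fixed"`: selects the return time
#'   constant (`tau_free` or `tau_fixed`).
#' @return A list with `trials` (list of tibbles `time_s`, `head_deg`),
#'   `truth` (tibble of injected events: `trial`, `onset_s`, `duration_s`,
#'   `amplitude_deg`, `peak_velocity_dps`, `tau_s`, `direction`), and
#'   `n_clipped` (count of amplitude draws clipped at the neck limit).
#' @export
generate_saccade_trials <- function(params, n_trials,
                                    seed = 1L,
                                    condition = c("body_free", "body_fixed")) {
  stopifnot(inherits(params, "saccade_gen_params"))
  condition <- match.arg(condition)
  if (n_trials == 0L) {
    return(list(trials = list(), truth = empty_truth_log(), n_clipped = 0L))
  }
  tau <- if (condition == "body_free") params$tau_free else params$tau_fixed
  fs <- params$sample_rate
  t <- seq(0, params$trial_duration - 1 / fs, by = 1 / fs)
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
  lp <- signal::butter(2, 5 / (fs / 2), type = "low")
  trials <- vector("list", n_trials)
  logs <- vector("list", n_trials)
  n_clipped <- 0L
  for (k in seq_len(n_trials)) {
    # event onsets: sequential exponential gaps floored at min_isi
    onsets <- numeric(0)
    tt <- 0.5
    repeat {
      tt <- tt + max(params$min_isi, stats::rexp(1, rate = params$rate))
      if (tt > params$trial_duration - 1.5) break
      onsets <- c(onsets, tt)
    }
    amp <- abs(stats::rnorm(length(onsets), params$amp_mean, params$amp_sd))
    clip <- amp > params$head_limit
    n_clipped <- n_clipped + sum(clip)
    amp <- pmin(pmax(amp, params$amp_min), params$head_limit)
    dur <- pmin(pmax(stats::rnorm(length(onsets), params$dur_mean,
                                  params$dur_sd), 0.04), 0.10)
    dir <- sample(c(-1, 1), length(onsets), replace = TRUE)
    head <- as.numeric(signal::filtfilt(lp, stats::rnorm(length(t)))) *
      params$noise_sd
    for (i in seq_along(onsets)) {
      u <- (t - onsets[i]) / dur[i]
      contrib <- numeric(length(t))
      rising <- u >= 0 & u < 1
      after <- u >= 1
      contrib[rising] <- saccade_rise(u[rising])
      contrib[after] <- exp(-(t[after] - onsets[i] - dur[i]) / tau)
      head <- head + dir[i] * amp[i] * contrib
    }
    trials[[k]] <- tibble::tibble(time_s = t, head_deg = head)
    logs[[k]] <- tibble::tibble(
      trial = k, onset_s = onsets, duration_s = dur,
      amplitude_deg = amp, peak_velocity_dps = 2 * amp / dur,
      tau_s = tau, direction = dir)
  }
  if (n_clipped > 0) {
    rlang::warn(sprintf("%d saccade amplitude draw(s) clipped at the %g deg neck limit.",
                        n_clipped, params$head_limit))
  }
  list(trials = trials, truth = dplyr::bind_rows(logs), n_clipped = n_clipped)
}

empty_truth_log <- function() {
  tibble::tibble(trial = integer(0), onset_s = numeric(0),
                 duration_s = numeric(0), amplitude_deg = numeric(0),
                 peak_velocity_dps = numeric(0), tau_s = numeric(0),
                 direction = numeric(0))
}
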