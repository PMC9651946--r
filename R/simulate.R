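#' Simulation configuration
#'
#' @param mode One of `"body_free"`, `"body_fixed"`, `"motor_replay"`.
#' @param noise_std_head,noise_std_body Standard deviation (deg) of white
#'   Gaussian measurement noise added to the recorded head and body angles
#'   (video-tracking noise, not process noise).
#' @param head_limit Anatomical limit of the neck joint (deg); the head angle
#'   is clamped to `[-head_limit, head_limit]`. Default 15.
#' @param mech_gate Scalar in `[0, 1]` multiplying the mechanosensory drive to
#'   the head. 1 models self-generated body motion; 0.1 models the weak
#'   response to externally generated body motion.
#' @param sample_rate Output sampling rate (Hz), default 100 (video rate).
#' @param internal_rate Internal simulation rate (Hz), default 1000, so that
#'   the 5 ms haltere delay is representable as an integer number of samples.
#' @param transient_discard Seconds discarded from the start of each trial.
#' @param saturation Apply the neck-joint clamp (default `TRUE`).
#' @param seed Integer seed for the measurement noise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("body_free", "body_fixed", "motor_replay"),
                       noise_std_head = 0.25, noise_std_body = 0.25,
                       head_limit = 15, mech_gate = 1,
                       sample_rate = 100, internal_rate = 1000,
                       transient_discard = 2, saturation = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (head_limit <= 0) rlang::abort("`head_limit` must be positive.")
  if (noise_std_head < 0 || noise_std_body < 0) {
    rlang::abort("noise standard deviations must be non-negative.")
  }
  if (mech_gate < 0 || mech_gate > 1) {
    rlang::abort("`mech_gate` must lie in [0, 1].")
  }
  if (internal_rate %% sample_rate != 0) {
    rlang::abort("`internal_rate` must be an integer multiple of `sample_rate`.")
  }
  structure(
    list(mode = mode, noise_std_head = noise_std_head,
         noise_std_body = noise_std_body, head_limit = head_limit,
         mech_gate = mech_gate, sample_rate = sample_rate,
         internal_rate = internal_rate,
         transient_discard = transient_discard,
         saturation = saturation, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# --- discrete-time machinery -------------------------------------------------

# bilinear-transform discretization of the rational part; the pure delay is
# carried separately as an integer number of internal samples
discretize_tf <- function(tf, fs) {
  d <- as.integer(round(tf$delay_s * fs))
  if (length(tf$poles) == 0L) {
    # static gain as a degenerate one-state filter so the stepper is uniform
    return(list(b = c(tf$gain, 0), a = c(1, 0), delay = d, state = 0))
  }
  zd <- signal::bilinear(Sz = tf$zeros, Sp = tf$poles, Sg = tf$gain, T = 1 / fs)
  arma <- signal::as.Arma(signal::Zpg(zero = zd$zero, pole = zd$pole,
                                      gain = zd$gain))
  b <- arma$b; a <- arma$a
  if (max(abs(Im(b))) > 1e-9 || max(abs(Im(a))) > 1e-9) {
    rlang::abort("discretized filter has complex coefficients; poles/zeros must come in conjugate pairs.")
  }
  b <- Re(b) / Re(a[1]); a <- Re(a) / Re(a[1])
  n <- max(length(a), length(b))
  list(b = c(b, rep(0, n - length(b))), a = c(a, rep(0, n - length(a))),
       delay = d, state = rep(0, n - 1L))
}

# one direct-form-II-transposed step; returns list(y, state)
filt_step <- function(flt, x) {
  b <- flt$b; a <- flt$a; z <- flt$state
  if (!length(z)) return(list(y = b[1] * x, state = z))
  y <- b[1] * x + z[1]
  nz <- length(z)
  if (nz > 1L) {
    z[1:(nz - 1)] <- b[2:nz] * x + z[2:nz] - a[2:nz] * y
  }
  z[nz] <- b[nz + 1] * x - a[nz + 1] * y
  list(y = y, state = z)
}

# filter an entire vector (used where no feedback loop is involved)
filt_all <- function(flt, x) {
  xd <- c(rep(0, flt$delay), x)[seq_along(x)]
  as.numeric(signal::filter(flt$b, flt$a, xd))
}

upsample_linear <- function(x, factor) {
  if (factor == 1L) return(x)
  n <- length(x)
  stats::approx(seq_len(n), x, xout = seq(1, n, by = 1 / factor))$y
}

delayed_at <- function(vec, t, d) {
  k <- t - d
  if (k < 1L) 0 else vec[k]
}

#' Numeric closed-loop stability check
#'
#' Evaluates the closed-loop characteristic function
#' `1 + G_head_V + Gb' (1 + mech_gate G_head_M)` (with
#' `Gb' = G_body_V / (1 - G_body_M)`) on a dense frequency grid and then
#' simulates the loop's pulse response without saturation or noise. The loop
#' is declared unstable when the pulse response grows; the error message
#' reports the frequency at which the characteristic function comes closest
#' to zero (the locus of the offending closed-loop pole pair).
#'
#' @param components A [loop_components()] object.
#' @param config A [sim_config()].
#' @return Invisibly `TRUE` when stable; aborts otherwise.
#' @export
check_loop_stability <- function(components, config = sim_config()) {
  fs <- config$internal_rate
  key <- rlang::hash(list(unclass(components), config$mech_gate, fs))
  if (isTRUE(.stability_cache[[key]])) return(invisible(TRUE))
  filters <- loop_filters(components, fs)
  n <- as.integer(5 * fs)
  r <- c(rep(0, 10), rep(10, 5), rep(0, n - 15)) # short pulse
  sim <- loop_core(filters, r, mode = "body_free",
                   mech_gate = config$mech_gate,
                   head_limit = Inf, saturation = FALSE)
  tail_idx <- seq.int(floor(0.8 * n), n)
  peak <- max(abs(sim$H), abs(sim$B), 1e-12)
  tail_amp <- max(abs(sim$H[tail_idx]), abs(sim$B[tail_idx]))
  if (!is.finite(tail_amp) || tail_amp > 0.5 * peak) {
    fg <- seq(0.01, 50, by = 0.01)
    Gv <- tf_eval(components$G_head_V, fg)
    Gm <- config$mech_gate * tf_eval(components$G_head_M, fg)
    Gb <- tf_eval(components$G_body_V, fg) /
      (1 - tf_eval(components$G_body_M, fg))
    char <- 1 + Gv + Gb * (1 + Gm)
    f_bad <- fg[which.min(Mod(char))]
    rlang::abort(sprintf(
      "closed loop is unstable: characteristic function closest to zero near %.2f Hz (offending pole pair near +/- 2i*pi*%.2f).",
      f_bad, f_bad))
  }
  .stability_cache[[key]] <- TRUE
  invisible(TRUE)
}

# memo of loops already verified stable (keyed by components + gate + rate)
.stability_cache <- new.env(parent = emptyenv())

loop_filters <- function(components, fs) {
  list(
    HV = discretize_tf(components$G_head_V, fs),
    HM = discretize_tf(components$G_head_M, fs),
    BV = discretize_tf(components$G_body_V, fs),
    BM = discretize_tf(components$G_body_M, fs)
  )
}

# The inner loop at the internal rate. All transforms have >= 1 sample of
# transport delay at the internal rate, so signals computed at step t only
# require inputs up to t - 1 and the loop is solvable sample by sample with
# no artificial computation delay. Direct-form-II-transposed updates are
# inlined for speed (this loop dominates the simulator's run time).
loop_core <- function(filters, r, mode, mech_gate, head_limit,
                      saturation = TRUE, b_imposed = NULL) {
  n <- length(r)
  H <- numeric(n); B <- numeric(n); E <- numeric(n)
  bHV <- filters$HV$b; aHV <- filters$HV$a; zHV <- filters$HV$state
  bHM <- filters$HM$b; aHM <- filters$HM$a; zHM <- filters$HM$state
  bBV <- filters$BV$b; aBV <- filters$BV$a; zBV <- filters$BV$state
  bBM <- filters$BM$b; aBM <- filters$BM$a; zBM <- filters$BM$state
  nHV <- length(zHV); nHM <- length(zHM)
  nBV <- length(zBV); nBM <- length(zBM)
  dHV <- max(1L, filters$HV$delay); dHM <- max(1L, filters$HM$delay)
  dBV <- max(1L, filters$BV$delay); dBM <- max(1L, filters$BM$delay)
  body_fixed <- mode == "body_fixed"
  replay <- mode == "motor_replay"
  for (t in seq_len(n)) {
    x <- if (t > dHV) E[t - dHV] else 0
    yHV <- bHV[1] * x + zHV[1]
    if (nHV > 1L) zHV[1:(nHV - 1L)] <- bHV[2:nHV] * x + zHV[2:nHV] - aHV[2:nHV] * yHV
    zHV[nHV] <- bHV[nHV + 1L] * x - aHV[nHV + 1L] * yHV
    if (body_fixed) {
      h <- yHV
      b <- 0
    } else {
      x <- if (replay) {
        if (t > dHM) b_imposed[t - dHM] else 0
      } else {
        if (t > dHM) B[t - dHM] else 0
      }
      yHM <- bHM[1] * x + zHM[1]
      if (nHM > 1L) zHM[1:(nHM - 1L)] <- bHM[2:nHM] * x + zHM[2:nHM] - aHM[2:nHM] * yHM
      zHM[nHM] <- bHM[nHM + 1L] * x - aHM[nHM + 1L] * yHM
      h <- yHV + mech_gate * yHM
      if (replay) {
        b <- b_imposed[t]
      } else {
        x <- if (t > dBV) E[t - dBV] else 0
        yBV <- bBV[1] * x + zBV[1]
        if (nBV > 1L) zBV[1:(nBV - 1L)] <- bBV[2:nBV] * x + zBV[2:nBV] - aBV[2:nBV] * yBV
        zBV[nBV] <- bBV[nBV + 1L] * x - aBV[nBV + 1L] * yBV
        x <- if (t > dBM) B[t - dBM] else 0
        yBM <- bBM[1] * x + zBM[1]
        if (nBM > 1L) zBM[1:(nBM - 1L)] <- bBM[2:nBM] * x + zBM[2:nBM] - aBM[2:nBM] * yBM
        zBM[nBM] <- bBM[nBM + 1L] * x - aBM[nBM + 1L] * yBM
        b <- yBV + yBM
      }
    }
    if (saturation) h <- min(max(h, -head_limit), head_limit)
    H[t] <- h
    B[t] <- b
    # motor replay: the display co-rotates with the body, so body motion
    # induces no retinal slip and only head motion drives the visual error
    E[t] <- if (replay) -h else r[t] - h - b
  }
  list(H = H, B = B, E = E)
}

finish_trial <- function(r_out, H, B, config, spec, components, truth_extra = NULL) {
  fs <- config$sample_rate
  keep <- as.integer(config$transient_discard * fs) + 1L
  idx <- seq.int(keep, length(r_out))
  if (config$noise_std_head > 0 || config$noise_std_body > 0) {
    noise <- local_noise(config$seed, length(idx))
    H[idx] <- H[idx] + config$noise_std_head * noise$head
    if (config$mode != "body_fixed") {
      B[idx] <- B[idx] + config$noise_std_body * noise$body
    }
  }
  t <- (idx - keep) / fs
  out <- tibble::tibble(
    time_s = t,
    stimulus_deg = r_out[idx],
    head_deg = H[idx],
    body_deg = B[idx],
    error_deg = r_out[idx] - H[idx] - B[idx]
  )
  attr(out, "spec") <- spec
  attr(out, "config") <- config
  attr(out, "truth") <- components
  attr(out, "truth_extra") <- truth_extra
  class(out) <- c("fly_trial", class(out))
  out
}

local_noise <- function(seed, n) {
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
  list(head = stats::rnorm(n), body = stats::rnorm(n))
}

#' Simulate one closed-loop trial
#'
#' Runs the nested feedback loop `H = G_head_V E + G_head_M B`,
#' `B = G_body_V E + G_body_M B`, `E = R - H - B` in discrete time at
#' `config$internal_rate` (bilinear-transform discretization; pure delays as
#' integer internal samples), clamps the head at the neck-joint limit,
#' decimates to `config$sample_rate`, discards the initial transient, and
#' adds measurement noise. In `body_fixed` mode the body is clamped
#' (`B = 0`, `E = R - H`).
#'
#' @param components A [loop_components()] object (e.g. [default_fly()]).
#' @param stimulus Tibble with `time_s` and `stimulus_deg` (e.g. from
#'   [single_sine()]); its sampling rate must equal `config$sample_rate`.
#' @param config A [sim_config()].
#' @return A `fly_trial` tibble with columns `time_s`, `stimulus_deg`,
#'   `head_deg`, `body_deg`, `error_deg` and attributes `spec`, `config`,
#'   `truth` (the generating [loop_components()]).
#' @examples
#' trial <- simulate_trial(default_fly(), single_sine(2.1, duration = 6),
#'                         sim_config(noise_std_head = 0, noise_std_body = 0))
#' @export
simulate_trial <- function(components, stimulus,
                           config = sim_config()) {
  stopifnot(inherits(components, "loop_components"))
  sr <- infer_sample_rate(stimulus)
  if (abs(sr - config$sample_rate) > 1e-6) {
    rlang::abort(sprintf(
      "stimulus sample rate (%g Hz) does not match config$sample_rate (%g Hz).",
      sr, config$sample_rate))
  }
  if (config$mode == "motor_replay") {
    rlang::abort("use simulate_motor_replay() for motor_replay mode.")
  }
  check_loop_stability(components, config)
  fs <- config$internal_rate
  factor <- as.integer(fs / config$sample_rate)
  spec <- attr(stimulus, "spec")
  r_int <- if (inherits(spec, "perturbation_spec")) {
    # synthesize the stimulus exactly at the internal rate (linear
    # interpolation would attenuate the highest stimulus frequencies)
    t_int <- (seq_len((nrow(stimulus) - 1L) * factor + 1L) - 1L) / fs
    spec_signal(spec, t_int)
  } else {
    upsample_linear(stimulus$stimulus_deg, factor)
  }
  filters <- loop_filters(components, fs)
  sim <- loop_core(filters, r_int, mode = config$mode,
                   mech_gate = config$mech_gate,
                   head_limit = config$head_limit,
                   saturation = config$saturation)
  dec <- seq(1, length(r_int), by = factor)
  finish_trial(stimulus$stimulus_deg, sim$H[dec], sim$B[dec],
               config, attr(stimulus, "spec"), components)
}

#' Simulate a motor-replay trial
#'
#' Body motion is imposed externally (the fly is mounted on a motor) and the
#' visual display co-rotates with the body, so body motion induces no visual
#' feedback; head visual feedback remains because the head is free to move.
#' The mechanosensory drive to the head is scaled by `config$mech_gate`
#' (default 0.1 here: externally generated body motion engages only a weak
#' mechanosensory response). With `passive = TRUE` all neural controllers are
#' zeroed and the head follows the body only through a weak passive neck
#' coupling, modeling an anesthetized animal.
#'
#' @param components A [loop_components()] object.
#' @param body_motion Tibble with `time_s` and `body_deg`: the prescribed
#'   body trajectory.
#' @param config A [sim_config()] with `mode = "motor_replay"`.
#' @param passive If `TRUE`, simulate the anesthetized (passive-neck) variant.
#' @param passive_coupling Dimensionless body-to-head coupling of the passive
#'   neck (default 0.01, producing sub-degree passive head motion for
#'   tens-of-degrees body motion).
#' @return A `fly_trial` tibble (columns as in [simulate_trial()];
#'   `stimulus_deg` is zero).
#' @export
simulate_motor_replay <- function(components, body_motion,
                                  config = sim_config(mode = "motor_replay",
                                                      mech_gate = 0.1),
                                  passive = FALSE, passive_coupling = 0.01) {
  stopifnot(inherits(components, "loop_components"))
  if (config$mode != "motor_replay") {
    rlang::abort("config$mode must be 'motor_replay'.")
  }
  if (!nrow(body_motion)) rlang::abort("`body_motion` is empty.")
  if (!"body_deg" %in% names(body_motion)) {
    rlang::abort("`body_motion` needs a `body_deg` column.")
  }
  sr <- infer_sample_rate(body_motion)
  if (abs(sr - config$sample_rate) > 1e-6) {
    rlang::abort("body_motion sample rate does not match config$sample_rate.")
  }
  fs <- config$internal_rate
  factor <- as.integer(fs / config$sample_rate)
  b_int <- upsample_linear(body_motion$body_deg, factor)
  if (passive) {
    neck <- discretize_tf(tf_mul(components$P_head,
                                 tf_zpk(gain = passive_coupling)), fs)
    H <- filt_all(neck, b_int)
    if (config$saturation) {
      H <- pmin(pmax(H, -config$head_limit), config$head_limit)
    }
    sim <- list(H = H, B = b_int)
  } else {
    filters <- loop_filters(components, fs)
    sim <- loop_core(filters, rep(0, length(b_int)), mode = "motor_replay",
                     mech_gate = config$mech_gate,
                     head_limit = config$head_limit,
                     saturation = config$saturation, b_imposed = b_int)
  }
  dec <- seq(1, length(b_int), by = factor)
  finish_trial(rep(0, length(body_motion$body_deg)),
               sim$H[dec], sim$B[dec], config, NULL, components)
}
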