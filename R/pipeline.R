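#' Pipeline run configuration
#'
#' Collects every numeric default of the simulate - identify - decompose -
#' saccades workflow in one serializable object. A config round-trips
#' through [write_run_config()] / [read_run_config()] byte-identically.
#'
#' @param n_flies Number of synthetic animals per condition.
#' @param freqs Single-sine battery frequencies (Hz).
#' @param v_norm Peak stimulus velocity (deg/s).
#' @param duration Analysis window per trial (s); the transient is extra.
#' @param transient Discarded initial transient (s).
#' @param sample_rate Output rate (Hz).
#' @param noise_std Measurement noise SD (deg) on head and body angles.
#' @param head_limit Neck-joint limit (deg).
#' @param mech_gate_external Mechanosensory gate for externally generated
#'   body motion (motor replay); self-generated motion uses gate 1.
#' @param coherence_floor Coherence below which an external mechanosensory
#'   estimate is flagged low-confidence.
#' @param saccade_vel_threshold Saccade detection threshold (deg/s).
#' @param saccade_trials Trials per group for the saccade analysis.
#' @param seed Master seed; every random stage derives its seed from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_flies = 5,
                       freqs = c(0.7, 1, 1.5, 2.1, 3.5, 5.3, 10.6),
                       v_norm = 250, duration = 20, transient = 2,
                       sample_rate = 100, noise_std = 0.25,
                       head_limit = 15, mech_gate_external = 0.1,
                       coherence_floor = 0.2,
                       saccade_vel_threshold = 100,
                       saccade_trials = 110, seed = 1L) {
  structure(
    list(n_flies = as.integer(n_flies), freqs = as.numeric(freqs),
         v_norm = v_norm, duration = duration, transient = transient,
         sample_rate = sample_rate, noise_std = noise_std,
         head_limit = head_limit, mech_gate_external = mech_gate_external,
         coherence_floor = coherence_floor,
         saccade_vel_threshold = saccade_vel_threshold,
         saccade_trials = as.integer(saccade_trials),
         seed = as.integer(seed)),
    class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

trial_seed <- function(base, fly, trial, salt = 0L) {
  (base * 7919L + fly * 1013L + trial * 131L + salt) %% 2147483647L
}

sim_battery <- function(components, config, mode, salt = 0L) {
  lapply(seq_len(config$n_flies), function(fly) {
    lapply(seq_along(config$freqs), function(i) {
      f <- config$freqs[i]
      stim <- single_sine(f, v_norm = config$v_norm,
                          duration = config$duration + config$transient,
                          sample_rate = config$sample_rate)
      cfg <- sim_config(mode = mode,
                        noise_std_head = config$noise_std,
                        noise_std_body = config$noise_std,
                        head_limit = config$head_limit,
                        sample_rate = config$sample_rate,
                        transient_discard = config$transient,
                        seed = trial_seed(config$seed, fly, i, salt))
      simulate_trial(components, stim, cfg)
    })
  })
}

# per-fly transform at the battery frequencies, one trial per frequency;
# optional saturation correction of the output (head) amplitude
battery_frf <- function(trials, freqs, input_col, output_col,
                        head_limit = NULL) {
  vals <- complex(length(freqs))
  ok <- logical(length(freqs))
  for (i in seq_along(freqs)) {
    tr <- preprocess(trials[[i]][, c("time_s", input_col, output_col)])
    fr <- frf(tr[, c("time_s", input_col)], tr[, c("time_s", output_col)],
              stim_freqs = freqs[i])
    v <- fr$response[fr$is_stim]
    ok[i] <- fr$valid[fr$is_stim]
    if (!is.null(head_limit) &&
        max(abs(trials[[i]][[output_col]])) > 0.95 * head_limit) {
      sc <- saturation_correct(trials[[i]][, c("time_s", output_col)],
                               freqs[i], head_limit)
      v <- v * sc$factor # gain only; Arg unchanged since factor is real > 0
    }
    vals[i] <- v
  }
  new_frf(freqs, vals, rep(TRUE, length(freqs)), ok)
}

battery_coherence <- function(trials_by_fly, freqs, input_col, output_col) {
  vapply(seq_along(freqs), function(i) {
    ins <- lapply(trials_by_fly, function(tt) tt[[i]][, c("time_s", input_col)])
    outs <- lapply(trials_by_fly, function(tt) tt[[i]][, c("time_s", output_col)])
    coherence(ins, outs, freqs[i])$coherence
  }, numeric(1))
}

#' Run the full simulate - identify - decompose - saccades pipeline
#'
#' Simulates body-free and body-fixed single-sine batteries for
#' `config$n_flies` synthetic animals, identifies the closed-loop
#' transforms per fly (with saturation correction of clipped body-fixed
#' head responses), averages across flies, runs the feedback decomposition
#' (closed-loop terms, visual-only and mechanosensory-only predictions,
#' self- and externally generated mechanosensory estimates, weighting
#' ratio), analyzes synthetic saccade sets, and writes every table plus a
#' manifest to `out_dir`. Rerunning with the same config reproduces all
#' outputs bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param components Loop components to simulate; default [default_fly()].
#' @return Invisibly, a list with the main in-memory results (`averages`,
#'   `decomposition`, `gm`, `weighting`, `saccades`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         components = default_fly()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s",
                           name, conditionMessage(e)))
    })
  }
  freqs <- config$freqs

  free <- stage("simulate", sim_battery(components, config, "body_free", salt = 1L))
  fixed <- stage("simulate", sim_battery(components, config, "body_fixed", salt = 2L))

  ident <- stage("identify", {
    per_fly <- lapply(seq_len(config$n_flies), function(k) {
      list(
        H_over_R_free = battery_frf(free[[k]], freqs, "stimulus_deg", "head_deg"),
        B_over_R = battery_frf(free[[k]], freqs, "stimulus_deg", "body_deg"),
        GvM = battery_frf(free[[k]], freqs, "error_deg", "head_deg"),
        H_over_R_fixed = battery_frf(fixed[[k]], freqs, "stimulus_deg",
                                     "head_deg", head_limit = config$head_limit),
        Gv = battery_frf(fixed[[k]], freqs, "error_deg", "head_deg",
                         head_limit = config$head_limit)
      )
    })
    avg <- lapply(c("H_over_R_free", "B_over_R", "GvM",
                    "H_over_R_fixed", "Gv"),
                  function(nm) average_across_flies(
                    lapply(per_fly, `[[`, nm)))
    names(avg) <- c("H_over_R_free", "B_over_R", "GvM",
                    "H_over_R_fixed", "Gv")
    avg$H_over_R_free$coherence <-
      battery_coherence(free, freqs, "stimulus_deg", "head_deg")
    avg$B_over_R$coherence <-
      battery_coherence(free, freqs, "stimulus_deg", "body_deg")
    avg$H_over_R_fixed$coherence <-
      battery_coherence(fixed, freqs, "stimulus_deg", "head_deg")
    avg
  })

  dec <- stage("decompose", {
    terms <- closed_loop_head_free(ident$Gv,
                                   estimate_Gm_self(ident$Gv,
                                                    ident$H_over_R_free,
                                                    ident$B_over_R) |>
                                     gm_as_frf(),
                                   ident$B_over_R)
    list(
      terms = terms,
      pred_fixed = closed_loop_head_fixed(ident$Gv),
      pred_visual_only = predict_visual_only(ident$Gv, ident$B_over_R),
      pred_mechano_only = predict_mechano_only(ident$GvM),
      gm_self = estimate_Gm_self(ident$Gv, ident$H_over_R_free,
                                 ident$B_over_R),
      weighting = feedback_weighting(ident$GvM, ident$Gv)
    )
  })

  replay <- stage("replay", {
    gm_by_gate <- lapply(c(self = 1, external = config$mech_gate_external),
                         function(gate) {
      hb <- replay_frf(components, free, freqs, gate, config)
      estimate_Gm_external(ident$Gv, hb,
                           coherence_floor = config$coherence_floor)
    })
    gm_by_gate
  })

  sacc <- stage("saccades", {
    params <- saccade_gen_params(head_limit = config$head_limit)
    g_free <- generate_saccade_trials(params, config$saccade_trials,
                                      seed = trial_seed(config$seed, 0L, 0L, 3L),
                                      condition = "body_free")
    g_fixed <- generate_saccade_trials(params, config$saccade_trials,
                                       seed = trial_seed(config$seed, 0L, 0L, 4L),
                                       condition = "body_fixed")
    ev_free <- analyze_saccade_trials(g_free$trials,
                                      vel_threshold = config$saccade_vel_threshold)
    ev_fixed <- analyze_saccade_trials(g_fixed$trials,
                                       vel_threshold = config$saccade_vel_threshold)
    list(events_free = ev_free, events_fixed = ev_fixed,
         stats_free = saccade_population_stats(ev_free),
         stats_fixed = saccade_population_stats(ev_fixed),
         tau_comparison = compare_groups(ev_fixed, ev_free, "tau_s"))
  })

  files <- stage("write", {
    paths <- c(
      write_frf_csv(ident$H_over_R_free, file.path(out_dir, "frf_head_free.csv")),
      write_frf_csv(ident$H_over_R_fixed, file.path(out_dir, "frf_head_fixed.csv")),
      write_frf_csv(ident$B_over_R, file.path(out_dir, "frf_body_free.csv")),
      write_frf_csv(ident$Gv, file.path(out_dir, "frf_Gv.csv")),
      write_frf_csv(ident$GvM, file.path(out_dir, "frf_GvM.csv")),
      write_frf_csv(dec$pred_fixed, file.path(out_dir, "pred_head_fixed.csv")),
      write_frf_csv(dec$pred_visual_only, file.path(out_dir, "pred_visual_only.csv")),
      write_frf_csv(dec$pred_mechano_only, file.path(out_dir, "pred_mechano_only.csv")),
      write_frf_csv(dec$weighting, file.path(out_dir, "weighting_ratio.csv")),
      write_decomposition_csv(dec$terms, file.path(out_dir, "decomposition.csv")),
      write_gm_csv(dec$gm_self, replay, file.path(out_dir, "gm_estimates.csv")),
      write_events_csv(sacc, file.path(out_dir, "saccade_events.csv")),
      write_saccade_stats(sacc, file.path(out_dir, "saccade_stats.csv"))
    )
    cfg_path <- file.path(out_dir, "config.json")
    write_run_config(config, cfg_path)
    c(paths, cfg_path)
  })

  manifest <- stage("manifest", {
    man <- list(
      package = "gazeloop",
      version = as.character(utils::packageVersion("gazeloop")),
      seed = config$seed,
      files = as.list(stats::setNames(
        unname(tools::md5sum(sort(files))), basename(sort(files))))
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(list(averages = ident, decomposition = dec, gm = replay,
                 saccades = sacc, manifest = manifest))
}

gm_as_frf <- function(gm_tbl) {
  new_frf(gm_tbl$freq_hz, gm_tbl$Gm, gm_tbl$is_stim, gm_tbl$valid)
}

mean_body_response <- function(free_trials, i) {
  # mean body trajectory across flies for battery trial i, used as the
  # prescribed motion in replay simulations
  b <- rowMeans(sapply(free_trials, function(tt) tt[[i]]$body_deg))
  tibble::tibble(time_s = free_trials[[1]][[i]]$time_s, body_deg = b)
}

# replay the mean body motion of each battery trial on the motor for
# `n_replay` animals and average the B-to-H transform across them
replay_frf <- function(components, free_trials, freqs, gate, config,
                       n_replay = 6L) {
  per_fly <- lapply(seq_len(n_replay), function(fly) {
    vals <- complex(length(freqs))
    ok <- logical(length(freqs))
    for (i in seq_along(freqs)) {
      body <- mean_body_response(free_trials, i)
      cfg <- sim_config(mode = "motor_replay", mech_gate = gate,
                        noise_std_head = config$noise_std,
                        noise_std_body = 0,
                        head_limit = config$head_limit,
                        sample_rate = config$sample_rate,
                        transient_discard = config$transient,
                        seed = trial_seed(config$seed, fly, i,
                                          5L + as.integer(round(gate * 10))))
      tr <- simulate_motor_replay(components, body, cfg)
      pp <- preprocess(tr[, c("time_s", "body_deg", "head_deg")])
      fr <- frf(pp[, c("time_s", "body_deg")], pp[, c("time_s", "head_deg")],
                stim_freqs = freqs[i])
      vals[i] <- fr$response[fr$is_stim]
      ok[i] <- fr$valid[fr$is_stim]
    }
    new_frf(freqs, vals, rep(TRUE, length(freqs)), ok)
  })
  average_across_flies(per_fly)
}

write_decomposition_csv <- function(terms, path) {
  df <- terms[terms$is_stim, ]
  out <- data.frame(
    freq_hz = df$freq_hz,
    head_visual_gain = Mod(df$term_head_visual),
    head_visual_phase_deg = wrap_deg(Arg(df$term_head_visual) * 180 / pi),
    body_visual_gain = Mod(df$term_body_visual),
    body_visual_phase_deg = wrap_deg(Arg(df$term_body_visual) * 180 / pi),
    body_mech_gain = Mod(df$term_body_mech),
    body_mech_phase_deg = wrap_deg(Arg(df$term_body_mech) * 180 / pi),
    total_gain = df$gain, total_phase_deg = df$phase_deg,
    valid = df$valid)
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_gm_csv <- function(gm_self, replay, path) {
  df <- gm_self[gm_self$is_stim, ]
  out <- data.frame(
    freq_hz = df$freq_hz,
    gm_self_gain = df$gain, gm_self_phase_deg = df$phase_deg,
    gm_external_gain = replay$external$gain[replay$external$is_stim],
    gm_external_low_confidence =
      replay$external$low_confidence[replay$external$is_stim],
    valid = df$valid)
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_events_csv <- function(sacc, path) {
  ev <- dplyr::bind_rows(
    dplyr::mutate(sacc$events_free, condition = "body_free"),
    dplyr::mutate(sacc$events_fixed, condition = "body_fixed"))
  utils::write.csv(as.data.frame(ev), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_saccade_stats <- function(sacc, path) {
  st <- dplyr::bind_rows(
    dplyr::mutate(sacc$stats_free, condition = "body_free"),
    dplyr::mutate(sacc$stats_fixed, condition = "body_fixed"))
  utils::write.csv(as.data.frame(st), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
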