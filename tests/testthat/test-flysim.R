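test_that("the default fly is a stable loop with the expected tuning", {
  fly <- default_fly()
  expect_s3_class(fly, "loop_components")
  expect_silent(check_loop_stability(fly))
  truth <- closed_loop_truth(fly, c(0.7, 10.6))
  # body is low-pass: closed-loop body gain falls from 0.7 to 10.6 Hz
  expect_gt(Mod(truth$B_over_R[1]), Mod(truth$B_over_R[2]))
  # mechanosensory transform is high-pass
  expect_gt(Mod(truth$G_head_M[2]), Mod(truth$G_head_M[1]))
})

test_that("zero input and zero noise give a zero trial", {
  zero <- single_sine(1, v_norm = 0, duration = 6)
  tr <- simulate_trial(default_fly(), zero, noise_free_config())
  expect_true(all(tr$head_deg == 0))
  expect_true(all(tr$body_deg == 0))
})

test_that("body-fixed mode clamps the body exactly", {
  tr <- simulate_trial(default_fly(), single_sine(2.1, duration = 6),
                       noise_free_config(mode = "body_fixed"))
  expect_true(all(tr$body_deg == 0))
})

test_that("pre-noise bookkeeping E + H + B - R = 0 holds to machine precision", {
  tr <- quick_trial()
  expect_lt(max(abs(tr$error_deg + tr$head_deg + tr$body_deg -
                      tr$stimulus_deg)), 1e-12)
})

test_that("identical seeds give bit-identical trials", {
  fly <- default_fly()
  stim <- single_sine(2.1, duration = 6)
  cfg <- sim_config(seed = 99L)
  a <- simulate_trial(fly, stim, cfg)
  b <- simulate_trial(fly, stim, cfg)
  expect_identical(a$head_deg, b$head_deg)
  expect_identical(a$body_deg, b$body_deg)
})

test_that("without saturation and noise the loop is linear in the stimulus", {
  fly <- default_fly()
  cfg <- noise_free_config(saturation = FALSE)
  tr1 <- simulate_trial(fly, single_sine(1.5, v_norm = 100, duration = 8), cfg)
  tr2 <- simulate_trial(fly, single_sine(1.5, v_norm = 200, duration = 8), cfg)
  expect_equal(tr2$head_deg, 2 * tr1$head_deg, tolerance = 1e-9)
  expect_equal(tr2$body_deg, 2 * tr1$body_deg, tolerance = 1e-9)
})

test_that("simulated closed loop matches the analytic solution at 2.1 Hz", {
  fly <- default_fly()
  tr <- quick_trial()
  pp <- preprocess(tr[, c("time_s", "stimulus_deg", "head_deg")])
  fr <- frf(pp[, c("time_s", "stimulus_deg")], pp[, c("time_s", "head_deg")],
            stim_freqs = 2.1)
  est <- fr$response[fr$is_stim]
  truth <- closed_loop_truth(fly, 2.1)$H_over_R
  expect_lt(abs(Mod(est) / Mod(truth) - 1), 0.01)
  dphase <- (Arg(est) - Arg(truth)) * 180 / pi
  expect_lt(abs((dphase + 180) %% 360 - 180), 1)
})

test_that("a large low-frequency stimulus saturates the body-fixed head", {
  tr <- simulate_trial(default_fly(),
                       single_sine(0.7, v_norm = 400, duration = 8),
                       noise_free_config(mode = "body_fixed"))
  at_limit <- abs(abs(tr$head_deg) - 15) < 1e-9
  expect_gt(mean(at_limit), 0.1) # sustained plateaus at +/- head_limit
  expect_lte(max(abs(tr$head_deg)), 15)
})

test_that("an unstable loop is rejected with a diagnostic", {
  fly <- default_fly()
  bad <- loop_components(
    C_head_V = tf_zpk(poles = -1 / 0.05, gain = 200 / 0.05, delay_s = 0.030),
    C_head_M = fly$C_head_M, C_body_V = fly$C_body_V,
    C_body_M = fly$C_body_M, P_head = fly$P_head, P_body = fly$P_body)
  expect_error(simulate_trial(bad, single_sine(2.1, duration = 6),
                              noise_free_config()),
               "unstable")
})

test_that("motor replay: gate 0 silences the head; gain scales with the gate", {
  fly <- default_fly()
  body <- single_sine(2.1, v_norm = 100, duration = 10)
  names(body)[2] <- "body_deg"
  h_at_gate <- function(gate) {
    cfg <- sim_config(mode = "motor_replay", mech_gate = gate,
                      noise_std_head = 0, noise_std_body = 0,
                      transient_discard = 2)
    tr <- simulate_motor_replay(fly, body, cfg)
    pp <- preprocess(tr[, c("time_s", "body_deg", "head_deg")])
    fr <- frf(pp[, c("time_s", "body_deg")], pp[, c("time_s", "head_deg")],
              stim_freqs = 2.1)
    fr$response[fr$is_stim]
  }
  cfg0 <- sim_config(mode = "motor_replay", mech_gate = 0,
                     noise_std_head = 0, noise_std_body = 0)
  tr0 <- simulate_motor_replay(fly, body, cfg0)
  expect_true(all(tr0$head_deg == 0))
  ratio <- Mod(h_at_gate(1)) / Mod(h_at_gate(0.1))
  expect_equal(ratio, 10, tolerance = 1e-6)
})

test_that("the passive (anesthetized) head response is smaller than the active one", {
  fly <- default_fly()
  body <- single_sine(1, v_norm = 100, duration = 10)
  names(body)[2] <- "body_deg"
  cfg <- sim_config(mode = "motor_replay", mech_gate = 0.1,
                    noise_std_head = 0, noise_std_body = 0,
                    transient_discard = 2)
  active <- simulate_motor_replay(fly, body, cfg)
  passive <- simulate_motor_replay(fly, body, cfg, passive = TRUE)
  expect_lt(max(abs(passive$head_deg)), max(abs(active$head_deg)))
  expect_error(simulate_motor_replay(fly, body[0, ], cfg), "empty")
})

test_that("saccade generator: bookkeeping, durations, and determinism", {
  params <- saccade_gen_params()
  empty <- generate_saccade_trials(params, 0L)
  expect_length(empty$trials, 0L)
  expect_identical(nrow(empty$truth), 0L)
  g <- generate_saccade_trials(params, 10L, seed = 5L)
  expect_length(g$trials, 10L)
  # ground-truth log matches the injections, durations under 200 ms
  expect_gt(nrow(g$truth), 0L)
  expect_true(all(g$truth$duration_s < 0.2))
  g2 <- generate_saccade_trials(params, 10L, seed = 5L)
  expect_identical(g$trials[[3]]$head_deg, g2$trials[[3]]$head_deg)
})
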