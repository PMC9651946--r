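mk_frf <- function(values, grid = seq_along(values)) {
  new_frf(grid, as.complex(values), rep(TRUE, length(values)),
          rep(TRUE, length(values)))
}

random_frf <- function(n, grid = seq_len(n)) {
  mk_frf(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)), grid)
}

test_that("body-free closed loop: hand-checked values and limiting cases", {
  # Gv = 1, Gm = 1, B/R = 0.5: 0.5 - 0.25 + 0.25 = 0.5
  out <- closed_loop_head_free(mk_frf(1), mk_frf(1), mk_frf(0.5))
  expect_equal(out$total, 0.5 + 0i)
  expect_equal(out$term_head_visual, 0.5 + 0i)
  expect_equal(out$term_body_visual, -0.25 + 0i)
  expect_equal(out$term_body_mech, 0.25 + 0i)
  # Gm = 0 and B/R = 0 reduces exactly to the body-fixed form
  gv <- mk_frf(2 * exp(-1i * 30 * pi / 180))
  free <- closed_loop_head_free(gv, mk_frf(0), mk_frf(0))
  fixed <- closed_loop_head_fixed(gv)
  expect_identical(free$total, fixed$response)
  # high-gain limit: H/R -> 1 - B/R
  big <- closed_loop_head_free(mk_frf(1e6), mk_frf(0), mk_frf(0.3))
  expect_equal(big$total, 0.7 + 0i, tolerance = 1e-5)
})

test_that("body-fixed closed loop matches direct complex evaluation", {
  expect_equal(closed_loop_head_fixed(mk_frf(1))$response, 0.5 + 0i)
  expect_equal(closed_loop_head_fixed(mk_frf(0))$response, 0 + 0i)
  z <- 2 * exp(-1i * 30 * pi / 180)
  expect_equal(closed_loop_head_fixed(mk_frf(z))$response, z / (1 + z))
  # near-singular loop (Gv ~ -1) is flagged, not divided
  out <- closed_loop_head_fixed(mk_frf(c(1, -1 + 1e-12i)))
  expect_true(out$valid[1])
  expect_false(out$valid[2])
})

test_that("visual-only prediction: body feedback cancels the stimulus at unity B/R", {
  gv <- mk_frf(c(3, 3))
  expect_equal(predict_visual_only(gv, mk_frf(c(0, 0)))$response,
               closed_loop_head_fixed(gv)$response)
  pred <- predict_visual_only(gv, mk_frf(c(1, 1)))
  expect_equal(pred$gain, c(0, 0), tolerance = 1e-12)
})

test_that("visual-only prediction agrees with a simulation with the gate closed", {
  fly <- default_fly()
  f <- 2.1
  tr <- simulate_trial(fly, single_sine(f, duration = 12),
                       noise_free_config(mech_gate = 0))
  pp <- preprocess(tr[, c("time_s", "stimulus_deg", "head_deg")])
  fr <- frf(pp[, c("time_s", "stimulus_deg")], pp[, c("time_s", "head_deg")], f)
  sim_hr <- fr$response[fr$is_stim]
  truth <- closed_loop_truth(fly, f, mech_gate = 0)
  pred <- predict_visual_only(mk_frf(truth$G_head_V, f),
                              mk_frf(truth$B_over_R, f))
  expect_lt(abs(Mod(sim_hr) / pred$gain - 1), 0.02)
})

test_that("mechanosensory-only prediction and the E-to-H round trip", {
  expect_equal(predict_mechano_only(mk_frf(1))$response, 0.5 + 0i)
  expect_equal(predict_mechano_only(mk_frf(0))$response, 0 + 0i)
  # consistency in the no-body-visual configuration (E = R - H): with
  # GvM = Gv + Gm * B/E, the one-term form GvM/(1+GvM) equals the two-term
  # closed loop Gv/(1+Gv) + Gm/(1+Gv) * B/R for a loop-consistent B/R
  set.seed(4)
  gv <- random_frf(20)$response
  gm <- random_frf(20)$response
  be <- random_frf(20)$response # body motion per unit sensory error
  gvm <- gv + gm * be
  br <- be / (1 + gvm)
  two_term <- gv / (1 + gv) + gm * br / (1 + gv)
  one_term <- predict_mechano_only(mk_frf(gvm, 1:20))$response
  expect_lt(max(Mod(one_term - two_term)), 1e-9)
})

test_that("self-generated Gm estimation inverts the closed loop exactly", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 50
    gv <- random_frf(n); gm <- random_frf(n); br <- random_frf(n)
    hr <- closed_loop_head_free(gv, gm, br)
    est <- estimate_Gm_self(gv, mk_frf(hr$total, seq_len(n)), br)
    expect_lt(max(Mod(est$Gm - gm$response)), 1e-9)
    # the alternative (E/B) form agrees with the primary form
    expect_lt(max(Mod(est$Gm - est$Gm_alt)), 1e-8)
  }
  # a purely visual head response yields Gm = 0
  gv <- mk_frf(c(1.2, 0.8)); br <- mk_frf(c(0.6, 0.3))
  hr_vis <- predict_visual_only(gv, br)
  est0 <- estimate_Gm_self(gv, hr_vis, br)
  expect_lt(max(Mod(est0$Gm)), 1e-9)
})

test_that("externally generated Gm: conventions and degenerate agreement", {
  gv <- mk_frf(c(0.5, 0.5)); hb0 <- mk_frf(c(0, 0))
  est <- estimate_Gm_external(gv, hb0)
  expect_equal(est$Gm, c(0 + 0i, 0 + 0i))
  # with Gv = 0 both conventions coincide at H/B
  hb <- mk_frf(c(0.3 + 0.1i, 0.2))
  est2 <- estimate_Gm_external(mk_frf(c(0, 0)), hb)
  expect_equal(est2$Gm_printed, est2$Gm_rederived)
  expect_equal(est2$Gm, hb$response)
  # the two conventions differ only through (1 -/+ Gv)
  est3 <- estimate_Gm_external(gv, hb)
  expect_equal(est3$Gm_printed / est3$Gm_rederived,
               (1 - gv$response) / (1 + gv$response))
})

test_that("feedback weighting: null case, scalar ratio, group property", {
  set.seed(6)
  gv <- random_frf(15)
  expect_equal(feedback_weighting(gv, gv)$gain, rep(1, 15))
  expect_equal(feedback_weighting(gv, gv)$phase_deg, rep(0, 15))
  scaled <- mk_frf(0.4 * gv$response, gv$freq_hz)
  expect_equal(feedback_weighting(scaled, gv)$gain, rep(0.4, 15),
               tolerance = 1e-12)
  a <- random_frf(15); b <- random_frf(15); c <- random_frf(15)
  lhs <- feedback_weighting(a, b)$response * feedback_weighting(b, c)$response
  expect_equal(lhs, feedback_weighting(a, c)$response, tolerance = 1e-12)
})

test_that("on the default fly the decomposition reproduces the expected ordering", {
  fly <- default_fly()
  f7 <- battery_freqs
  truth <- closed_loop_truth(fly, f7)
  gv <- mk_frf(truth$G_head_V, f7)
  gm <- mk_frf(truth$G_head_M, f7)
  br <- mk_frf(truth$B_over_R, f7)
  terms <- closed_loop_head_free(gv, gm, br)
  # body visual feedback bites hardest at the lowest frequencies
  rel_bv <- Mod(terms$term_body_visual) / Mod(terms$term_head_visual)
  expect_gt(rel_bv[1], rel_bv[length(f7)])
  # mechanosensory feedback damps: folding it in lowers predicted head gain
  # across the battery relative to the visual-only prediction
  pred_vis <- predict_visual_only(gv, br)
  expect_true(all(terms$gain <= pred_vis$gain + 1e-12))
})
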