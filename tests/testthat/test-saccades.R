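test_that("detection ignores noise and smooth oscillation below threshold", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  set.seed(7)
  flat <- tibble::tibble(time_s = t, head = rnorm(length(t), sd = 0.05))
  expect_identical(nrow(suppressWarnings(detect_saccades(flat))), 0L)
  # 1 Hz, 5 deg oscillation peaks at 2*pi*5 ~ 31 deg/s, under a 100 deg/s bar
  smooth <- tibble::tibble(time_s = t, head = 5 * sin(2 * pi * t))
  expect_identical(nrow(detect_saccades(smooth, vel_threshold = 100)), 0L)
})

test_that("injected saccades are all recovered with accurate onsets", {
  params <- saccade_gen_params(noise_sd = 0)
  g <- generate_saccade_trials(params, 5L, seed = 11L)
  for (k in seq_along(g$trials)) {
    ev <- detect_saccades(g$trials[[k]])
    truth_k <- g$truth[g$truth$trial == k, ]
    expect_identical(nrow(ev), nrow(truth_k))
    expect_true(all(abs(ev$onset_s - truth_k$onset_s) <= 0.02))
  }
})

test_that("detection is sign-symmetric", {
  params <- saccade_gen_params()
  g <- generate_saccade_trials(params, 3L, seed = 13L)
  tr <- g$trials[[1]]
  ev <- detect_saccades(tr)
  flipped <- tr
  flipped$head_deg <- -flipped$head_deg
  ev2 <- detect_saccades(flipped)
  expect_identical(nrow(ev), nrow(ev2))
  expect_equal(ev$amplitude_deg, ev2$amplitude_deg)
  expect_equal(ev$direction, -ev2$direction)
})

test_that("exponential decay fits recover tau", {
  t <- seq(0, 2 - 0.01, by = 0.01)
  d <- tibble::tibble(time_s = t, head = 8 * exp(-t / 0.1))
  ev <- list(offset_s = 0)
  fit <- fit_decay_tau(d, ev, window = 1)
  expect_equal(fit$tau, 0.1, tolerance = 1e-6)
  expect_true(fit$reliable)
  # noisy recovery: median of many fits lands within 10%
  set.seed(8)
  taus <- replicate(100, {
    y <- 8 * exp(-t / 0.1) + rnorm(length(t), sd = 0.4)
    fit_decay_tau(tibble::tibble(time_s = t, head = y), ev, window = 1)$tau
  })
  expect_lt(abs(median(taus, na.rm = TRUE) / 0.1 - 1), 0.1)
  # constant window: degenerate, flagged unreliable
  flatfit <- fit_decay_tau(tibble::tibble(time_s = t, head = rep(2, length(t))),
                           ev, window = 1)
  expect_false(flatfit$reliable)
  # truncated window is rejected
  expect_error(fit_decay_tau(d, list(offset_s = 1.5), window = 1), "window")
})

test_that("population statistics pool and summarize correctly", {
  ev <- gazeloop:::empty_saccade_tbl()
  expect_error(saccade_population_stats(ev), "no events")
  one <- tibble::add_row(ev, onset_s = 1, offset_s = 1.05, duration_s = 0.05,
                         amplitude_deg = 10, peak_velocity_dps = 300,
                         direction = 1)
  st <- saccade_population_stats(one)
  amp <- st[st$metric == "amplitude_deg", ]
  expect_equal(amp$mean, 10); expect_equal(amp$median, 10); expect_equal(amp$sd, 0)
  two <- tibble::add_row(one, onset_s = 2, offset_s = 2.05, duration_s = 0.05,
                         amplitude_deg = 20, peak_velocity_dps = 400,
                         direction = -1)
  st2 <- saccade_population_stats(two)
  expect_equal(st2$mean[st2$metric == "amplitude_deg"], 15)
})

test_that("detected saccade durations stay under 200 ms on generator defaults", {
  g <- generate_saccade_trials(saccade_gen_params(), 20L, seed = 21L)
  ev <- analyze_saccade_trials(g$trials)
  expect_gt(nrow(ev), 20)
  expect_lt(median(ev$duration_s), 0.2)
})

test_that("group comparison separates 8x shifted tau distributions", {
  set.seed(9)
  mk_group <- function(med) {
    ev <- gazeloop:::empty_saccade_tbl()
    n <- 300
    tibble::add_row(ev, onset_s = seq_len(n), offset_s = seq_len(n) + 0.05,
                    duration_s = 0.05, amplitude_deg = 10,
                    peak_velocity_dps = 300, direction = 1) |>
      dplyr::mutate(tau_s = med * exp(rnorm(n, 0, 0.3)))
  }
  a <- mk_group(0.8); b <- mk_group(0.1)
  cmp <- compare_groups(a, b, "tau_s")
  expect_lt(cmp$wilcoxon$p.value, 1e-3)
  expect_lt(cmp$t_test$p.value, 1e-3)
  expect_equal(cmp$median_ratio, 8, tolerance = 0.2)
  # identical groups: rank-sum p near 1
  same <- compare_groups(a, a, "tau_s")
  expect_gt(same$wilcoxon$p.value, 0.9)
  expect_error(compare_groups(a, b, "not_a_metric"), "absent")
  td <- tidy(cmp)
  expect_identical(td$test, c("wilcoxon_rank_sum", "t_test"))
  expect_true(all(td$p_value < 1e-3))
})

test_that("variance comparison: F-test behavior and symmetry", {
  set.seed(10)
  a <- rnorm(500, sd = 2); b <- rnorm(500, sd = 6)
  ft <- compare_variances(a, b)
  expect_lt(ft$p.value, 1e-3)
  self <- compare_variances(a, a)
  expect_equal(unname(self$statistic), 1)
  fwd <- compare_variances(a, b); rev <- compare_variances(b, a)
  expect_equal(unname(fwd$statistic), 1 / unname(rev$statistic))
  expect_equal(fwd$p.value, rev$p.value)
  expect_error(compare_variances(rep(1, 5), b), "zero variance")
})
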