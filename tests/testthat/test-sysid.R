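test_that("preprocess removes a linear ramp and rejects low sample rates", {
  t <- seq(0, 5 - 0.01, by = 0.01)
  ramp <- tibble::tibble(time_s = t, angle = 2 + 3 * t)
  out <- preprocess(ramp)
  expect_lt(max(abs(out$angle)), 1e-9 * diff(range(ramp$angle)))
  slow <- tibble::tibble(time_s = seq(0, 10, by = 1 / 60),
                         angle = rnorm(601))
  expect_error(preprocess(slow), "sample rate")
})

test_that("the low-pass passes 5 Hz and strongly attenuates 45 Hz", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  amp_after <- function(f) {
    d <- preprocess(tibble::tibble(time_s = t, angle = sin(2 * pi * f * t)))
    fit <- lssa_fit(d, f)
    fit$amplitude
  }
  expect_equal(amp_after(5), 1, tolerance = 0.02)
  expect_lt(amp_after(45), amp_after(5) / 10)
})

test_that("chirp-z spectrum equals the direct DFT sum on random signals", {
  set.seed(1)
  for (rep in 1:5) {
    x <- rnorm(200)
    grid <- seq(0, 50, by = 0.05)
    sp <- czt_spectrum(x, sample_rate = 100)
    oracle <- dft_oracle(x, 100, grid)
    expect_lt(max(Mod(sp$spectrum - oracle)), 1e-9)
  }
})

test_that("chirp-z normalization: unit sine gives magnitude 1 and its phase", {
  stim <- single_sine(2.1, v_norm = 2.1 * 2 * pi, duration = 20)
  sp <- czt_spectrum(stim)
  i <- which(abs(sp$freq_hz - 2.1) < 1e-9)
  expect_equal(sp$amplitude[i], 1, tolerance = 1e-6)
  expect_lt(abs(sp$phase_deg[i]), 1e-3)
  # zero signal, zero spectrum
  z <- czt_spectrum(rep(0, 500), sample_rate = 100)
  expect_true(all(z$amplitude == 0))
  # linearity
  t <- seq(0, 10 - 0.01, by = 0.01)
  x1 <- sin(2 * pi * 1.5 * t); x2 <- 0.4 * sin(2 * pi * 4.2 * t + 1)
  s1 <- czt_spectrum(x1, sample_rate = 100)$spectrum
  s2 <- czt_spectrum(x2, sample_rate = 100)$spectrum
  s12 <- czt_spectrum(x1 + x2, sample_rate = 100)$spectrum
  expect_lt(max(Mod(s12 - s1 - s2)), 1e-9)
  expect_error(czt_spectrum(x1, sample_rate = 100, df = 0), "df")
})

test_that("frf identity, pure delay, and analytic filter responses", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  x <- tibble::tibble(time_s = t,
                      v = sin(2 * pi * 1 * t) + sin(2 * pi * 3.5 * t + 0.7))
  # identity
  fr <- frf(x, x, stim_freqs = c(1, 3.5))
  expect_equal(fr$gain[fr$is_stim], c(1, 1), tolerance = 1e-9)
  expect_equal(fr$phase_deg[fr$is_stim], c(0, 0), tolerance = 1e-9)
  # 50 ms delay -> phase -360 * f * 0.05 deg
  y <- tibble::tibble(time_s = t,
                      v = sin(2 * pi * 1 * (t - 0.05)) +
                        sin(2 * pi * 3.5 * (t - 0.05) + 0.7))
  fr <- frf(x, y, stim_freqs = c(1, 3.5))
  expect_equal(fr$phase_deg[fr$is_stim], -360 * c(1, 3.5) * 0.05,
               tolerance = 0.05)
  # known first-order low-pass (5 Hz corner), steady-state response
  fc <- 5
  lp_resp <- function(f) 1 / (1 + 1i * f / fc)
  y2 <- tibble::tibble(time_s = t,
                       v = Mod(lp_resp(1)) * sin(2 * pi * 1 * t + Arg(lp_resp(1))) +
                         Mod(lp_resp(3.5)) *
                           sin(2 * pi * 3.5 * t + 0.7 + Arg(lp_resp(3.5))))
  fr2 <- frf(x, y2, stim_freqs = c(1, 3.5))
  expect_equal(fr2$gain[fr2$is_stim], Mod(lp_resp(c(1, 3.5))),
               tolerance = 0.01)
  dph <- fr2$phase_deg[fr2$is_stim] - Arg(lp_resp(c(1, 3.5))) * 180 / pi
  expect_true(all(abs(dph) < 1))
})

test_that("frf flags frequencies where the input is effectively absent", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  x <- tibble::tibble(time_s = t, v = sin(2 * pi * 2 * t))
  y <- tibble::tibble(time_s = t, v = sin(2 * pi * 2 * t))
  fr <- frf(x, y, stim_freqs = c(2, 7))
  expect_true(fr$valid[fr$freq_hz == 2])
  expect_false(fr$valid[fr$freq_hz == 7])
  expect_true(is.na(fr$response[fr$freq_hz == 7]))
})

test_that("compensation error endpoints and symmetry", {
  mk <- function(v) new_frf(c(1, 2), c(v, v), c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(compensation_error(mk(1 + 0i))$comp_err, c(0, 0))
  expect_equal(compensation_error(mk(0 + 0i))$comp_err, c(1, 1))
  expect_equal(compensation_error(mk(0 + 1i))$comp_err, rep(sqrt(2), 2),
               tolerance = 1e-12)
  # conjugating X (negating phase) leaves epsilon unchanged
  set.seed(2)
  z <- complex(real = rnorm(10), imaginary = rnorm(10))
  g <- new_frf(1:10, z, rep(TRUE, 10), rep(TRUE, 10))
  gc <- new_frf(1:10, Conj(z), rep(TRUE, 10), rep(TRUE, 10))
  expect_equal(compensation_error(g)$comp_err, compensation_error(gc)$comp_err)
})

test_that("coherence: identical trials give 1, independent noise stays low", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  set.seed(3)
  mk_in <- function() tibble::tibble(time_s = t, v = sin(2 * pi * 2.1 * t))
  ins <- replicate(20, mk_in(), simplify = FALSE)
  expect_equal(coherence(ins, ins, 2.1)$coherence, 1, tolerance = 1e-9)
  outs_noise <- replicate(20, tibble::tibble(time_s = t, v = rnorm(length(t))),
                          simplify = FALSE)
  expect_lt(coherence(ins, outs_noise, 2.1)$coherence, 0.2)
  # moderate noise lands strictly in between
  outs_mid <- lapply(seq_len(20), function(i) {
    tibble::tibble(time_s = t, v = sin(2 * pi * 2.1 * t) + rnorm(length(t), sd = 2))
  })
  ch <- coherence(ins, outs_mid, 2.1)$coherence
  expect_gt(ch, 0.2); expect_lt(ch, 1)
  expect_error(coherence(ins[1], ins[1], 2.1), "2 trials")
})

test_that("LSSA recovers a clipped sinusoid once saturation is masked", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  clean <- sin(2 * pi * 1.5 * t)
  clipped <- pmin(pmax(clean, -0.8), 0.8)
  d <- tibble::tibble(time_s = t, angle = clipped)
  fit_clean <- lssa_fit(tibble::tibble(time_s = t, angle = clean), 1.5)
  expect_equal(fit_clean$amplitude, 1, tolerance = 1e-6)
  mask <- abs(clipped) >= 0.8 - 1e-12
  fit_masked <- lssa_fit(d, 1.5, exclude_mask = mask)
  expect_equal(fit_masked$amplitude, 1, tolerance = 0.02)
  fit_unmasked <- lssa_fit(d, 1.5)
  expect_lt(fit_unmasked$amplitude, 1)
  expect_error(lssa_fit(d, 1.5, exclude_mask = rep(TRUE, length(t))),
               "unmasked")
})

test_that("saturation correction recovers a 20 deg sine clipped at 15 deg", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  d <- tibble::tibble(time_s = t,
                      head = pmin(pmax(20 * sin(2 * pi * 0.7 * t), -15), 15))
  sc <- saturation_correct(d, 0.7, limit = 15)
  expect_equal(sc$amplitude_corrected, 20, tolerance = 0.05)
  expect_lt(sc$amplitude_raw, sc$amplitude_corrected)
  # unsaturated trace: empty mask, factor ~ 1
  d2 <- tibble::tibble(time_s = t, head = 5 * sin(2 * pi * 0.7 * t))
  sc2 <- saturation_correct(d2, 0.7, limit = 15)
  expect_false(any(sc2$mask))
  expect_equal(sc2$factor, 1, tolerance = 1e-6)
})

test_that("averaging across flies uses circular statistics for phase", {
  mk <- function(gain, phase) {
    new_frf(c(1, 2), gain * exp(1i * phase * pi / 180),
            c(TRUE, TRUE), c(TRUE, TRUE))
  }
  # wrapped phases average to 180, not 0
  avg <- average_across_flies(list(mk(1, 179), mk(1, -179)))
  expect_equal(abs(avg$phase_deg), c(180, 180))
  # two-point gain statistics
  avg2 <- average_across_flies(list(mk(1, 0), mk(3, 0)))
  expect_equal(avg2$gain, c(2, 2))
  expect_equal(avg2$gain_sd, rep(sqrt(2), 2))
  # identical inputs: zero dispersion
  avg3 <- average_across_flies(list(mk(2, 30), mk(2, 30)))
  expect_equal(avg3$gain_sd, c(0, 0))
  expect_equal(avg3$phase_sd_deg, c(0, 0), tolerance = 1e-6)
  expect_error(average_across_flies(list(mk(1, 0), new_frf(3, 1 + 0i, TRUE, TRUE))),
               "grid")
})

test_that("Monte Carlo uncertainty propagation matches first-order theory", {
  grid <- c(1, 2, 3)
  mk <- function(gain, gsd) {
    fr <- new_frf(grid, rep(gain + 0i, 3), rep(TRUE, 3), rep(TRUE, 3))
    fr$gain_sd <- rep(gsd, 3)
    fr$phase_sd_deg <- rep(0, 3)
    fr
  }
  prod_expr <- function(x) x$a * x$b
  # zero input dispersion -> zero output dispersion
  out0 <- propagate_uncertainty(list(a = mk(1, 0), b = mk(1, 0)), prod_expr,
                                n_draws = 200, seed = 1)
  expect_equal(out0$gain_sd, rep(0, 3), tolerance = 1e-12)
  # small relative SDs add in quadrature for a product
  out <- propagate_uncertainty(list(a = mk(2, 0.04), b = mk(1, 0.03)),
                               prod_expr, n_draws = 4000, seed = 2)
  expect_equal(out$gain_sd / out$gain, rep(sqrt(0.02^2 + 0.03^2), 3),
               tolerance = 0.15)
  # determinism under the seed
  outa <- propagate_uncertainty(list(a = mk(2, 0.04), b = mk(1, 0.03)),
                                prod_expr, n_draws = 500, seed = 9)
  outb <- propagate_uncertainty(list(a = mk(2, 0.04), b = mk(1, 0.03)),
                                prod_expr, n_draws = 500, seed = 9)
  expect_identical(outa$gain_sd, outb$gain_sd)
  expect_error(propagate_uncertainty(list(a = mk(1, 0)), prod_expr,
                                     n_draws = 50), "n_draws")
})
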