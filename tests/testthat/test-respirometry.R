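test_that("oxygen trace validation catches malformed inputs", {
  expect_error(oxygen_trace(c(0, 2, 2), c(8, 8, 8)), "strictly increasing")
  expect_error(oxygen_trace(c(0, 2), c(8, -1)), "positive")
  expect_error(oxygen_trace(0, 8), "at least 2")
  expect_warning(oxygen_trace(c(0, 2, 40), c(8, 8, 8)), "gap")
})

test_that("segmentation arithmetic matches the cycle structure", {
  t <- seq(0, 3600 - 2, by = 2)
  tr <- oxygen_trace(t, rep(8, length(t)))
  w <- segment_trace(tr, phase_schedule(540, 180, 60))
  expect_length(w, 5)
  expect_true(all(vapply(w, nrow, integer(1)) == 240))  # 480 s at 2 s

  w0 <- segment_trace(tr, phase_schedule(540, 180, 0))
  expect_true(all(vapply(w0, nrow, integer(1)) == 270))  # full 540 s

  short <- oxygen_trace(seq(0, 400, 2), rep(8, 201))
  expect_warning(res <- segment_trace(short, phase_schedule()), "shorter")
  expect_length(res, 0)
})

test_that("slope fitting equals the closed-form OLS solution", {
  # exact line
  tr <- make_linear_trace(8, -1, 480)
  f <- fit_slope(tr)
  expect_equal(f$slope_mg_l_h, -1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # constant O2
  fc <- fit_slope(data.frame(time_s = seq(0, 100, 2), o2_mg_l = 7.5))
  expect_equal(fc$slope_mg_l_h, 0)
  expect_equal(fc$r_squared, 1)

  # random noisy inputs agree with the closed form exactly
  set.seed(7)
  for (i in 1:20) {
    t <- seq(0, 478, 2)
    o2 <- 8 - runif(1, 0, 2) * t / 3600 + rnorm(length(t), 0, 0.02)
    f <- fit_slope(data.frame(time_s = t, o2_mg_l = o2))
    o <- oracle_ols(t, o2)
    expect_equal(f$slope_mg_l_h, o$slope_mg_l_h, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-10)
  }

  expect_error(fit_slope(data.frame(time_s = 1:5, o2_mg_l = rep(8, 5))),
               "at least 10")
})

test_that("slope-to-MO2 conversion uses the effective volume", {
  geom <- chamber_geometry(1.29)
  expect_equal(geom$v_eff_l, 0.09871)
  f <- fit_slope(make_linear_trace(8, -1, 480))
  rec <- slope_to_mo2(f, geom)
  expect_equal(rec$mo2_mg_h, 0.09871, tolerance = 1e-9)

  # linearity in effective volume
  geom2 <- chamber_geometry(1.29, chamber_volume_l = 0.1 + 0.09871)
  expect_equal(slope_to_mo2(f, geom2)$mo2_mg_h, 2 * 0.09871,
               tolerance = 1e-9)

  # zero slope, and positive-slope flagging
  f0 <- fit_slope(data.frame(time_s = seq(0, 100, 2), o2_mg_l = 7.5))
  expect_equal(slope_to_mo2(f0, geom)$mo2_mg_h, 0)
  fpos <- fit_slope(make_linear_trace(7, +1, 480))
  expect_false(slope_to_mo2(fpos, geom)$valid)

  expect_error(chamber_geometry(200, 0.1), "does not fit")
})

test_that("background model interpolates linearly between pre and post means", {
  bg <- estimate_background(c(0, 0), c(-0.02, -0.02), 0, 10000)
  expect_equal(bg$pre_slope, 0)
  expect_equal(bg$post_slope, 0.02)
  expect_equal(background_at(bg, 5000), 0.01)
  expect_warning(background_at(bg, 20000), "outside")
  expect_error(estimate_background(numeric(0), -0.02, 0, 100), "pre")
})

test_that("background correction is the identity at zero background and linear otherwise", {
  geom <- chamber_geometry(1.29)
  recs <- data.frame(t_mid_s = c(1000, 5000), mo2_mg_h = c(0.6, 0.7),
                     r2 = 1, valid = TRUE, corrected = FALSE)
  zero <- estimate_background(0, 0, 0, 10000)
  out0 <- correct_background(recs, zero, geom)
  expect_equal(out0$mo2_mg_h, recs$mo2_mg_h)
  expect_true(all(out0$corrected))

  unif <- estimate_background(-0.02, -0.02, 0, 10000)
  out <- correct_background(recs, unif, geom)
  expect_equal(out$mo2_mg_h, recs$mo2_mg_h - 0.02 * geom$v_eff_l)

  # floored at zero and flagged
  small <- data.frame(t_mid_s = 100, mo2_mg_h = 1e-5, r2 = 1, valid = TRUE,
                      corrected = FALSE)
  outf <- correct_background(small, unif, geom)
  expect_equal(outf$mo2_mg_h, 0)
  expect_false(outf$valid)
})

test_that("processing a noiseless synthetic trace recovers programmed slopes exactly", {
  cfg <- sim_config(seed = 1, sensor_noise_sd = 0, stress_multiplier = 0,
                    activity_excess_mean = 0, background_pre = 0,
                    background_post = 0)
  sim <- simulate_oxygen_trace(cfg, 0.60, 1.29, "alone", seed = 2)
  tbl <- process_trace(sim$trace, chamber_geometry(1.29))
  expect_gt(nrow(tbl), 80)
  expect_equal(tbl$mo2_mg_h, rep(0.60, nrow(tbl)), tolerance = 1e-10)
  expect_true(all(tbl$valid))
})

test_that("fast matrix path agrees with per-window lm fitting", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_oxygen_trace(cfg, 0.60, 1.29, "alone", seed = 6)
  geom <- chamber_geometry(1.29)
  fast <- process_trace(sim$trace, geom)
  slow <- do.call(rbind, lapply(segment_trace(sim$trace, phase_schedule()),
                                function(w) slope_to_mo2(fit_slope(w), geom)))
  expect_equal(nrow(fast), nrow(slow))
  expect_equal(fast$mo2_mg_h, slow$mo2_mg_h, tolerance = 1e-10)
  expect_equal(fast$r2, slow$r2, tolerance = 1e-8)
})

test_that("correction commutes with concentration rescaling", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_oxygen_trace(cfg, 0.60, 1.29, "alone", seed = 12)
  geom <- chamber_geometry(1.29)
  bg <- estimate_background(-0.005, -0.02, 0, max(sim$trace$time_s))
  a <- process_trace(sim$trace, geom, background = bg)
  scaled <- oxygen_trace(sim$trace$time_s, sim$trace$o2_mg_l * 2)
  bg2 <- estimate_background(-0.01, -0.04, 0, max(sim$trace$time_s))
  b <- process_trace(scaled, geom, background = bg2)
  expect_equal(b$mo2_mg_h, 2 * a$mo2_mg_h, tolerance = 1e-9)
})
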