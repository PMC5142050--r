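test_that("generators are deterministic under fixed seeds", {
  cfg <- sim_config(seed = 5)
  a <- simulate_oxygen_trace(cfg, 0.6, 1.29, "alone", seed = 8)
  b <- simulate_oxygen_trace(cfg, 0.6, 1.29, "alone", seed = 8)
  expect_identical(a, b)

  ca <- simulate_cohort(sim_config(seed = 17, n_fish_per_treatment = 1,
                                   n_shoals_per_treatment = 1))
  cb <- simulate_cohort(sim_config(seed = 17, n_fish_per_treatment = 1,
                                   n_shoals_per_treatment = 1))
  expect_identical(ca, cb)
})

test_that("an empty cohort keeps a valid schema", {
  co <- simulate_cohort(sim_config(seed = 1, n_fish_per_treatment = 0,
                                   n_shoals_per_treatment = 0))
  expect_equal(nrow(co$metadata), 0)
  expect_length(co$respirometry, 0)
  expect_equal(nrow(co$choice_metadata), 0)
  expect_true(all(c("fish_id", "co2_uatm", "mass_g", "smr_basal") %in%
                    names(co$metadata)))
})

test_that("with noise, drift and stress off, every phase slope is the programmed SMR", {
  cfg <- sim_config(seed = 2, sensor_noise_sd = 0, stress_multiplier = 0,
                    activity_excess_mean = 0, background_pre = 0,
                    background_post = 0)
  sim <- simulate_oxygen_trace(cfg, 0.55, 1.0, "alone", seed = 3)
  v_eff <- 0.1 - 1.0 / 1000
  tbl <- process_trace(sim$trace, chamber_geometry(1.0))
  expect_equal(tbl$mo2_mg_h, rep(0.55, nrow(tbl)), tolerance = 1e-10)
  expect_equal(sim$truth$smr_true, 0.55)
  expect_equal(sim$truth$v_eff_l, v_eff)
})

test_that("calming multiplier 1 makes testing treatments exchangeable", {
  cfg <- sim_config(seed = 4, calming_multiplier = 1, sensor_noise_sd = 0,
                    stress_multiplier = 0, activity_excess_mean = 0,
                    background_pre = 0, background_post = 0)
  a <- simulate_oxygen_trace(cfg, 0.6, 1.29, "alone", seed = 9)
  g <- simulate_oxygen_trace(cfg, 0.6, 1.29, "group", seed = 9)
  expect_identical(a$trace, g$trace)
  expect_equal(a$truth$smr_true, g$truth$smr_true)
})

test_that("chase recovery truth satisfies the aerobic-scope identity and window bias", {
  cfg <- sim_config(seed = 6, sensor_noise_sd = 0)
  ch <- simulate_chase_recovery(cfg, 0.6, 1.29, seed = 7)
  expect_equal(ch$truth$as_true, ch$truth$mmr_true - ch$truth$smr_basal)
  expect_equal(ch$truth$mmr_true, 0.6 * cfg$scope_multiplier)

  mmr_est <- compute_mmr(ch$trace, chamber_geometry(1.29))
  wmean <- oracle_window_mean(ch$truth$mmr_true, ch$truth$smr_basal,
                              cfg$recovery_tau_s, 180)
  # noiseless: the first-window mean bounds the estimate from below (up to
  # the one-sample discretization of the cumulative decline), the true peak
  # from above
  expect_gte(mmr_est, wmean - 0.01 * ch$truth$mmr_true)
  expect_lte(mmr_est, ch$truth$mmr_true)

  # scope multiplier 1 is the AS = 0 boundary case
  cfg1 <- sim_config(seed = 6, scope_multiplier = 1, sensor_noise_sd = 0)
  ch1 <- simulate_chase_recovery(cfg1, 0.6, 1.29, seed = 8)
  expect_equal(ch1$truth$as_true, 0)
  expect_equal(compute_mmr(ch1$trace, chamber_geometry(1.29)), 0.6,
               tolerance = 0.01)
})

test_that("trace generation rejects parameters implying hypoxia", {
  cfg <- sim_config(seed = 3)
  expect_error(simulate_oxygen_trace(cfg, 6.0, 1.29, "alone", seed = 1),
               "2 mg/L")
})

test_that("choice trajectories are consistent with their event-level truth", {
  cfg <- sim_config(seed = 30, uninformed_prob = 0)
  set.seed(30)
  for (i in 1:10) {
    tr <- simulate_choice_trial(cfg, 0.65, 3.22, "left")
    r <- score_trajectory(tr$trajectory, tr$zones)
    expect_equal(r$total_visits, tr$truth$n_visits, tolerance = 0.15)
    # scored zone time exceeds the event-sojourn truth slightly: the tail of
    # each approach/departure transit already lies within two body lengths
    scored_f <- r$prop_familiar * cfg$choice_trial_s
    expect_gte(scored_f, 0.9 * tr$truth$time_familiar_s)
    expect_lte(scored_f,
               tr$truth$time_familiar_s + 2.5 * tr$truth$n_visits + 5)
    expect_true(r$informed == tr$truth$informed ||
                  r$total_visits != tr$truth$n_visits)
  }
})

test_that("forced-informed conditioning injects a second-zone visit at p = 1", {
  cfg <- sim_config(seed = 31, uninformed_prob = 0)
  tr <- simulate_choice_trial(cfg, 1.0, 3.22, "left", seed = 44)
  expect_true(tr$truth$informed)
  expect_gt(tr$truth$time_unfamiliar_s, 0)
  r <- score_trajectory(tr$trajectory, tr$zones)
  expect_gt(r$prop_familiar, r$prop_unfamiliar)
})

test_that("cohort ground truth covers every generated quantity", {
  co <- simulate_cohort(sim_config(seed = 55, n_fish_per_treatment = 2,
                                   n_shoals_per_treatment = 2))
  gt <- co$ground_truth
  expect_equal(nrow(gt), 6)
  expect_true(all(c("smr_basal", "smr_group", "mmr_true", "as_true",
                    "calming_pct_true") %in% names(gt)))
  expect_equal(gt$as_true, gt$mmr_true - gt$smr_basal)
  expect_equal(unique(gt$calming_pct_true), 22.8)
  expect_true(all(c("p_familiar_true") %in% names(co$choice_metadata)))
  # every fish has both testing treatments
  expect_true(all(vapply(co$respirometry, function(f)
    all(c("alone", "group", "chase") %in% names(f)), logical(1))))
})
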