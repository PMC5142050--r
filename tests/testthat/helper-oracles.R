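# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# Numerical CO2-system solve: root-find DIC such that the full alkalinity
# balance closes, building every species from speciation fractions. Shares
# only the constant formulations with the package (the quantity under test
# is the solve, given the constants).
oracle_pco2 <- function(temperature, salinity, ph_nbs, ta_umol_kg) {
  k <- compute_constants(temperature, salinity)
  ta <- ta_umol_kg * 1e-6
  h <- 10^(-ph_nbs) / k$fh
  h_free <- h / (1 + k$total_sulfate / k$ks + k$total_fluoride / k$kf)
  ta_model <- function(dic) {
    denom <- h^2 + k$k1 * h + k$k1 * k$k2
    hco3 <- dic * k$k1 * h / denom
    co3 <- dic * k$k1 * k$k2 / denom
    hco3 + 2 * co3 + k$total_boron * k$kb / (k$kb + h) + k$kw / h -
      h_free - k$total_sulfate / (1 + k$ks / h_free) -
      k$total_fluoride / (1 + k$kf / h_free)
  }
  dic <- stats::uniroot(function(d) ta_model(d) - ta, c(1e-8, 0.02),
                        tol = 1e-15)$root
  co2_star <- dic * h^2 / (h^2 + k$k1 * h + k$k1 * k$k2)
  co2_star / k$k0 * 1e6
}

# Closed-form OLS slope (per hour) and r-squared.
oracle_ols <- function(time_s, o2) {
  tc <- time_s - mean(time_s)
  slope <- sum(tc * o2) / sum(tc^2)
  pred <- mean(o2) + slope * tc
  sst <- sum((o2 - mean(o2))^2)
  list(slope_mg_l_h = slope * 3600,
       r2 = if (sst == 0) 1 else 1 - sum((o2 - pred)^2) / sst)
}

# Mean of an exponential recovery over its first window [0, w]:
# mo2(t) = base + (peak - base) * exp(-t / tau)
oracle_window_mean <- function(peak, base, tau, w) {
  base + (peak - base) * tau / w * (1 - exp(-w / tau))
}

# A noiseless linear-decline trace (one sealed period).
make_linear_trace <- function(o2_0 = 8, slope_per_h = -1, duration_s = 480,
                              dt = 2) {
  t <- seq(0, duration_s - dt, by = dt)
  oxygen_trace(t, o2_0 + slope_per_h * t / 3600, dt)
}

# Event-level choice outcomes for calibration studies: same sojourn model as
# the generator, scored from the recorded event truth (no positional walk).
# Retests until informed, as in the study's retest rule.
event_level_choice <- function(cfg, p_familiar, max_attempts = 10) {
  for (a in seq_len(max_attempts)) {
    tr <- simulate_choice_trial(cfg, p_familiar, emit = "events")
    if (tr$truth$informed) break
  }
  tf <- tr$truth$time_familiar_s
  tu <- tr$truth$time_unfamiliar_s
  data.frame(pref_familiar = tf / (tf + tu), n_visits = tr$truth$n_visits,
             informed = tr$truth$informed)
}
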