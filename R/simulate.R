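#' Simulation configuration for a synthetic study
#'
#' Bundles every parameter of the synthetic-data generator, with defaults
#' that emulate the study conditions: 9 min measure / 3 min flush cycling
#' logged every 2 s over a 17-19 h overnight trial, handling stress that
#' decays over the first hours, linear microbial background growth, Gaussian
#' sensor noise, a multiplicative group "calming" reduction of basal
#' metabolism, an exhaustive-chase recovery for MMR, and a two-state-plus-
#' neutral sojourn model for the choice arena calibrated to ~45 shoal visits
#' per 15 min trial.
#'
#' @param seed Master seed; all child seeds are derived from it.
#' @param n_fish_per_treatment Fish per CO2 treatment in the respirometry
#'   experiment (default 10).
#' @param co2_levels Nominal CO2 treatments, uatm.
#' @param mass_mean_g,mass_sd_g Body-mass distribution (g).
#' @param length_mean_cm,length_sd_cm Standard-length distribution (cm).
#' @param allometry_a,allometry_b SMR allometry `SMR = a * mass^b` (mg O2/h
#'   at mass in g); defaults give 0.60 mg O2/h at the 1.29 g mean mass.
#' @param smr_cv Between-fish lognormal CV of SMR around the allometric mean.
#' @param stress_multiplier,stress_tau_h Initial handling-stress elevation:
#'   instantaneous MO2 is `SMR * (1 + A * exp(-t / tau) + activity)`.
#' @param activity_excess_mean Mean of the per-phase exponential
#'   spontaneous-activity excess (so routine MO2 sits ~10% above basal).
#' @param calming_multiplier Multiplier on basal MO2 in the group testing
#'   treatment (default 0.772, i.e. a 22.8% reduction).
#' @param scope_multiplier True MMR as a multiple of basal SMR (default 3).
#' @param recovery_tau_s Exponential decay constant of post-chase MO2 (s).
#' @param chase_minutes_range Recovery-trace duration range (min).
#' @param background_pre,background_post Empty-chamber O2 decline rate at
#'   trial start/end (mg O2 L-1 h-1); background grows linearly between.
#' @param sensor_noise_sd Gaussian sensor noise on O2 samples (mg/L).
#' @param trial_hours_range Overnight trial duration range (h).
#' @param o2_saturation_mg_l Air-saturated O2 concentration (mg/L).
#' @param flush_tau_s Time constant of the flush-phase relaxation toward
#'   saturation (s).
#' @param chamber_volume_l Respirometer volume (L).
#' @param sample_interval_s O2 logging interval (s).
#' @param measure_s,flush_s,discard_s Phase schedule (see
#'   [phase_schedule()]).
#' @param p_familiar Named vector of per-treatment probabilities that a zone
#'   visit targets the familiar shoal.
#' @param uninformed_prob Probability that a trial is uninformed (fish never
#'   samples the second zone) and triggers a retest.
#' @param sojourn_mean_s,transit_mean_s Mean zone-sojourn and neutral-transit
#'   durations (s); defaults give ~45 visits per 900 s trial.
#' @param choice_shoal_sd_logit Between-shoal SD of the familiar-choice
#'   probability on the logit scale.
#' @param choice_trial_s Choice-trial duration (s).
#' @param traj_dt_s Trajectory emission interval (s).
#' @param n_shoals_per_treatment,fish_per_shoal_tested Choice-experiment
#'   design (9 shoals x 2 focal fish per treatment).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_fish_per_treatment = 10L,
                       co2_levels = c(450, 750, 1000),
                       mass_mean_g = 1.29, mass_sd_g = 0.22,
                       length_mean_cm = 3.22, length_sd_cm = 0.16,
                       allometry_a = 0.49, allometry_b = 0.8,
                       smr_cv = 0.20,
                       stress_multiplier = 1.0, stress_tau_h = 1.5,
                       activity_excess_mean = 0.10,
                       calming_multiplier = 0.772,
                       scope_multiplier = 3.0,
                       recovery_tau_s = 450,
                       chase_minutes_range = c(8, 10),
                       background_pre = 0.005, background_post = 0.02,
                       sensor_noise_sd = 0.01,
                       trial_hours_range = c(17, 19),
                       o2_saturation_mg_l = 6.4,
                       flush_tau_s = 30,
                       chamber_volume_l = 0.100,
                       sample_interval_s = 2,
                       measure_s = 540, flush_s = 180, discard_s = 60,
                       p_familiar = c(`450` = 0.65, `750` = 0.5,
                                      `1000` = 0.5),
                       uninformed_prob = 0.22,
                       sojourn_mean_s = 14, transit_mean_s = 6,
                       choice_shoal_sd_logit = 0.15,
                       choice_trial_s = 900,
                       traj_dt_s = 0.2,
                       n_shoals_per_treatment = 9L,
                       fish_per_shoal_tested = 2L) {
  cfg <- as.list(environment())
  stopifnot(cfg$mass_sd_g >= 0, cfg$smr_cv >= 0, cfg$sensor_noise_sd >= 0,
            cfg$calming_multiplier > 0, cfg$scope_multiplier > 0,
            cfg$stress_multiplier >= 0, cfg$stress_tau_h > 0,
            cfg$activity_excess_mean >= 0,
            all(cfg$p_familiar >= 0 & cfg$p_familiar <= 1),
            cfg$uninformed_prob >= 0, cfg$uninformed_prob <= 1,
            cfg$sojourn_mean_s > 0, cfg$transit_mean_s > 0,
            cfg$n_fish_per_treatment >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate an overnight intermittent-flow oxygen trace
#'
#' The true instantaneous fish MO2 is
#' `SMR_basal * calming * (1 + A * exp(-t / tau) + activity(phase))`, where
#' `SMR_basal` is the fish's basal rate (times the calming multiplier in the
#' group treatment), the exponential term is the decaying handling-stress
#' elevation and `activity` is a per-phase spontaneous-activity excess drawn
#' `Exp(mean)`. During sealed measurement phases the chamber O2 declines
#' at `MO2/V_eff + background(t)` (mg O2 L-1 h-1) plus Gaussian sensor
#' noise; flush phases relax O2 back toward saturation exponentially.
#'
#' @param config A [sim_config()].
#' @param smr_basal_mg_h The fish's basal (alone) SMR, mg O2/h.
#' @param mass_g Body mass, g (sets the effective volume).
#' @param testing `"alone"` or `"group"` (the latter applies the calming
#'   multiplier).
#' @param seed Optional seed for this trace.
#' @return A list with `trace` (an [oxygen_trace()]) and `truth`: the
#'   basal rate after calming (`smr_true`), the analytic stabilised routine
#'   mean (`rmr_true`), per-phase true mean MO2 over the retained window
#'   (`phases`), the first-window truth (`fs_true`), background endpoints,
#'   trial duration and effective volume.
#' @export
simulate_oxygen_trace <- function(config, smr_basal_mg_h, mass_g,
                                  testing = c("alone", "group"),
                                  seed = NULL) {
  testing <- match.arg(testing)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  calm <- if (testing == "group") cfg$calming_multiplier else 1
  smr_t <- smr_basal_mg_h * calm
  v_eff <- cfg$chamber_volume_l - mass_g / 1000
  stopifnot(v_eff > 0)

  hours <- stats::runif(1, cfg$trial_hours_range[1], cfg$trial_hours_range[2])
  dt <- cfg$sample_interval_s
  cycle <- cfg$measure_s + cfg$flush_s
  n <- floor(hours * 3600 / dt)
  t <- (seq_len(n) - 1) * dt
  total_s <- t[n]

  phase <- t %/% cycle
  offset <- t %% cycle
  measure <- offset < cfg$measure_s
  n_phase <- max(phase) + 1

  # per-phase spontaneous-activity excess and decaying handling-stress
  # elevation enter additively, as fractions of the basal rate
  act <- stats::rexp(n_phase, rate = 1 / max(cfg$activity_excess_mean,
                                             1e-12))
  if (cfg$activity_excess_mean == 0) act <- rep(0, n_phase)
  tau_s <- cfg$stress_tau_h * 3600
  mo2_inst <- smr_t * (1 + cfg$stress_multiplier * exp(-t / tau_s) +
                         act[phase + 1])
  bg <- cfg$background_pre +
    (cfg$background_post - cfg$background_pre) * t / total_s
  dec <- numeric(n)
  dec[measure] <- (mo2_inst[measure] / v_eff + bg[measure]) * dt / 3600

  first_idx <- seq(1, n, by = cycle / dt)       # first sample of each phase
  last_idx <- c(first_idx[-1] - 1L, n)
  cs <- cumsum(dec)
  cs0 <- (cs - dec)[first_idx]
  phase_sum <- cs[last_idx] - cs0
  f <- exp(-cfg$flush_s / cfg$flush_tau_s)
  d_start <- numeric(n_phase)
  for (p in seq_len(n_phase - 1)) {
    d_start[p + 1] <- f * (d_start[p] + phase_sum[p])
  }
  within <- cs - cs0[phase + 1]
  deficit <- d_start[phase + 1] + within
  fl <- !measure
  deficit[fl] <- (d_start[phase[fl] + 1] + phase_sum[phase[fl] + 1]) *
    exp(-(offset[fl] - cfg$measure_s + dt) / cfg$flush_tau_s)
  o2 <- cfg$o2_saturation_mg_l - deficit +
    stats::rnorm(n, 0, cfg$sensor_noise_sd)
  if (min(o2) < 2) {
    stop("simulated O2 fell below 2 mg/L; parameters imply a hypoxic trial ",
         "the protocol would have aborted", call. = FALSE)
  }

  retained <- measure & offset >= cfg$discard_s
  n_per <- (cfg$measure_s - cfg$discard_s) / dt
  complete <- which(tabulate(phase[retained] + 1L, n_phase) == n_per) - 1L
  keep <- retained & (phase %in% complete)
  mo2_true <- colMeans(matrix(mo2_inst[keep], nrow = n_per))
  t_mid <- colMeans(matrix(t[keep], nrow = n_per))
  h <- total_s / 3600
  th <- cfg$stress_tau_h
  rmr_true <- smr_t * (1 + cfg$activity_excess_mean +
                         cfg$stress_multiplier * th *
                           (exp(-5 / th) - exp(-h / th)) / (h - 5))

  list(trace = oxygen_trace(t, o2, dt),
       truth = list(smr_true = smr_t,
                    smr_basal = smr_basal_mg_h,
                    testing = testing,
                    rmr_true = rmr_true,
                    fs_true = mo2_true[1],
                    phases = data.frame(phase = complete, t_mid_s = t_mid,
                                        mo2_true = mo2_true),
                    background_pre = cfg$background_pre,
                    background_post = cfg$background_post,
                    trial_hours = h, v_eff_l = v_eff))
}

#' Simulate an empty-chamber background trace
#'
#' Three measurement periods of the empty chamber with a constant microbial
#' O2-decline rate plus sensor noise, for use with [estimate_background()].
#'
#' @param config A [sim_config()].
#' @param slope_mg_l_h Background O2-decline rate (mg O2 L-1 h-1).
#' @param seed Optional seed.
#' @return An [oxygen_trace()] covering three measure/flush cycles.
#' @export
simulate_background_trace <- function(config, slope_mg_l_h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  dt <- cfg$sample_interval_s
  cycle <- cfg$measure_s + cfg$flush_s
  n <- 3 * cycle / dt
  t <- (seq_len(n) - 1) * dt
  offset <- t %% cycle
  measure <- offset < cfg$measure_s
  dec <- ifelse(measure, slope_mg_l_h * dt / 3600, 0)
  phase <- t %/% cycle
  cs <- cumsum(dec)
  first_idx <- which(!duplicated(phase))
  within <- cs - (cs - dec)[first_idx][phase + 1]
  o2 <- cfg$o2_saturation_mg_l - ifelse(measure, within, 0) +
    stats::rnorm(n, 0, cfg$sensor_noise_sd)
  oxygen_trace(t, pmax(o2, 0.1), dt)
}

#' Simulate a post-chase recovery trace
#'
#' After exhaustive chasing, MO2 starts at the fish's true MMR
#' (`scope_multiplier * SMR_basal`) and decays exponentially toward basal
#' with time constant `recovery_tau_s`, in a sealed chamber logged every
#' sample interval.
#'
#' @inheritParams simulate_oxygen_trace
#' @return A list with `trace` and `truth` (`mmr_true`, `smr_basal`,
#'   `recovery_tau_s`, `v_eff_l`, plus `as_true = mmr_true - smr_basal`).
#' @export
simulate_chase_recovery <- function(config, smr_basal_mg_h, mass_g,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  mmr_true <- smr_basal_mg_h * cfg$scope_multiplier
  v_eff <- cfg$chamber_volume_l - mass_g / 1000
  stopifnot(v_eff > 0)
  minutes <- stats::runif(1, cfg$chase_minutes_range[1],
                          cfg$chase_minutes_range[2])
  dt <- cfg$sample_interval_s
  n <- floor(minutes * 60 / dt)
  t <- (seq_len(n) - 1) * dt
  mo2 <- smr_basal_mg_h + (mmr_true - smr_basal_mg_h) *
    exp(-t / cfg$recovery_tau_s)
  dec <- cumsum((mo2 / v_eff) * dt / 3600)
  o2 <- cfg$o2_saturation_mg_l - dec + stats::rnorm(n, 0, cfg$sensor_noise_sd)
  if (min(o2) < 2) {
    stop("simulated recovery O2 fell below 2 mg/L", call. = FALSE)
  }
  list(trace = oxygen_trace(t, o2, dt),
       truth = list(mmr_true = mmr_true, smr_basal = smr_basal_mg_h,
                    as_true = mmr_true - smr_basal_mg_h,
                    recovery_tau_s = cfg$recovery_tau_s, v_eff_l = v_eff))
}

# Draw the sojourn/transit event sequence of one choice trial.
.choice_events <- function(cfg, p_familiar, informed) {
  t_end <- cfg$choice_trial_s
  starts <- numeric(0); ends <- numeric(0); states <- integer(0)
  tt <- 0
  repeat {
    tt <- tt + stats::rexp(1, 1 / cfg$transit_mean_s)   # neutral transit
    if (tt >= t_end) break
    dur <- stats::rexp(1, 1 / cfg$sojourn_mean_s)
    starts <- c(starts, tt); ends <- c(ends, min(tt + dur, t_end))
    states <- c(states, 0L)                             # zone tbd
    tt <- tt + dur
    if (tt >= t_end) break
  }
  nv <- length(starts)
  if (nv == 0) {
    return(data.frame(state = integer(0), start_s = numeric(0),
                      end_s = numeric(0)))
  }
  if (!informed) {
    z0 <- if (stats::runif(1) < p_familiar) 1L else 2L
    states <- rep(z0, nv)
  } else {
    draw <- function() ifelse(stats::runif(nv) < p_familiar, 1L, 2L)
    states <- draw()
    tries <- 0
    while (nv >= 2 && length(unique(states)) < 2 && tries < 100) {
      states <- draw(); tries <- tries + 1
    }
    if (nv >= 2 && length(unique(states)) < 2) {
      # conditioning impossible by resampling (p at 0/1): inject one visit
      flip <- sample.int(nv, 1)
      states[flip] <- 3L - states[flip]
    }
  }
  data.frame(state = states, start_s = starts, end_s = ends)
}

#' Simulate one choice-test trial
#'
#' A continuous-time two-state-plus-neutral sojourn model: the focal fish
#' alternates neutral transits (exponential, mean `transit_mean_s`) and zone
#' sojourns (exponential, mean `sojourn_mean_s`); each sojourn targets the
#' familiar zone with probability `p_familiar`. With probability
#' `1 - uninformed_prob` the trial is conditioned to visit both zones
#' (informed); otherwise every sojourn targets a single zone and the trial
#' will fail the informed-choice filter. Optionally the event sequence is
#' emitted as a positional random walk consistent with zone membership.
#'
#' @param config A [sim_config()].
#' @param p_familiar Probability a zone visit targets the familiar shoal.
#' @param body_length_cm Focal-fish standard length (sets the zone radius).
#' @param familiar_side `"left"` or `"right"`.
#' @param seed Optional seed.
#' @param emit `"trajectory"` (default) or `"events"` (skip the positional
#'   walk; faster, for calibration studies at the event level).
#' @return A list with `events`, `truth` (true visit count, per-zone times,
#'   informed flag, `p_familiar`), `zones`, and — when emitted —
#'   `trajectory` (`time_s`, `x_cm`, `y_cm`).
#' @export
simulate_choice_trial <- function(config, p_familiar, body_length_cm = 3.22,
                                  familiar_side = c("left", "right"),
                                  seed = NULL,
                                  emit = c("trajectory", "events")) {
  familiar_side <- match.arg(familiar_side)
  emit <- match.arg(emit)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  stopifnot(p_familiar >= 0, p_familiar <= 1)
  informed <- stats::runif(1) >= cfg$uninformed_prob
  ev <- .choice_events(cfg, p_familiar, informed)
  zones <- build_zones(arena_geometry(body_length_cm), familiar_side)

  dur <- ev$end_s - ev$start_s
  truth <- list(
    n_visits = nrow(ev),
    time_familiar_s = sum(dur[ev$state == 1L]),
    time_unfamiliar_s = sum(dur[ev$state == 2L]),
    informed = informed && length(unique(ev$state)) >= 2,
    p_familiar = p_familiar)

  out <- list(events = ev, truth = truth, zones = zones)
  if (emit == "trajectory") {
    out$trajectory <- .emit_trajectory(cfg, ev, zones)
  }
  out
}

# Turn an event sequence into (x, y) positions at the trajectory rate.
.emit_trajectory <- function(cfg, ev, zones) {
  g <- zones$geometry
  dt <- cfg$traj_dt_s
  times <- seq(0, cfg$choice_trial_s - dt, by = dt)
  n <- length(times)
  cx <- c(zones$familiar$centre_x_cm, zones$unfamiliar$centre_x_cm)
  cy <- c(zones$familiar$centre_y_cm, zones$unfamiliar$centre_y_cm)
  zr <- zones$familiar$radius_cm
  rin <- g$container_radius_cm + 0.3
  mid <- c(g$length_cm / 2, g$width_cm / 2)

  x <- rep(mid[1], n); y <- rep(mid[2], n)
  zone_pt <- function(z) {
    th <- stats::runif(1, 0, 2 * pi)
    r <- stats::runif(1, rin, zr - 0.3)
    p <- c(cx[z] + r * cos(th), cy[z] + r * sin(th))
    p[1] <- min(max(p[1], 0.3), g$length_cm - 0.3)
    p[2] <- min(max(p[2], 0.3), g$width_cm - 0.3)
    p
  }
  for (i in seq_len(nrow(ev))) {
    idx <- which(times >= ev$start_s[i] & times < ev$end_s[i])
    if (!length(idx)) next
    z <- ev$state[i]
    anchor <- zone_pt(z)
    jx <- anchor[1] + stats::rnorm(length(idx), 0, 0.8)
    jy <- anchor[2] + stats::rnorm(length(idx), 0, 0.8)
    # keep the sojourn inside the association zone and the arena
    dxz <- jx - cx[z]; dyz <- jy - cy[z]
    rr <- sqrt(dxz^2 + dyz^2)
    over <- rr > zr - 0.2
    scl <- ifelse(over, (zr - 0.2) / rr, 1)
    jx <- cx[z] + dxz * scl; jy <- cy[z] + dyz * scl
    x[idx] <- pmin(pmax(jx, 0.05), g$length_cm - 0.05)
    y[idx] <- pmin(pmax(jy, 0.05), g$width_cm - 0.05)
  }
  # neutral transits: linear legs through a mid-tank waypoint
  if (nrow(ev)) {
    bounds <- rbind(c(0, ev$start_s[1]),
                    if (nrow(ev) > 1)
                      cbind(ev$end_s[-nrow(ev)], ev$start_s[-1]),
                    c(ev$end_s[nrow(ev)], cfg$choice_trial_s))
    for (b in seq_len(nrow(bounds))) {
      idx <- which(times >= bounds[b, 1] & times < bounds[b, 2])
      if (!length(idx)) next
      p0 <- if (idx[1] == 1) mid else c(x[idx[1] - 1], y[idx[1] - 1])
      after <- which(times > bounds[b, 2] - 1e-9)
      p1 <- if (length(after)) c(x[after[1]], y[after[1]]) else mid
      wp <- c(stats::runif(1, mid[1] - 10, mid[1] + 10),
              stats::runif(1, 4, g$width_cm - 4))
      m <- length(idx)
      half <- ceiling(m / 2)
      fr1 <- if (half > 0) seq_len(half) / (half + 1) else numeric(0)
      fr2 <- if (m - half > 0) seq_len(m - half) / (m - half + 1) else numeric(0)
      px <- c(p0[1] + (wp[1] - p0[1]) * fr1, wp[1] + (p1[1] - wp[1]) * fr2)
      py <- c(p0[2] + (wp[2] - p0[2]) * fr1, wp[2] + (p1[2] - wp[2]) * fr2)
      x[idx] <- pmin(pmax(px + stats::rnorm(m, 0, 0.2), 0.05),
                     g$length_cm - 0.05)
      y[idx] <- pmin(pmax(py + stats::rnorm(m, 0, 0.2), 0.05),
                     g$width_cm - 0.05)
    }
  }
  data.frame(time_s = times, x_cm = x, y_cm = y)
}

#' Simulate a complete study cohort
#'
#' Generates the full factorial dataset with recorded ground truth: fish
#' metadata (mass, length, basal SMR) for each CO2 treatment; for the
#' respirometry experiment, both testing treatments' overnight traces, the
#' chase-recovery trace and empty-chamber background traces per fish; for
#' the choice experiment, one (final) trial per focal fish with
#' retest-on-uninformed logic. A master seed fans out deterministic child
#' seeds, so identical configs give identical datasets.
#'
#' @param config A [sim_config()].
#' @param experiments Which experiments to generate: any of
#'   `"respirometry"`, `"choice"`.
#' @return A list of class `cohort_dataset` with `config`, `metadata`
#'   (respirometry fish), `respirometry` (per-fish list: `alone`, `group`,
#'   `chase`, `bg_pre`, `bg_post`, each with their truth), `choice_metadata`,
#'   `choice_trials` (per focal fish: final trial plus `n_attempts`), and
#'   `ground_truth` (one row per fish with every true quantity).
#' @export
simulate_cohort <- function(config,
                            experiments = c("respirometry", "choice")) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  experiments <- match.arg(experiments, several.ok = TRUE)
  set.seed(cfg$seed)

  out <- list(config = cfg)
  sdlog <- sqrt(log(1 + cfg$smr_cv^2))

  if ("respirometry" %in% experiments) {
    n_t <- cfg$n_fish_per_treatment
    n_fish <- n_t * length(cfg$co2_levels)
    meta <- data.frame(
      fish_id = sprintf("F%03d", seq_len(max(n_fish, 0))),
      shoal_id = sprintf("RS%03d", seq_len(max(n_fish, 0))),
      co2_uatm = rep(cfg$co2_levels, each = n_t),
      # study cohorts are tightly size-matched; truncate the tails a real
      # experimenter would never place in a 100 ml chamber
      mass_g = pmin(pmax(stats::rnorm(n_fish, cfg$mass_mean_g,
                                      cfg$mass_sd_g), 0.7), 1.9),
      length_cm = pmax(stats::rnorm(n_fish, cfg$length_mean_cm,
                                    cfg$length_sd_cm), 1.5))
    meta$smr_basal <- cfg$allometry_a * meta$mass_g^cfg$allometry_b *
      exp(pmin(pmax(stats::rnorm(n_fish, -sdlog^2 / 2, sdlog),
                    -2 * sdlog), 2 * sdlog))
    seeds <- if (n_fish > 0) sample.int(2^31 - 1, 5 * n_fish) else integer(0)
    resp <- vector("list", n_fish)
    names(resp) <- meta$fish_id
    for (i in seq_len(n_fish)) {
      s <- seeds[(5 * (i - 1) + 1):(5 * i)]
      alone <- simulate_oxygen_trace(cfg, meta$smr_basal[i], meta$mass_g[i],
                                     "alone", seed = s[1])
      grp <- simulate_oxygen_trace(cfg, meta$smr_basal[i], meta$mass_g[i],
                                   "group", seed = s[2])
      chase <- simulate_chase_recovery(cfg, meta$smr_basal[i],
                                       meta$mass_g[i], seed = s[3])
      bg_pre <- simulate_background_trace(cfg, cfg$background_pre,
                                          seed = s[4])
      bg_post <- simulate_background_trace(cfg, cfg$background_post,
                                           seed = s[5])
      resp[[i]] <- list(alone = alone, group = grp, chase = chase,
                        bg_pre = bg_pre, bg_post = bg_post)
    }
    out$metadata <- meta
    out$respirometry <- resp
    gt <- meta
    gt$smr_group <- meta$smr_basal * cfg$calming_multiplier
    gt$mmr_true <- meta$smr_basal * cfg$scope_multiplier
    gt$as_true <- meta$smr_basal * (cfg$scope_multiplier - 1)
    gt$calming_pct_true <- rep(100 * (1 - cfg$calming_multiplier), nrow(meta))
    out$ground_truth <- gt
  }

  if ("choice" %in% experiments) {
    n_s <- cfg$n_shoals_per_treatment
    n_per <- cfg$fish_per_shoal_tested
    n_trials <- n_s * n_per * length(cfg$co2_levels)
    cmeta <- data.frame(
      fish_id = sprintf("C%03d", seq_len(max(n_trials, 0))),
      shoal_id = sprintf("CS%02d",
                         rep(seq_len(n_s * length(cfg$co2_levels)),
                             each = n_per))[seq_len(max(n_trials, 0))],
      co2_uatm = rep(cfg$co2_levels, each = n_s * n_per),
      body_length_cm = pmax(stats::rnorm(n_trials, cfg$length_mean_cm,
                                         cfg$length_sd_cm), 1.5),
      familiar_side = sample(c("left", "right"), max(n_trials, 0),
                             replace = TRUE))
    shoal_ids <- unique(cmeta$shoal_id)
    shoal_eff <- stats::rnorm(length(shoal_ids), 0, cfg$choice_shoal_sd_logit)
    names(shoal_eff) <- shoal_ids
    p_by_trt <- cfg$p_familiar[as.character(cmeta$co2_uatm)]
    cmeta$p_familiar_true <- stats::plogis(stats::qlogis(pmin(pmax(
      p_by_trt, 1e-6), 1 - 1e-6)) + shoal_eff[cmeta$shoal_id])
    cseeds <- if (n_trials > 0) sample.int(2^31 - 1, n_trials) else integer(0)
    trials <- vector("list", n_trials)
    names(trials) <- cmeta$fish_id
    for (i in seq_len(n_trials)) {
      set.seed(cseeds[i])
      attempt <- 0
      repeat {
        attempt <- attempt + 1
        tr <- simulate_choice_trial(cfg, cmeta$p_familiar_true[i],
                                    cmeta$body_length_cm[i],
                                    cmeta$familiar_side[i])
        if (tr$truth$informed || attempt >= 6) break
      }
      tr$n_attempts <- attempt
      trials[[i]] <- tr
    }
    out$choice_metadata <- cmeta
    out$choice_trials <- trials
  }
  class(out) <- "cohort_dataset"
  out
}
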