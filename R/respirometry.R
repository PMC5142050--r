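#' Construct a validated oxygen trace
#'
#' An oxygen trace is the raw record of an intermittent-flow respirometry
#' trial: dissolved O2 concentration logged at a fixed interval (nominally
#' every 2 s) over the whole trial.
#'
#' @param time_s Time since trial start, seconds, strictly increasing.
#' @param o2_mg_l Dissolved oxygen concentration, mg/L, strictly positive.
#' @param sample_interval_s Nominal sampling interval, seconds.
#' @return A `data.frame` of class `oxygen_trace` with columns `time_s`,
#'   `o2_mg_l` and attribute `sample_interval_s`. Gaps larger than five
#'   sampling intervals raise a warning.
#' @export
oxygen_trace <- function(time_s, o2_mg_l, sample_interval_s = 2) {
  if (length(time_s) < 2L) stop("an oxygen trace needs at least 2 points",
                                call. = FALSE)
  if (length(time_s) != length(o2_mg_l)) {
    stop("time_s and o2_mg_l must have equal length", call. = FALSE)
  }
  dtime <- diff(time_s)
  if (any(dtime <= 0)) {
    bad <- which(dtime <= 0)[1] + 1L
    stop("time_s must be strictly increasing (first violation at row ", bad,
         ")", call. = FALSE)
  }
  if (any(!is.finite(o2_mg_l)) || any(o2_mg_l <= 0)) {
    stop("o2_mg_l must be finite and positive", call. = FALSE)
  }
  if (any(dtime > 5 * sample_interval_s)) {
    warning(sum(dtime > 5 * sample_interval_s),
            " gap(s) larger than 5 sampling intervals in trace")
  }
  structure(data.frame(time_s = time_s, o2_mg_l = o2_mg_l),
            sample_interval_s = sample_interval_s,
            class = c("oxygen_trace", "data.frame"))
}

#' Intermittent-flow phase schedule
#'
#' @param measure_s Duration of each sealed measurement phase, seconds
#'   (default 540 s = 9 min).
#' @param flush_s Duration of each flush phase, seconds (default 180 s =
#'   3 min).
#' @param discard_s Leading seconds of each measurement phase dropped before
#'   slope fitting, to let the chamber re-equilibrate after the flush pump
#'   stops (default 60 s).
#' @return A list of class `phase_schedule`.
#' @export
phase_schedule <- function(measure_s = 540, flush_s = 180, discard_s = 60) {
  stopifnot(measure_s > discard_s, discard_s >= 0, flush_s > 0)
  structure(list(measure_s = measure_s, flush_s = flush_s,
                 discard_s = discard_s, cycle_s = measure_s + flush_s),
            class = "phase_schedule")
}

#' Respirometry chamber geometry
#'
#' The effective respirometer volume is the chamber (plus tubing) volume
#' minus the volume displaced by the fish, taken at a density of 1 g/ml
#' unless overridden.
#'
#' @param fish_mass_g Body mass of the focal fish, grams.
#' @param chamber_volume_l Volume of chamber plus gas-impermeable tubing,
#'   litres (default 0.100).
#' @param fish_density_g_per_ml Assumed fish density (default 1.0).
#' @param subtract_fish_volume If `FALSE`, the full chamber volume is used.
#' @return A list of class `chamber_geometry` with the derived `v_eff_l`.
#' @export
chamber_geometry <- function(fish_mass_g, chamber_volume_l = 0.100,
                             fish_density_g_per_ml = 1.0,
                             subtract_fish_volume = TRUE) {
  stopifnot(fish_mass_g > 0, chamber_volume_l > 0, fish_density_g_per_ml > 0)
  v_eff <- if (subtract_fish_volume) {
    chamber_volume_l - fish_mass_g / (1000 * fish_density_g_per_ml)
  } else {
    chamber_volume_l
  }
  if (v_eff <= 0) {
    stop("effective volume is non-positive: fish (", fish_mass_g,
         " g) does not fit the ", chamber_volume_l, " L chamber",
         call. = FALSE)
  }
  structure(list(chamber_volume_l = chamber_volume_l,
                 fish_mass_g = fish_mass_g,
                 fish_density_g_per_ml = fish_density_g_per_ml,
                 v_eff_l = v_eff),
            class = "chamber_geometry")
}

#' Segment a trace into measurement-phase windows
#'
#' Cuts an intermittent-flow trace into its sealed measurement windows using
#' the pump schedule (clock-based segmentation; the apparatus cycles on a
#' fixed timer). The leading `discard_s` of each measurement phase is
#' dropped, flush phases are discarded entirely, and a trailing partial
#' measurement phase is dropped.
#'
#' @param trace An [oxygen_trace()].
#' @param schedule A [phase_schedule()].
#' @return A list of `data.frame`s (`time_s`, `o2_mg_l`), one per complete
#'   measurement window, each with attributes `phase` (0-based cycle index)
#'   and `t_mid_s` (midpoint of the retained window). A trace shorter than
#'   one full cycle returns an empty list with a warning.
#' @export
segment_trace <- function(trace, schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  t <- trace$time_s
  span <- t[length(t)] - t[1]
  if (span < schedule$measure_s) {
    warning("trace shorter than one measurement phase; no windows returned")
    return(list())
  }
  phase <- (t - t[1]) %/% schedule$cycle_s
  offset <- (t - t[1]) %% schedule$cycle_s
  keep <- offset >= schedule$discard_s & offset < schedule$measure_s
  # a phase is complete if the trace extends to the end of its measure window
  complete <- (phase * schedule$cycle_s + schedule$measure_s) <=
    (span + attr(trace, "sample_interval_s") %||% 2)
  keep <- keep & complete[seq_along(keep)]
  if (!any(keep)) {
    warning("no complete measurement windows in trace")
    return(list())
  }
  idx <- split(which(keep), phase[keep])
  lapply(idx, function(i) {
    win <- data.frame(time_s = t[i], o2_mg_l = trace$o2_mg_l[i])
    attr(win, "phase") <- phase[i[1]]
    attr(win, "t_mid_s") <- (t[i[1]] + t[i[length(i)]]) / 2
    win
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the oxygen-decline slope of one measurement window
#'
#' Ordinary least-squares regression of O2 concentration on time, rescaled to
#' a per-hour slope. Oxygen uptake gives a negative slope.
#'
#' @param phase A measurement window from [segment_trace()] (or any
#'   `data.frame` with `time_s`, `o2_mg_l`).
#' @param n_min Minimum number of points for a valid fit.
#' @return A list of class `slope_fit`: `slope_mg_l_h`, `intercept_mg_l`,
#'   `r_squared`, `n_points`, `t_mid_s`.
#' @export
fit_slope <- function(phase, n_min = 10) {
  n <- nrow(phase)
  if (n < n_min) {
    stop("measurement window has ", n, " points; need at least ", n_min,
         call. = FALSE)
  }
  if (stats::var(phase$time_s) == 0) {
    stop("degenerate window: zero variance in time", call. = FALSE)
  }
  fit <- stats::lm(o2_mg_l ~ time_s, data = phase)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((phase$o2_mg_l - mean(phase$o2_mg_l))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(slope_mg_l_h = unname(stats::coef(fit)[2]) * 3600,
                 intercept_mg_l = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = n,
                 t_mid_s = attr(phase, "t_mid_s") %||% mean(range(phase$time_s))),
            class = "slope_fit")
}

#' Convert a slope fit to a whole-animal oxygen-uptake rate
#'
#' MO2 (mg O2 per hour) is the magnitude of the O2 decline rate times the
#' effective chamber volume. A slope that indicates increasing oxygen beyond
#' `positive_tol` is flagged invalid (`valid = FALSE`) and excluded
#' downstream.
#'
#' @param fit A [fit_slope()] result.
#' @param geom A [chamber_geometry()].
#' @param positive_tol Tolerance (mg O2 L-1 h-1) above which a positive
#'   slope invalidates the record.
#' @return A one-row `data.frame`: `t_mid_s`, `mo2_mg_h`, `r2`, `valid`,
#'   `corrected`.
#' @export
slope_to_mo2 <- function(fit, geom, positive_tol = 0.01) {
  stopifnot(inherits(fit, "slope_fit"), inherits(geom, "chamber_geometry"))
  valid <- fit$slope_mg_l_h <= positive_tol
  data.frame(t_mid_s = fit$t_mid_s,
             mo2_mg_h = max(-fit$slope_mg_l_h, 0) * geom$v_eff_l,
             r2 = fit$r_squared,
             valid = valid,
             corrected = FALSE)
}

#' Linear background (microbial) respiration model
#'
#' Background respiration is measured in the empty chamber for several
#' measurement periods before and after the trial; the model assumes a
#' linear increase in the background O2-decline rate between the pre- and
#' post-trial means.
#'
#' @param pre_fits,post_fits Lists of [fit_slope()] results (or numeric
#'   vectors of slopes, mg O2 L-1 h-1, stored negative for uptake) from the
#'   empty chamber before/after the trial.
#' @param t_start_s,t_end_s Seconds spanning the fish trial.
#' @return A list of class `background_model` with `pre_slope`, `post_slope`
#'   (mg O2 L-1 h-1, positive = background uptake), `t_start_s`, `t_end_s`.
#' @export
estimate_background <- function(pre_fits, post_fits, t_start_s, t_end_s) {
  as_bg <- function(x, side) {
    if (length(x) == 0) {
      stop("no ", side, "-trial background fits supplied", call. = FALSE)
    }
    if (is.numeric(x)) return(mean(-x))
    mean(vapply(x, function(f) -f$slope_mg_l_h, numeric(1)))
  }
  stopifnot(t_end_s > t_start_s)
  structure(list(pre_slope = as_bg(pre_fits, "pre"),
                 post_slope = as_bg(post_fits, "post"),
                 t_start_s = t_start_s, t_end_s = t_end_s),
            class = "background_model")
}

#' Background uptake rate at a time point
#'
#' Linear interpolation between the pre- and post-trial background rates;
#' times outside the trial span use the nearest endpoint with a warning.
#'
#' @param model A [estimate_background()] model.
#' @param t_s Time(s), seconds.
#' @return Background O2-decline rate(s), mg O2 L-1 h-1.
#' @export
background_at <- function(model, t_s) {
  stopifnot(inherits(model, "background_model"))
  if (any(t_s < model$t_start_s | t_s > model$t_end_s)) {
    warning("time(s) outside background model span; endpoint value used")
  }
  frac <- pmin(pmax((t_s - model$t_start_s) /
                      (model$t_end_s - model$t_start_s), 0), 1)
  model$pre_slope + frac * (model$post_slope - model$pre_slope)
}

#' Subtract background respiration from MO2 records
#'
#' Each whole-animal MO2 is reduced by the interpolated background rate times
#' the effective volume. Corrected values that fall below zero are floored at
#' zero and flagged invalid.
#'
#' @param records A `data.frame` of MO2 records ([slope_to_mo2()] rows).
#' @param model A [estimate_background()] model.
#' @param geom The [chamber_geometry()] used for the records.
#' @return `records` with `mo2_mg_h` corrected and `corrected = TRUE`.
#' @export
correct_background <- function(records, model, geom) {
  stopifnot(inherits(model, "background_model"),
            inherits(geom, "chamber_geometry"))
  bg <- background_at(model, records$t_mid_s) * geom$v_eff_l
  corrected <- records$mo2_mg_h - bg
  floored <- corrected < 0
  records$mo2_mg_h <- pmax(corrected, 0)
  records$valid <- records$valid & !floored
  records$corrected <- TRUE
  records
}

# Fast closed-form OLS slopes for a matrix of equal-length windows
# (columns = windows, rows = samples at common within-window times).
.matrix_slopes <- function(o2_mat, t_within) {
  tc <- t_within - mean(t_within)
  sxx <- sum(tc^2)
  slopes <- as.vector(crossprod(tc, o2_mat)) / sxx        # mg/L per s
  fitted_dev <- outer(tc, slopes)
  o2c <- sweep(o2_mat, 2, colMeans(o2_mat))
  sst <- colSums(o2c^2)
  ssr <- colSums((o2c - fitted_dev)^2)
  r2 <- ifelse(sst == 0, 1, 1 - ssr / sst)
  list(slope_mg_l_h = slopes * 3600, r2 = r2)
}

#' Process a full trace into a background-corrected MO2 table
#'
#' The standard per-trial driver: segments the trace, fits every measurement
#' window, converts slopes to whole-animal MO2, applies the slope-quality
#' filter, and (when a background model is given) subtracts microbial
#' respiration. For traces on a regular sampling grid the per-window OLS is
#' computed in closed form in one pass.
#'
#' @param trace An [oxygen_trace()].
#' @param geom A [chamber_geometry()].
#' @param schedule A [phase_schedule()].
#' @param background Optional [estimate_background()] model.
#' @param r2_min Minimum r-squared for a window to be retained as valid
#'   (default 0.9).
#' @return A `data.frame` with one row per measurement window: `phase`,
#'   `t_mid_s`, `mo2_mg_h`, `r2`, `valid`, `corrected`.
#' @export
process_trace <- function(trace, geom, schedule = phase_schedule(),
                          background = NULL, r2_min = 0.9) {
  empty <- data.frame(phase = integer(), t_mid_s = numeric(),
                      mo2_mg_h = numeric(), r2 = numeric(),
                      valid = logical(), corrected = logical())
  t <- trace$time_s
  dt_all <- diff(t)
  dt <- dt_all[1]
  n_per <- round((schedule$measure_s - schedule$discard_s) / dt)
  regular <- all(abs(dt_all - dt) < 1e-9) && n_per >= 10 &&
    abs(schedule$cycle_s / dt - round(schedule$cycle_s / dt)) < 1e-9 &&
    abs(schedule$discard_s / dt - round(schedule$discard_s / dt)) < 1e-9
  if (regular) {
    rel <- t - t[1]
    phase <- rel %/% schedule$cycle_s
    offset <- rel %% schedule$cycle_s
    retained <- offset >= schedule$discard_s & offset < schedule$measure_s
    n_phase <- max(phase) + 1
    complete <- which(tabulate(phase[retained] + 1L, n_phase) == n_per) - 1L
    if (!length(complete)) {
      warning("trace shorter than one measurement phase; no windows returned")
      return(empty)
    }
    keep <- retained & (phase %in% complete)
    o2_mat <- matrix(trace$o2_mg_l[keep], nrow = n_per)
    t_mat <- matrix(t[keep], nrow = n_per)
    fits <- .matrix_slopes(o2_mat, t_mat[, 1] - t_mat[1, 1])
    records <- data.frame(
      phase = complete,
      t_mid_s = (t_mat[1, ] + t_mat[n_per, ]) / 2,
      mo2_mg_h = pmax(-fits$slope_mg_l_h, 0) * geom$v_eff_l,
      r2 = fits$r2,
      valid = fits$slope_mg_l_h <= 0.01,
      corrected = FALSE)
  } else {
    windows <- segment_trace(trace, schedule)
    if (!length(windows)) return(empty)
    records <- do.call(rbind, lapply(windows, function(w) {
      rec <- slope_to_mo2(fit_slope(w), geom)
      cbind(phase = attr(w, "phase"), rec)
    }))
  }
  records$valid <- records$valid & records$r2 >= r2_min
  if (!is.null(background)) {
    records <- correct_background(records, background, geom)
  }
  rownames(records) <- NULL
  records
}
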