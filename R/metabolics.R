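#' Minimal measured metabolic rate (MR_min)
#'
#' Estimates MR_min as the mean of the lowest 10% of all MO2 measurements
#' from a trial (the decile-mean convention of the standard SMR
#' quantification literature). The alternative reading — the 10% quantile
#' point itself — is available via `method = "quantile"`.
#'
#' @param mo2 Numeric vector of (background-corrected) MO2 values, mg O2/h.
#' @param method `"lowest_decile_mean"` (default) or `"quantile"`.
#' @param n_min Minimum number of measurements required (default 10).
#' @return MR_min, mg O2 per hour.
#' @export
compute_mr_min <- function(mo2, method = c("lowest_decile_mean", "quantile"),
                           n_min = 10) {
  method <- match.arg(method)
  mo2 <- mo2[is.finite(mo2)]
  n <- length(mo2)
  if (n < n_min) {
    stop("need at least ", n_min, " MO2 measurements for MR_min; got ", n,
         call. = FALSE)
  }
  if (method == "quantile") {
    return(unname(stats::quantile(mo2, 0.10, type = 7)))
  }
  k <- ceiling(n / 10)
  mean(sort(mo2)[seq_len(k)])
}

#' Routine metabolic rate (RMR)
#'
#' Mean MO2 of the undisturbed animal, excluding an initial habituation
#' window (default: the first 5 h in the respirometer, over which MO2 is
#' still decaying from handling stress).
#'
#' @param mo2 Numeric vector of MO2 values, mg O2/h.
#' @param t_mid_s Window midpoints, seconds since trial start.
#' @param exclude_first_h Hours excluded from the start (default 5).
#' @return RMR, mg O2 per hour.
#' @export
compute_rmr <- function(mo2, t_mid_s, exclude_first_h = 5) {
  stopifnot(length(mo2) == length(t_mid_s))
  keep <- is.finite(mo2) & t_mid_s > exclude_first_h * 3600
  if (!any(keep)) {
    stop("no MO2 measurements after the first ", exclude_first_h,
         " h; cannot compute RMR", call. = FALSE)
  }
  mean(mo2[keep])
}

#' Maximum metabolic rate (MMR) from a post-chase recovery trace
#'
#' After exhaustive chase exercise the fish is sealed into the respirometer
#' and oxygen uptake measured for 8-10 min; uptake slopes are taken over
#' 3-min intervals and the greatest is MMR. Windows are consecutive and
#' non-overlapping by default; `rolling = TRUE` slides the window by one
#' sample instead.
#'
#' @param trace An [oxygen_trace()] of the recovery period (sealed; no
#'   flush phases).
#' @param geom A [chamber_geometry()].
#' @param window_s Slope window length, seconds (default 180).
#' @param rolling Use a rolling window instead of consecutive blocks.
#' @param background Optional [estimate_background()] model.
#' @return MMR, mg O2 per hour.
#' @export
compute_mmr <- function(trace, geom, window_s = 180, rolling = FALSE,
                        background = NULL) {
  t <- trace$time_s
  dt <- attr(trace, "sample_interval_s") %||% stats::median(diff(t))
  span <- t[length(t)] - t[1] + dt
  if (span < window_s) {
    stop("recovery trace (", round(span), " s) is shorter than one ",
         window_s, " s window", call. = FALSE)
  }
  n_per <- round(window_s / dt)
  starts <- if (rolling) {
    seq_len(length(t) - n_per + 1)
  } else {
    seq(1, length(t) - n_per + 1, by = n_per)
  }
  mo2 <- vapply(starts, function(i) {
    idx <- i:(i + n_per - 1)
    win <- data.frame(time_s = t[idx], o2_mg_l = trace$o2_mg_l[idx])
    rec <- slope_to_mo2(fit_slope(win), geom)
    if (!is.null(background)) {
      rec$mo2_mg_h <- rec$mo2_mg_h -
        background_at(background, rec$t_mid_s) * geom$v_eff_l
    }
    rec$mo2_mg_h
  }, numeric(1))
  max(mo2)
}

#' Initial stress response (ISR)
#'
#' The fraction of aerobic scope consumed by handling stress at the start of
#' a trial: `ISR = (FS - MR_min) / AS`, where FS is the first measurement
#' slope after transfer and AS = MMR - MR_min. Values outside \[0, 1\] are
#' returned as-is with attribute `out_of_range = TRUE`, not clamped.
#'
#' @param fs First-slope MO2, mg O2/h.
#' @param mr_min MR_min, mg O2/h.
#' @param aerobic_scope AS = MMR - MR_min, mg O2/h; must be positive.
#' @return ISR (unitless fraction).
#' @export
compute_isr <- function(fs, mr_min, aerobic_scope) {
  if (!is.finite(aerobic_scope) || aerobic_scope <= 0) {
    stop("aerobic scope must be positive; got ", aerobic_scope, call. = FALSE)
  }
  isr <- (fs - mr_min) / aerobic_scope
  if (isr < -1e-9 || isr > 1 + 1e-9) attr(isr, "out_of_range") <- TRUE
  isr
}

#' Social calming effect on MR_min
#'
#' Percentage reduction in MR_min when the focal fish is tested with
#' shoal-mate cues relative to testing alone:
#' `100 * (MR_min_alone - MR_min_group) / MR_min_alone`. An increase in the
#' group treatment yields a negative reduction.
#'
#' @param summary_alone,summary_group One-row summaries (as returned by
#'   [summarize_metabolics()]) for the same fish in the alone and group
#'   testing treatments, or bare numeric MR_min values.
#' @return A one-row `data.frame` with `fish_id` (if available) and
#'   `pct_reduction`.
#' @export
compute_calming <- function(summary_alone, summary_group) {
  get_val <- function(x) if (is.numeric(x)) x else x$mr_min
  get_id <- function(x) if (is.numeric(x)) NA_character_ else
    as.character(x$fish_id %||% NA_character_)
  id_a <- get_id(summary_alone); id_g <- get_id(summary_group)
  if (!is.na(id_a) && !is.na(id_g) && id_a != id_g) {
    stop("calming effect requires the same fish in both testing treatments (",
         id_a, " vs ", id_g, ")", call. = FALSE)
  }
  a <- get_val(summary_alone); g <- get_val(summary_group)
  stopifnot(is.finite(a), a > 0, is.finite(g))
  data.frame(fish_id = if (is.na(id_a)) id_g else id_a,
             pct_reduction = 100 * (a - g) / a)
}

#' Allometric mass correction of metabolic values
#'
#' For figures, metabolic rates are standardised to a common body mass by
#' residualising the log10(rate) ~ log10(mass) relationship: each residual
#' is added to the fitted value at the reference mass and back-transformed.
#' Inference is always run on whole-animal values with mass as a covariate;
#' this correction is presentation-layer only.
#'
#' @param values Metabolic values, mg O2/h (> 0).
#' @param mass_g Body masses, grams (> 0), same length.
#' @param reference_mass_g Reference mass (default 1.29 g, the study-wide
#'   mean).
#' @return Mass-corrected values at the reference mass.
#' @export
mass_correct <- function(values, mass_g, reference_mass_g = 1.29) {
  stopifnot(length(values) == length(mass_g))
  if (length(values) < 3) {
    stop("mass correction needs at least 3 fish", call. = FALSE)
  }
  if (any(values <= 0) || any(mass_g <= 0)) {
    stop("values and masses must be positive for log-log regression",
         call. = FALSE)
  }
  lv <- log10(values); lm_ <- log10(mass_g)
  if (stats::var(lm_) == 0) return(values)  # no leverage: residuals + fit at
                                            # the common mass reproduce values
  fit <- stats::lm(lv ~ lm_)
  fitted_ref <- unname(stats::coef(fit)[1] +
                         stats::coef(fit)[2] * log10(reference_mass_g))
  unname(10^(stats::residuals(fit) + fitted_ref))
}

#' Summarise one fish-by-testing respirometry trial
#'
#' Collapses a background-corrected MO2 table (plus the separately measured
#' MMR) into the per-trial metabolic statistics: MR_min, RMR, FS (first
#' slope after transfer), AS = MMR - MR_min, and ISR.
#'
#' @param mo2_tbl A [process_trace()] table; only `valid` rows are used for
#'   MR_min/RMR, but FS is the first valid measurement of the trial.
#' @param mmr MMR, mg O2/h (from [compute_mmr()] on the chase-recovery
#'   trace); `NA` allowed, in which case AS and ISR are `NA`.
#' @param fish_id,testing Identifiers carried into the output row.
#' @param mr_min_method,exclude_first_h Passed to [compute_mr_min()] /
#'   [compute_rmr()].
#' @return A one-row `data.frame`: `fish_id`, `testing`, `mr_min`, `rmr`,
#'   `fs`, `mmr`, `aerobic_scope`, `isr`, with a `flag_mrmin_gt_rmr` column
#'   marking ill-behaved trials.
#' @export
summarize_metabolics <- function(mo2_tbl, mmr = NA_real_,
                                 fish_id = NA_character_,
                                 testing = c("alone", "group"),
                                 mr_min_method = "lowest_decile_mean",
                                 exclude_first_h = 5) {
  testing <- match.arg(testing)
  ok <- mo2_tbl$valid
  mr_min <- compute_mr_min(mo2_tbl$mo2_mg_h[ok], method = mr_min_method)
  rmr <- compute_rmr(mo2_tbl$mo2_mg_h[ok], mo2_tbl$t_mid_s[ok],
                     exclude_first_h = exclude_first_h)
  fs <- mo2_tbl$mo2_mg_h[ok][1]
  aerobic_scope <- if (is.finite(mmr)) mmr - mr_min else NA_real_
  isr <- if (is.finite(aerobic_scope) && aerobic_scope > 0) {
    as.numeric(compute_isr(fs, mr_min, aerobic_scope))
  } else NA_real_
  data.frame(fish_id = fish_id, testing = testing,
             mr_min = mr_min, rmr = rmr, fs = fs, mmr = mmr,
             aerobic_scope = aerobic_scope, isr = isr,
             flag_mrmin_gt_rmr = mr_min > rmr)
}
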