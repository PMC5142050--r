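#' Read an oxygen trace from CSV
#'
#' Expects a comma-separated file with a header row and columns `time_s`,
#' `o2_mg_l` (UTF-8, '.' decimal separator). Validation failures name the
#' offending rows.
#'
#' @param path Path to the CSV file.
#' @param sample_interval_s Nominal sampling interval (default 2 s).
#' @return An [oxygen_trace()].
#' @export
read_trace_csv <- function(path, sample_interval_s = 2) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  missing_cols <- setdiff(c("time_s", "o2_mg_l"), names(d))
  if (length(missing_cols)) {
    stop("trace file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(d$time_s) | !is.finite(d$o2_mg_l))
  if (length(bad)) {
    stop("unparseable/missing values in ", path, " at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nonmono <- which(diff(d$time_s) <= 0)
  if (length(nonmono)) {
    stop("time_s not strictly increasing in ", path, " at data row(s): ",
         paste(utils::head(nonmono + 1, 5), collapse = ", "), call. = FALSE)
  }
  oxygen_trace(d$time_s, d$o2_mg_l, sample_interval_s)
}

#' Write an oxygen trace to CSV
#'
#' @param trace An [oxygen_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "o2_mg_l")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a choice-test trajectory from CSV
#'
#' Columns `time_s`, `x_cm`, `y_cm`.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` suitable for [score_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path)
  missing_cols <- setdiff(c("time_s", "x_cm", "y_cm"), names(d))
  if (length(missing_cols)) {
    stop("trajectory file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nonmono <- which(diff(d$time_s) <= 0)
  if (length(nonmono)) {
    stop("time_s not strictly increasing in ", path, " at data row(s): ",
         paste(utils::head(nonmono + 1, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' Analyze a simulated (or assembled) cohort end-to-end
#'
#' Runs the complete processing chain on a [simulate_cohort()] dataset:
#' background estimation and trace processing per fish and testing
#' treatment, MMR from the chase recovery, per-trial metabolic summaries,
#' calming effects, choice-trial scoring with the informed filter, and the
#' full inference layer.
#'
#' @param cohort A `cohort_dataset`.
#' @param r2_min Slope-quality threshold passed to [process_trace()].
#' @return A list: `summaries` (fish x testing metabolic rows joined with
#'   metadata), `calming`, `choice_results`, `inference` (named list of
#'   test results), and `log` (record counts at each filter).
#' @export
analyze_cohort <- function(cohort, r2_min = 0.9) {
  cfg <- cohort$config
  schedule <- phase_schedule(cfg$measure_s, cfg$flush_s, cfg$discard_s)
  out <- list()
  log <- list()

  if (!is.null(cohort$respirometry) && length(cohort$respirometry)) {
    meta <- cohort$metadata
    rows <- vector("list", 2 * nrow(meta))
    calming <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      fish <- cohort$respirometry[[meta$fish_id[i]]]
      geom <- chamber_geometry(meta$mass_g[i], cfg$chamber_volume_l)
      pre_fits <- lapply(segment_trace(fish$bg_pre, schedule), fit_slope)
      post_fits <- lapply(segment_trace(fish$bg_post, schedule), fit_slope)
      per_test <- lapply(c(alone = "alone", group = "group"), function(tst) {
        tr <- fish[[tst]]$trace
        bg <- estimate_background(pre_fits, post_fits, 0,
                                  max(tr$time_s))
        tbl <- process_trace(tr, geom, schedule, background = bg,
                             r2_min = r2_min)
        mmr <- compute_mmr(fish$chase$trace, geom)
        summarize_metabolics(tbl, mmr = mmr, fish_id = meta$fish_id[i],
                             testing = tst)
      })
      s <- do.call(rbind, per_test)
      rows[[2 * i - 1]] <- s[1, ]; rows[[2 * i]] <- s[2, ]
      calming[[i]] <- compute_calming(s[s$testing == "alone", ],
                                      s[s$testing == "group", ])
    }
    summaries <- do.call(rbind, rows)
    summaries <- merge(summaries,
                       meta[, c("fish_id", "shoal_id", "co2_uatm", "mass_g")],
                       by = "fish_id", sort = FALSE)
    out$summaries <- summaries
    out$calming <- do.call(rbind, calming)

    out$inference <- list(
      mr_min = metabolic_mixed_model(summaries, "mr_min"),
      rmr = metabolic_mixed_model(summaries, "rmr"),
      isr = metabolic_mixed_model(summaries, "isr"),
      mmr = fixed_effect_model(summaries[summaries$testing == "alone", ],
                               "mmr"),
      aerobic_scope = fixed_effect_model(
        summaries[summaries$testing == "alone", ], "aerobic_scope"))
  }

  if (!is.null(cohort$choice_trials) && length(cohort$choice_trials)) {
    cmeta <- cohort$choice_metadata
    scored <- vector("list", nrow(cmeta))
    for (i in seq_len(nrow(cmeta))) {
      trial <- cohort$choice_trials[[cmeta$fish_id[i]]]
      res <- score_trajectory(trial$trajectory, trial$zones)
      scored[[i]] <- cbind(cmeta[i, c("fish_id", "shoal_id", "co2_uatm",
                                      "familiar_side")],
                           res, n_attempts = trial$n_attempts)
    }
    choice_results <- do.call(rbind, scored)
    rownames(choice_results) <- NULL
    flt <- apply_informed_filter(choice_results)
    log$choice_informed <- nrow(flt$retained)
    log$choice_retest <- nrow(flt$retest)
    out$choice_results <- choice_results
    out$inference$preference <-
      preference_deviation_test(flt$retained)
    out$inference$initial_choice <- initial_choice_test(flt$retained)
    out$inference$visits <- fixed_effect_model(
      flt$retained, "total_visits", include_mass = FALSE)
  }
  out$log <- log
  out
}

#' Run the full simulated pipeline into an output directory
#'
#' Simulates a cohort, analyses it end-to-end and writes the result tables
#' (CSV) plus a run manifest (JSON: command, configuration hash, package
#' version, seed, timestamps). Output directories are write-once: a
#' directory that already holds a manifest is refused.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly; side effect: CSV/JSON files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    stop("output directory already contains a run manifest; ",
         "outputs are write-once per run directory", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  res <- analyze_cohort(cohort)

  utils::write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth,
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(res$summaries,
                   file.path(out_dir, "metabolic_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(res$calming, file.path(out_dir, "calming.csv"),
                   row.names = FALSE)
  utils::write.csv(res$choice_results,
                   file.path(out_dir, "choice_results.csv"),
                   row.names = FALSE)
  inf_rows <- do.call(rbind, lapply(names(res$inference), function(nm) {
    x <- res$inference[[nm]]
    tr <- if (is.data.frame(x)) x else x$terms
    data.frame(
      analysis = nm,
      term = if ("term" %in% names(tr)) tr$term
             else if ("treatment" %in% names(tr))
               paste0("deviation@", tr$treatment)
             else "treatment",
      statistic = if ("f" %in% names(tr)) tr$f else tr$chisq,
      df1 = if ("df1" %in% names(tr)) tr$df1 else tr$df,
      df2 = if ("df2" %in% names(tr)) tr$df2 else NA_real_,
      p = tr$p,
      method = tr$method)
  }))
  utils::write.csv(inf_rows, file.path(out_dir, "inference.csv"),
                   row.names = FALSE)

  cfg_file <- tempfile()
  writeLines(paste(deparse(unclass(config)), collapse = "\n"), cfg_file)
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("shoalresp")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = c("metadata.csv", "ground_truth.csv",
                "metabolic_summaries.csv", "calming.csv",
                "choice_results.csv", "inference.csv"))
  unlink(cfg_file)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
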