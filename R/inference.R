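#' Test for preference deviation from the 0.5 null
#'
#' For each CO2 treatment, tests whether the familiar-shoal preference
#' (time with the familiar shoal as a share of total shoaling time) deviates
#' from the no-preference null of 0.5. The deviation (`response - 0.5`) is
#' the response of an intercept-only linear mixed model with a random shoal
#' intercept (individuals are nested within their experimental shoal);
#' the intercept's Satterthwaite t-test is reported as an F (= t^2). When
#' the grouping is uninformative (one fish per shoal throughout, or a
#' degenerate fit) the test falls back to a one-sample t-test and says so.
#'
#' @param results A `data.frame` of informed choice results with columns
#'   for the response, treatment and shoal.
#' @param response,treatment_col,shoal_col Column names (defaults
#'   `"pref_familiar"`, `"co2_uatm"`, `"shoal_id"`).
#' @param null Null value of the response (default 0.5).
#' @return A `data.frame`, one row per treatment: `treatment`, `estimate`
#'   (mean deviation), `se`, `f`, `df1`, `df2`, `p`, `method`.
#' @export
preference_deviation_test <- function(results, response = "pref_familiar",
                                      treatment_col = "co2_uatm",
                                      shoal_col = "shoal_id", null = 0.5) {
  stopifnot(all(c(response, treatment_col, shoal_col) %in% names(results)))
  trts <- unique(results[[treatment_col]])
  rows <- lapply(trts, function(trt) {
    d <- results[results[[treatment_col]] == trt, ]
    dev <- d[[response]] - null
    shoal <- factor(d[[shoal_col]])
    fallback <- function(note) {
      tt <- stats::t.test(dev)
      data.frame(treatment = trt, estimate = mean(dev),
                 se = unname(tt$stderr),
                 f = unname(tt$statistic)^2, df1 = 1,
                 df2 = unname(tt$parameter), p = tt$p.value,
                 method = note)
    }
    if (stats::var(dev) == 0) {
      return(data.frame(treatment = trt, estimate = mean(dev), se = 0,
                        f = if (mean(dev) == 0) 0 else Inf, df1 = 1,
                        df2 = length(dev) - 1,
                        p = if (mean(dev) == 0) 1 else 0,
                        method = "degenerate (zero response variance)"))
    }
    if (nlevels(shoal) < 2 || nlevels(shoal) == length(dev)) {
      return(fallback("one-sample t (singular shoal grouping)"))
    }
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(dev ~ 1 + (1 | shoal),
                                      data = data.frame(dev = dev,
                                                        shoal = shoal))),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback("one-sample t (LMM failed)"))
    cf <- stats::coef(summary(fit))
    data.frame(treatment = trt, estimate = cf[1, "Estimate"],
               se = cf[1, "Std. Error"],
               f = cf[1, "t value"]^2, df1 = 1, df2 = cf[1, "df"],
               p = cf[1, "Pr(>|t|)"],
               method = "LMM random shoal intercept (Satterthwaite)")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomial mixed model for initial shoal choice
#'
#' Each informed trial contributes one binary outcome (first zone entered =
#' familiar). The treatment effect is assessed with a binomial generalized
#' mixed model with a random shoal intercept; the treatment Wald chi-square
#' is reported. Complete separation (or a failed fit) triggers a penalized
#' fallback: a fixed-effect logistic fit on data augmented with one
#' half-weight pseudo-success and pseudo-failure per treatment cell, with a
#' warning.
#'
#' @param results Informed choice results with an `initial_choice` column
#'   (`"familiar"`/`"unfamiliar"`), treatment and shoal columns.
#' @param treatment_col,shoal_col Column names.
#' @return A list with `terms` (a one-row `data.frame`: `chisq`, `df`, `p`,
#'   `method`) and the fitted `model`.
#' @export
initial_choice_test <- function(results, treatment_col = "co2_uatm",
                                shoal_col = "shoal_id") {
  stopifnot(all(c("initial_choice", treatment_col, shoal_col) %in%
                  names(results)))
  d <- results[results$initial_choice %in% c("familiar", "unfamiliar"), ]
  d <- data.frame(y = as.integer(d$initial_choice == "familiar"),
                  trt = factor(d[[treatment_col]]),
                  shoal = factor(d[[shoal_col]]))
  fit <- tryCatch(
    suppressMessages(lme4::glmer(y ~ trt + (1 | shoal), data = d,
                                 family = stats::binomial)),
    error = function(e) NULL, warning = function(w) NULL)
  separated <- is.null(fit) || any(abs(lme4::fixef(fit)) > 10)
  if (!separated) {
    an <- car::Anova(fit, type = "II")
    terms <- data.frame(chisq = an[["Chisq"]][1], df = an[["Df"]][1],
                        p = an[["Pr(>Chisq)"]][1],
                        method = "binomial GLMM, Wald chi-square")
    return(list(terms = terms, model = fit))
  }
  warning("separation or failed GLMM fit; using penalized fixed-effect ",
          "logistic fallback (data augmentation)")
  aug <- do.call(rbind, lapply(levels(d$trt), function(l) {
    data.frame(y = c(1L, 0L), trt = factor(l, levels = levels(d$trt)),
               w = 0.5)
  }))
  d$w <- 1
  dd <- rbind(d[, c("y", "trt", "w")], aug)
  fit2 <- suppressWarnings(stats::glm(y ~ trt, family = stats::binomial,
                                      data = dd, weights = w))
  an <- suppressWarnings(car::Anova(fit2, type = "II"))
  terms <- data.frame(chisq = an[["LR Chisq"]][1], df = an[["Df"]][1],
                      p = an[["Pr(>Chisq)"]][1],
                      method = "penalized logistic fallback")
  list(terms = terms, model = fit2)
}

#' Mixed model for within-fish metabolic endpoints
#'
#' Fits the repeated-measures model of the respirometry experiment: the
#' whole-animal endpoint as a Gaussian linear mixed model with CO2 treatment,
#' testing treatment (alone/group) and their interaction as fixed effects,
#' body mass as a covariate, and a random intercept per individual. Marginal
#' (type III) F tests use the Satterthwaite denominator-degrees-of-freedom
#' approximation, named in the output. Fish lacking either testing treatment
#' are dropped with a message.
#'
#' @param summaries A `data.frame` with one row per fish x testing
#'   treatment: columns `fish_id`, `co2_uatm`, `testing`, `mass_g` and the
#'   endpoint.
#' @param endpoint Column name of the response (e.g. `"mr_min"`, `"rmr"`,
#'   `"isr"`).
#' @param include_mass Include the body-mass covariate (default `TRUE`).
#' @return A list of class `shoalresp_inference`: `terms` (`term`, `f`,
#'   `df1`, `df2`, `p`, `method`), `model` (the `lmerModLmerTest` fit), and
#'   `dropped` (unpaired fish ids).
#' @export
metabolic_mixed_model <- function(summaries, endpoint, include_mass = TRUE) {
  stopifnot(all(c("fish_id", "co2_uatm", "testing", endpoint) %in%
                  names(summaries)))
  d <- data.frame(y = summaries[[endpoint]],
                  fish = factor(summaries$fish_id),
                  co2 = factor(summaries$co2_uatm),
                  testing = factor(summaries$testing,
                                   levels = c("alone", "group")),
                  mass = if (include_mass) summaries$mass_g else 0)
  counts <- table(d$fish)
  unpaired <- names(counts)[counts < 2]
  if (length(unpaired)) {
    message("dropping ", length(unpaired), " unpaired fish: ",
            paste(unpaired, collapse = ", "))
    d <- d[!(as.character(d$fish) %in% unpaired), ]
  }
  form <- if (include_mass) y ~ co2 * testing + mass + (1 | fish)
          else y ~ co2 * testing + (1 | fish)
  fit <- tryCatch(suppressMessages(lmerTest::lmer(form, data = d)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(
      terms = data.frame(term = "testing", f = NA_real_, df1 = NA_real_,
                         df2 = NA_real_, p = NA_real_,
                         method = paste("degenerate fit:",
                                        conditionMessage(fit))),
      model = NULL, dropped = unpaired), class = "shoalresp_inference"))
  }
  an <- suppressMessages(stats::anova(fit, type = 3,
                                      ddf = "Satterthwaite"))
  terms <- data.frame(term = rownames(an), f = an[["F value"]],
                      df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                      p = an[["Pr(>F)"]],
                      method = "LMM type III F, Satterthwaite ddf")
  rownames(terms) <- NULL
  structure(list(terms = terms, model = fit, dropped = unpaired),
            class = "shoalresp_inference")
}

#' Tukey pairwise contrasts for the CO2 factor
#'
#' All pairwise comparisons of a fitted model's three-level CO2 factor with
#' family-wise (Tukey) adjustment, alongside the unadjusted p-values.
#'
#' @param model A fitted model (`lmerMod`/`lmerModLmerTest` or `lm`) whose
#'   fixed effects include the factor, or a [metabolic_mixed_model()] /
#'   [fixed_effect_model()] result.
#' @param factor_name Name of the factor in the model frame (default
#'   `"co2"`).
#' @return A `data.frame`: `contrast`, `estimate`, `se`, `df`, `t`, `p_raw`,
#'   `p_adj`.
#' @export
tukey_contrasts <- function(model, factor_name = "co2") {
  if (inherits(model, "shoalresp_inference")) model <- model$model
  mf <- stats::model.frame(model)
  if (!factor_name %in% names(mf) || nlevels(factor(mf[[factor_name]])) < 3) {
    stop("tukey_contrasts needs a fitted factor '", factor_name,
         "' with at least 3 levels", call. = FALSE)
  }
  emm <- emmeans::emmeans(model, specs = factor_name,
                          lmer.df = "satterthwaite")
  adj <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  data.frame(contrast = adj$contrast, estimate = adj$estimate,
             se = adj$SE, df = adj$df, t = adj$t.ratio,
             p_raw = raw$p.value, p_adj = adj$p.value)
}

#' Fixed-effect model for once-per-fish endpoints
#'
#' MMR and aerobic scope are measured once per fish, so they are analysed
#' with a Gaussian fixed-effects model: endpoint ~ CO2 treatment + body
#' mass. Zero response variance returns a degenerate-fit notice instead of
#' test statistics.
#'
#' @param summaries One row per fish with `co2_uatm`, `mass_g` and the
#'   endpoint column.
#' @param endpoint Response column name (e.g. `"mmr"`, `"aerobic_scope"`).
#' @param include_mass Include the mass covariate (default `TRUE`).
#' @return A list of class `shoalresp_inference`: `terms` (term, `f`, `df1`,
#'   `df2`, `p`, `method`), `coefficients`, `model`.
#' @export
fixed_effect_model <- function(summaries, endpoint, include_mass = TRUE) {
  stopifnot(all(c("co2_uatm", endpoint) %in% names(summaries)))
  d <- data.frame(y = summaries[[endpoint]],
                  co2 = factor(summaries$co2_uatm),
                  mass = if (include_mass) summaries$mass_g else 0)
  if (stats::var(d$y) == 0) {
    return(structure(list(
      terms = data.frame(term = "co2", f = NA_real_, df1 = NA_real_,
                         df2 = NA_real_, p = NA_real_,
                         method = "degenerate fit: zero response variance"),
      coefficients = NULL, model = NULL), class = "shoalresp_inference"))
  }
  form <- if (include_mass) y ~ co2 + mass else y ~ co2
  fit <- stats::lm(form, data = d)
  an <- car::Anova(fit, type = "II")
  keep <- rownames(an) != "Residuals"
  terms <- data.frame(term = rownames(an)[keep], f = an[["F value"]][keep],
                      df1 = an[["Df"]][keep],
                      df2 = an["Residuals", "Df"],
                      p = an[["Pr(>F)"]][keep],
                      method = "Gaussian fixed-effects model, type II F")
  rownames(terms) <- NULL
  structure(list(terms = terms,
                 coefficients = summary(fit)$coefficients, model = fit),
            class = "shoalresp_inference")
}
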