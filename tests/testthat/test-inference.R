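make_pref_data <- function(pref, n_shoals = 9, per_shoal = 2, trt = 450) {
  data.frame(pref_familiar = pref,
             co2_uatm = trt,
             shoal_id = rep(sprintf("S%02d", seq_len(n_shoals)),
                            each = per_shoal)[seq_along(pref)])
}

test_that("preference test is exact at the null and detects strong preference", {
  d <- make_pref_data(rep(0.5, 18))
  res <- preference_deviation_test(d)
  expect_equal(res$estimate, 0)
  expect_equal(res$f, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)

  set.seed(1)
  d2 <- make_pref_data(pmin(pmax(rnorm(18, 0.75, 0.05), 0), 1))
  res2 <- preference_deviation_test(d2)
  expect_lt(res2$p, 0.001)
  expect_gt(res2$estimate, 0.2)
})

test_that("preference test falls back to a one-sample t with singular grouping", {
  d <- make_pref_data(seq(0.4, 0.6, length.out = 8), n_shoals = 8,
                      per_shoal = 1)
  res <- preference_deviation_test(d)
  expect_match(res$method, "t \\(")
  tt <- t.test(d$pref_familiar - 0.5)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("preference power at the study design is high for p_familiar = 0.75", {
  cfg <- sim_config(seed = 60, choice_shoal_sd_logit = 0.1)
  set.seed(60)
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    prefs <- vapply(1:18, function(i)
      event_level_choice(cfg, 0.75)$pref_familiar, numeric(1))
    p <- preference_deviation_test(make_pref_data(prefs))$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("initial-choice model is null at a 50/50 split and flags separation", {
  set.seed(2)
  d <- data.frame(initial_choice = rep(c("familiar", "unfamiliar"), 27),
                  co2_uatm = rep(c(450, 750, 1000), each = 18),
                  shoal_id = rep(sprintf("S%02d", 1:27), each = 2))
  res <- initial_choice_test(d)
  expect_lt(res$terms$chisq, 0.5)
  expect_gt(res$terms$p, 0.5)

  d2 <- d
  d2$initial_choice[d2$co2_uatm == 450] <- "familiar"  # complete separation
  expect_warning(res2 <- initial_choice_test(d2), "separation|penalized")
  expect_match(res2$terms$method, "penalized")
  expect_true(is.finite(res2$terms$chisq))
})

test_that("metabolic mixed model reports design-consistent df and a null testing effect when treatments coincide", {
  set.seed(3)
  n <- 30
  base <- data.frame(fish_id = sprintf("F%02d", 1:n),
                     co2_uatm = rep(c(450, 750, 1000), each = 10),
                     mass_g = runif(n, 1, 1.6))
  y <- 0.5 + 0.3 * base$mass_g + rnorm(n, 0, 0.05)
  summaries <- rbind(cbind(base, testing = "alone", mr_min = y),
                     cbind(base, testing = "group",
                           mr_min = y + rnorm(n, 0, 0.01)))
  fit <- metabolic_mixed_model(summaries, "mr_min")
  terms <- fit$terms
  testing_row <- terms[terms$term == "testing", ]
  expect_gt(testing_row$p, 0.05)
  # paired design arithmetic: interaction denominator df ~ 26-27
  inter <- terms[terms$term == "co2:testing", ]
  expect_equal(inter$df1, 2)
  expect_gt(inter$df2, 24)
  expect_lt(inter$df2, 29)
  expect_match(unique(terms$method), "Satterthwaite")
})

test_that("metabolic mixed model detects a 20% within-fish calming effect", {
  set.seed(4)
  n <- 30
  base <- data.frame(fish_id = sprintf("F%02d", 1:n),
                     co2_uatm = rep(c(450, 750, 1000), each = 10),
                     mass_g = runif(n, 1, 1.6))
  smr <- 0.49 * base$mass_g^0.8 * exp(rnorm(n, 0, 0.2))
  summaries <- rbind(
    cbind(base, testing = "alone",
          mr_min = smr * exp(rnorm(n, 0, 0.05))),
    cbind(base, testing = "group",
          mr_min = smr * 0.8 * exp(rnorm(n, 0, 0.05))))
  fit <- metabolic_mixed_model(summaries, "mr_min")
  expect_lt(fit$terms[fit$terms$term == "testing", "p"], 0.05)
})

test_that("unpaired fish are dropped with a message", {
  set.seed(5)
  summaries <- data.frame(fish_id = c("A", "A", "B"),
                          co2_uatm = 450, testing = c("alone", "group",
                                                      "alone"),
                          mass_g = c(1.2, 1.2, 1.4),
                          mr_min = c(0.5, 0.4, 0.6))
  # two fish only -> degenerate for lmer; add more paired fish
  extra <- do.call(rbind, lapply(3:14, function(i) {
    data.frame(fish_id = sprintf("X%02d", i),
               co2_uatm = sample(c(450, 750, 1000), 1),
               testing = c("alone", "group"),
               mass_g = runif(1, 1, 1.6),
               mr_min = runif(2, 0.4, 0.7))
  }))
  expect_message(fit <- metabolic_mixed_model(rbind(summaries, extra),
                                              "mr_min"), "unpaired")
  expect_equal(fit$dropped, "B")
})

test_that("estimates are equivariant under unit rescaling of the response", {
  set.seed(6)
  n <- 24
  base <- data.frame(fish_id = sprintf("F%02d", 1:n),
                     co2_uatm = rep(c(450, 750, 1000), each = 8),
                     mass_g = runif(n, 1, 1.6))
  smr <- runif(n, 0.4, 0.8)
  summaries <- rbind(cbind(base, testing = "alone",
                           mr_min = smr),
                     cbind(base, testing = "group",
                           mr_min = smr * runif(n, 0.7, 0.9)))
  f1 <- metabolic_mixed_model(summaries, "mr_min")
  summaries2 <- summaries; summaries2$mr_min <- summaries2$mr_min * 1000
  f2 <- metabolic_mixed_model(summaries2, "mr_min")
  expect_equal(f1$terms$f, f2$terms$f, tolerance = 1e-6)
  expect_equal(f1$terms$p, f2$terms$p, tolerance = 1e-6)
})

test_that("Tukey contrasts control the family-wise error and order p-values", {
  set.seed(7)
  n <- 30
  d <- data.frame(fish_id = sprintf("F%02d", 1:n),
                  co2_uatm = rep(c(450, 750, 1000), each = 10),
                  mass_g = runif(n, 1, 1.6))
  # one level shifted by ~3 SE
  d$mmr <- 1.5 + 0.2 * (d$co2_uatm == 1000) + rnorm(n, 0, 0.12)
  fit <- fixed_effect_model(d, "mmr")
  ct <- tukey_contrasts(fit)
  expect_equal(nrow(ct), 3)
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-12))
  sig <- ct$p_adj < 0.05
  shifted <- grepl("1000", ct$contrast)
  expect_true(all(sig[shifted]))
  expect_false(any(sig[!shifted]))

  # exactly identical group means: all contrasts are exact zeros
  d2 <- d; d2$mmr <- rep(1.5 + rnorm(10, 0, 0.1), 3)
  ct2 <- tukey_contrasts(fixed_effect_model(d2, "mmr", include_mass = FALSE))
  expect_equal(ct2$estimate, rep(0, 3))
  expect_true(all(ct2$p_adj > 0.99))

  two <- d[d$co2_uatm != 1000, ]
  expect_error(tukey_contrasts(fixed_effect_model(two, "mmr")), "3 levels")
})

test_that("fixed-effect model recovers the allometric mass slope and guards zero variance", {
  set.seed(8)
  n <- 60
  d <- data.frame(co2_uatm = rep(c(450, 750, 1000), each = 20),
                  mass_g = runif(n, 0.8, 2))
  d$mmr <- 1.2 * d$mass_g + rnorm(n, 0, 0.05)   # mass effect only
  fit <- fixed_effect_model(d, "mmr")
  expect_gt(fit$terms[fit$terms$term == "co2", "p"], 0.01)
  expect_equal(unname(fit$coefficients["mass", "Estimate"]), 1.2,
               tolerance = 0.05)

  # adding a constant changes the intercept only
  d2 <- d; d2$mmr <- d$mmr + 5
  fit2 <- fixed_effect_model(d2, "mmr")
  expect_equal(fit$terms$f, fit2$terms$f, tolerance = 1e-9)
  expect_equal(unname(fit2$coefficients["(Intercept)", "Estimate"]) -
                 unname(fit$coefficients["(Intercept)", "Estimate"]), 5,
               tolerance = 1e-9)

  d3 <- d; d3$mmr <- 1.0
  deg <- fixed_effect_model(d3, "mmr")
  expect_match(deg$terms$method, "degenerate")
})

test_that("permuting testing labels within fish keeps the testing test near its nominal level", {
  set.seed(9)
  n <- 30
  base <- data.frame(fish_id = sprintf("F%02d", 1:n),
                     co2_uatm = rep(c(450, 750, 1000), each = 10),
                     mass_g = runif(n, 1, 1.6))
  smr <- runif(n, 0.4, 0.8)
  reps <- 200
  rej <- 0
  for (r in seq_len(reps)) {
    flip <- sample(c(0, 1), n, replace = TRUE)
    y1 <- smr + rnorm(n, 0, 0.05)
    y2 <- smr + rnorm(n, 0, 0.05)
    summaries <- rbind(
      cbind(base, testing = ifelse(flip == 0, "alone", "group"),
            mr_min = y1),
      cbind(base, testing = ifelse(flip == 0, "group", "alone"),
            mr_min = y2))
    p <- metabolic_mixed_model(summaries, "mr_min")$terms
    rej <- rej + (p[p$term == "testing", "p"] < 0.05)
  }
  expect_gt(rej / reps, 0.01)
  expect_lt(rej / reps, 0.10)
})
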