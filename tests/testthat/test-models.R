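test_that("closed-form OLS engine agrees with the reference least-squares fit", {
  set.seed(101)
  cohort <- generate_cohort(sim_config(n_participants = 80, seed = 101))
  h1 <- prepare_h1(cohort$records)
  fit <- fit_dual_slopes(h1, engine = "ols")
  ref <- stats::lm(
    ambivalence ~ (small_mag + a1 + a2 + a3 + small_mag:a1 +
      small_mag:a2 + small_mag:a3) * (pre_term + post_term),
    data = h1
  )
  b_ref <- coef(ref)
  expect_equal(nrow(fit$terms), 24L)
  expect_equal(fit$terms$estimate, unname(b_ref), tolerance = 1e-10)
  expect_equal(
    fit$terms$std_error,
    unname(sqrt(diag(stats::vcov(ref)))),
    tolerance = 1e-10
  )
})

test_that("Newton-Raphson logistic engine agrees with the reference GLM", {
  cohort <- generate_cohort(sim_config(
    n_participants = 60, seed = 102,
    sensitivity_mode = "sensitivity_based"
  ))
  h2 <- prepare_h2(cohort$records)
  fit <- fit_choice_model(h2, "AmbMag", engine = "newton")
  X <- as.data.frame(mcqamb:::.h2_design(h2, "AmbMag"))
  names(X) <- paste0("x", seq_along(X))
  X$y <- h2$choice_ll
  ref <- stats::glm(y ~ 0 + ., data = X, family = binomial())
  expect_equal(nrow(fit$terms), 32L)
  expect_equal(fit$terms$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  expect_equal(
    fit$terms$std_error,
    unname(sqrt(diag(stats::vcov(ref)))),
    tolerance = 1e-3
  )
})

test_that("Wald intervals and odds ratios follow the closed form b +/- 1.96 se", {
  cohort <- generate_cohort(sim_config(
    n_participants = 50, seed = 103,
    sensitivity_mode = "sensitivity_based"
  ))
  h2 <- prepare_h2(cohort$records)
  td <- tidy(fit_choice_model(h2, "Base", engine = "newton"))
  expect_equal(td$conf_low, td$estimate - 1.96 * td$std_error)
  expect_equal(td$conf_high, td$estimate + 1.96 * td$std_error)
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$p_value, 2 * pnorm(-abs(td$estimate / td$std_error)))
})

test_that("mixed and fixed-effects fits agree when there is no between-person variance", {
  # flat peak-height interval and no flat subpopulation: the only grouping
  # structure left is residual noise, so REML should find ~zero variances
  cfg <- sim_config(
    n_participants = 150, seed = 104, amb_shape = "linear",
    choice_noise = 1e4, p_flat_ambivalence = 0, p_extreme = 0,
    amb_peak_height_range = c(7, 7), amb_noise_sd = 0.8
  )
  cohort <- generate_cohort(cfg)
  h1 <- prepare_h1(cohort$records)
  mixed <- suppressMessages(fit_dual_slopes(h1))
  ols <- fit_dual_slopes(h1, engine = "ols")
  expect_lt(max(abs(mixed$terms$estimate - ols$terms$estimate)), 1e-3)

  cfg2 <- sim_config(
    n_participants = 100, seed = 105,
    sensitivity_mode = "sensitivity_based", gamma_amb_delay = 0,
    beta_delay_small = 0, p_flat_ambivalence = 0
  )
  h2 <- prepare_h2(generate_cohort(cfg2)$records)
  # the logistic mixed machinery, evaluated at the generating (zero)
  # random-slope variance, profiles out exactly the Newton-Raphson fit
  library(lme4)
  dat <- data.frame(
    y = h2$choice_ll, mr = h2$mag_ratio, dr = h2$delay_ratio,
    pid = h2$participant_id
  )
  mod <- glFormula(y ~ 0 + mr + dr + (0 + mr + dr | pid),
    data = dat, family = binomial()
  )
  devf <- do.call(mkGlmerDevfun, mod)
  devf(c(0, 0, 0))
  beta <- environment(devf)$pp$beta(1)
  nw <- fit_choice_model(h2, "Base", engine = "newton")
  expect_lt(max(abs(beta - nw$terms$estimate)), 1e-3)
  # the freely estimated mixed fit agrees on every sign of the full model
  gl <- suppressMessages(fit_choice_model(h2, "AmbMag", engine = "glmer"))
  nw_full <- fit_choice_model(h2, "AmbMag", engine = "newton")
  expect_equal(
    sign(gl$terms$estimate[match(nw_full$terms$term, gl$terms$term)]),
    sign(nw_full$terms$estimate)
  )
})

test_that("the slope-asymmetry contrast is the delta-method linear contrast", {
  fit <- fake_fit("dual_slopes", 0)
  fit$terms <- tibble::tibble(
    term = c("Pre-Switch", "Post-Switch"),
    estimate = c(0.37, -0.53)
  )
  fit$vcov <- matrix(c(4e-4, 1e-4, 1e-4, 16e-4), 2, 2,
    dimnames = list(
      c("Pre-Switch", "Post-Switch"),
      c("Pre-Switch", "Post-Switch")
    )
  )
  out <- slope_asymmetry_contrast(fit)
  expect_equal(out$estimate, 0.16)
  expect_equal(out$std_error, sqrt(4e-4 + 16e-4 + 2e-4))
  # symmetric slopes -> zero contrast
  fit$terms$estimate <- c(0.4, -0.4)
  expect_equal(slope_asymmetry_contrast(fit)$estimate, 0)
  fit$vcov <- matrix(0, 0, 0)
  expect_error(slope_asymmetry_contrast(fit), "covariance")
})

test_that("AIC preference requires a margin of 4 over every rival", {
  fits <- list(
    AmbMag = fake_fit("AmbMag", 4112.0),
    BaseAmbMag = fake_fit("BaseAmbMag", 4159.0),
    Base = fake_fit("Base", 4306.1)
  )
  cmp <- compare_aic(fits)
  expect_equal(cmp$preferred, "AmbMag")
  expect_equal(cmp$table$model, c("AmbMag", "BaseAmbMag", "Base"))
  expect_equal(max(cmp$table$delta), 4306.1 - 4112.0)
  # order of the list must not matter
  expect_equal(compare_aic(rev(fits))$preferred, "AmbMag")
  # margins below 4, or exact ties, yield no preference
  near <- list(A = fake_fit("A", 100), B = fake_fit("B", 103))
  expect_equal(compare_aic(near)$preferred, "no preference")
  tied <- list(A = fake_fit("A", 100), B = fake_fit("B", 100))
  expect_equal(compare_aic(tied)$preferred, "no preference")
  bad <- list(A = fake_fit("A", 100, n_obs = 50), B = fake_fit("B", 90))
  expect_error(compare_aic(bad), "differing numbers of observations")
})

test_that("nested choice models never lose log-likelihood as terms are added", {
  cohort <- generate_cohort(sim_config(
    n_participants = 80, seed = 106,
    sensitivity_mode = "sensitivity_based"
  ))
  h2 <- prepare_h2(cohort$records)
  lls <- vapply(
    c("Base", "BaseAmbMag", "AmbMag"),
    function(m) fit_choice_model(h2, m, engine = "newton")$log_lik,
    numeric(1)
  )
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("the paired magnitude-effect test matches closed-form arithmetic", {
  # differences 0.5, 0.7, 0.6: mean 0.6, sd 0.1, t = 0.6 / (0.1 / sqrt(3))
  out <- magnitude_effect_test(c(1.5, 1.7, 1.6), c(1, 1, 1))
  expect_equal(out$mean_diff, 0.6)
  expect_equal(out$sd_diff, 0.1)
  expect_equal(out$t, 10.392, tolerance = 1e-4)
  expect_equal(out$df, 2)
  expect_equal(out$cohens_d, 6)
  ref <- t.test(c(1.5, 1.7, 1.6), c(1, 1, 1), paired = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
  expect_error(magnitude_effect_test(1:3, 1:3), "zero variance")
  expect_error(magnitude_effect_test(1:3, 1:4), "equal length")
})

test_that("tidy and glance expose coefficient tables and fit summaries", {
  cohort <- generate_cohort(sim_config(n_participants = 60, seed = 107))
  h1 <- prepare_h1(cohort$records)
  fit <- fit_dual_slopes(h1, engine = "ols")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("Pre-Switch", "Post-Switch", "SmallMag:A1:Pre-Switch") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(h1))
  expect_equal(gl$engine, "ols")
})
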