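# Dual-slopes mixed model of switch-centered ambivalence, nested logistic
# choice models with reward sensitivities, AIC comparison, and the
# magnitude-effect quality check. Mixed fits go through lme4; the
# fixed-effects-only engines (closed-form least squares, Newton-Raphson
# logistic) are implemented directly and double as test oracles.

.wald_terms <- function(b, vc, logistic = FALSE) {
  se <- sqrt(diag(vc))
  z <- b / se
  out <- tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf_low = unname(b - 1.96 * se),
    conf_high = unname(b + 1.96 * se)
  )
  if (logistic) {
    out <- dplyr::mutate(out, odds_ratio = exp(.data$estimate), .before = "estimate")
  }
  out
}

.new_mcq_fit <- function(terms, vcov, aic, log_lik, n_obs, n_groups,
                         ranef_var, converged, singular, engine, family,
                         label) {
  structure(
    list(
      terms = terms, vcov = vcov, aic = aic, log_lik = log_lik,
      n_obs = n_obs, n_groups = n_groups, ranef_var = ranef_var,
      converged = converged, singular = singular, engine = engine,
      family = family, label = label
    ),
    class = "mcq_fit"
  )
}

# closed-form ordinary least squares: coefficients, vcov, Gaussian logLik
.ols_fit <- function(X, y) {
  XtX <- crossprod(X)
  b <- drop(solve(XtX, crossprod(X, y)))
  names(b) <- colnames(X)
  res <- drop(y - X %*% b)
  n <- length(y)
  p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  vc <- sigma2 * solve(XtX)
  sigma2_ml <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  list(b = b, vcov = vc, log_lik = ll, aic = 2 * (p + 1) - 2 * ll)
}

# Newton-Raphson (iteratively reweighted least squares) logistic regression
.newton_logistic <- function(X, y, max_iter = 100L, tol = 1e-10) {
  b <- rep(0, ncol(X))
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, crossprod(X, y - mu)),
      error = function(e) NULL
    )
    if (is.null(step)) break
    b <- b + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  names(b) <- colnames(X)
  eta <- drop(X %*% b)
  separated <- any(abs(eta) > 30)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(X, X * w))
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(
    b = b, vcov = vc, log_lik = ll, aic = 2 * ncol(X) - 2 * ll,
    converged = converged && !separated, separated = separated
  )
}

.lme4_converged <- function(fit) {
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  msgs <- fit@optinfo$conv$lme4$messages
  opt_ok && length(msgs) == 0L
}

.dual_slopes_rename <- c(
  "(Intercept)" = "(Intercept)", small_mag = "SmallMag",
  a1 = "A1", a2 = "A2", a3 = "A3",
  pre_term = "Pre-Switch", post_term = "Post-Switch"
)

.rename_terms <- function(terms) {
  vapply(strsplit(terms, ":", fixed = TRUE), function(parts) {
    paste(ifelse(parts %in% names(.dual_slopes_rename),
      .dual_slopes_rename[parts], parts
    ), collapse = ":")
  }, character(1))
}

#' Fit the dual-slopes model of switch-centered ambivalence
#'
#' Models the 0-10 ambivalence score as piecewise linear in the
#' switch-centered trial number, with separate slopes before
#' (`Pre-Switch = min(centered, 0)`) and after
#' (`Post-Switch = max(centered, 0)`) the switch trial and the intercept
#' placed on the switch trial itself. Effects-coded magnitude and
#' ambivalence-condition factors enter both as main effects and in
#' interaction with the two slopes. The default engine is a linear mixed
#' model (REML) with random intercepts and random pre/post slopes by
#' participant; `engine = "ols"` is a fixed-effects-only closed-form
#' least-squares fit used as an independent oracle. Confidence intervals are
#' Wald (`b` +/- 1.96 SE) and p-values Wald z.
#'
#' @param h1 Prepared table from [prepare_h1()].
#' @param engine `"lmer"` (mixed, default) or `"ols"` (fixed effects only).
#' @param reml Use REML for the mixed fit.
#' @return An object of class `mcq_fit`; see [tidy.mcq_fit()] and
#'   [glance.mcq_fit()].
#' @export
fit_dual_slopes <- function(h1, engine = c("lmer", "ols"), reml = TRUE, ...) {
  engine <- match.arg(engine)
  need <- c(
    "participant_id", "ambivalence", "pre_term", "post_term",
    "small_mag", "a1", "a2", "a3"
  )
  missing <- setdiff(need, names(h1))
  if (length(missing)) {
    stop("`h1` is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  fixed <- ambivalence ~ (small_mag + a1 + a2 + a3 + small_mag:a1 +
    small_mag:a2 + small_mag:a3) * (pre_term + post_term)
  if (engine == "ols") {
    X <- stats::model.matrix(fixed, data = h1)
    fit <- .ols_fit(X, h1$ambivalence)
    terms <- .wald_terms(fit$b, fit$vcov)
    terms$term <- .rename_terms(terms$term)
    vc <- fit$vcov
    dimnames(vc) <- list(terms$term, terms$term)
    return(.new_mcq_fit(
      terms, vc, fit$aic, fit$log_lik, nrow(h1),
      dplyr::n_distinct(h1$participant_id), numeric(0),
      TRUE, FALSE, "ols", "gaussian", "dual_slopes"
    ))
  }
  form <- stats::update(
    fixed,
    . ~ . + (pre_term + post_term | participant_id)
  )
  fit <- lme4::lmer(form, data = h1, REML = reml, ...)
  b <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  terms <- .wald_terms(b, vc)
  terms$term <- .rename_terms(terms$term)
  dimnames(vc) <- list(terms$term, terms$term)
  vc_re <- lme4::VarCorr(fit)$participant_id
  re_var <- stats::setNames(diag(vc_re), .rename_terms(rownames(vc_re)))
  re_var <- c(re_var, residual = stats::sigma(fit)^2)
  .new_mcq_fit(
    terms, vc, stats::AIC(fit), as.numeric(stats::logLik(fit)),
    nrow(h1), dplyr::n_distinct(h1$participant_id), re_var,
    .lme4_converged(fit), lme4::isSingular(fit), "lmer", "gaussian",
    "dual_slopes"
  )
}

#' Contrast of post- versus pre-switch slope steepness
#'
#' Tests whether ambivalence falls away from the switch trial more sharply
#' than it rises toward it: the linear contrast
#' `|Post-Switch| - Pre-Switch = -Post-Switch - Pre-Switch` (the post slope
#' is negative when ambivalence peaks at the switch), with a delta-method
#' standard error from the fitted fixed-effect covariance and a Wald z
#' p-value (two-sided).
#'
#' @param fit An `mcq_fit` from [fit_dual_slopes()].
#' @return One-row tibble with `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
slope_asymmetry_contrast <- function(fit) {
  stopifnot(inherits(fit, "mcq_fit"))
  need <- c("Pre-Switch", "Post-Switch")
  if (!all(need %in% fit$terms$term) || !all(need %in% rownames(fit$vcov))) {
    stop("`fit` must contain Pre-Switch and Post-Switch terms and their covariance.",
      call. = FALSE
    )
  }
  b <- stats::setNames(fit$terms$estimate, fit$terms$term)
  est <- -b[["Post-Switch"]] - b[["Pre-Switch"]]
  v <- fit$vcov["Post-Switch", "Post-Switch"] +
    fit$vcov["Pre-Switch", "Pre-Switch"] +
    2 * fit$vcov["Pre-Switch", "Post-Switch"]
  se <- sqrt(v)
  tibble::tibble(
    estimate = est, std_error = se, statistic = est / se,
    p_value = 2 * stats::pnorm(-abs(est / se))
  )
}

# All fixed-effect columns of the choice models contain a reward sensitivity
# (terms without one are dropped, including the intercept by default). Each
# sensitivity is crossed with none/some of: effects-coded magnitude, the
# three ambivalence-condition contrasts, and the ambivalence score.
.h2_design <- function(h2, model) {
  with_pairing <- model %in% c("BaseAmbMag", "AmbMag")
  with_amb <- model == "AmbMag"
  sens <- c(MagRatio = "mag_ratio", DelayRatio = "delay_ratio")
  amb_levels <- c(A1 = "a1", A2 = "a2", A3 = "a3")
  cols <- list()
  for (s in names(sens)) {
    base <- h2[[sens[s]]]
    sm_opts <- if (with_pairing) c(FALSE, TRUE) else FALSE
    aj_opts <- if (with_pairing) c(NA, names(amb_levels)) else NA
    amb_opts <- if (with_amb) c(FALSE, TRUE) else FALSE
    for (amb in amb_opts) {
      for (sm in sm_opts) {
        for (aj in aj_opts) {
          col <- base
          name <- s
          if (sm) {
            col <- col * h2$small_mag
            name <- paste(name, "SmallMag", sep = ":")
          }
          if (!is.na(aj)) {
            col <- col * h2[[amb_levels[aj]]]
            name <- paste(name, aj, sep = ":")
          }
          if (amb) {
            col <- col * h2$amb_score
            name <- paste(name, "AmbScore", sep = ":")
          }
          cols[[name]] <- col
        }
      }
    }
  }
  do.call(cbind, cols)
}

#' Fit a trial-level logistic choice model
#'
#' Predicts the probability of choosing the larger-later reward from the
#' reward sensitivities (the natural-log magnitude and delay ratios), in one
#' of three nested specifications: `"Base"` (sensitivities only),
#' `"BaseAmbMag"` (sensitivities crossed with the effects-coded
#' magnitude-ambivalence pairing factors), and `"AmbMag"` (additionally
#' crossed with the 0-10 ambivalence score, whose interaction with the delay
#' sensitivity carries the ambivalence-attenuation hypothesis). Every fixed
#' term contains a sensitivity; terms without one -- including the intercept,
#' unless `intercept = TRUE` -- are excluded. The default engine is a
#' logistic mixed model (lme4) with per-participant random slopes on both
#' sensitivities; `engine = "newton"` is a fixed-effects-only Newton-Raphson
#' fit, exact on cohorts without between-participant sensitivity variation
#' and used as the oracle and in large replicate sweeps.
#'
#' @param h2 Prepared table from [prepare_h2()].
#' @param model `"Base"`, `"BaseAmbMag"` or `"AmbMag"`.
#' @param engine `"glmer"` (mixed, default) or `"newton"`.
#' @param intercept Include a fixed intercept (default `FALSE`, matching the
#'   term-dropping rule read literally).
#' @param random_intercept Add a per-participant random intercept to the
#'   mixed fit (default `FALSE`).
#' @param ... Passed to the lme4 fitting function (e.g. `control`).
#' @param nAGQ Integration setting passed to [lme4::glmer()]; the default 0
#'   is fast and adequate for sign/CI behaviour.
#' @return An object of class `mcq_fit` (with odds ratios in its term table).
#' @export
fit_choice_model <- function(h2, model = c("AmbMag", "BaseAmbMag", "Base"),
                             engine = c("glmer", "newton"),
                             intercept = FALSE, random_intercept = FALSE,
                             nAGQ = 0L, ...) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  need <- c(
    "participant_id", "choice_ll", "mag_ratio", "delay_ratio",
    "amb_score", "small_mag", "a1", "a2", "a3"
  )
  missing <- setdiff(need, names(h2))
  if (length(missing)) {
    stop("`h2` is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  X <- .h2_design(h2, model)
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  y <- h2$choice_ll
  n_groups <- dplyr::n_distinct(h2$participant_id)

  if (engine == "newton") {
    fit <- .newton_logistic(X, y)
    terms <- .wald_terms(fit$b, fit$vcov, logistic = TRUE)
    return(.new_mcq_fit(
      terms, fit$vcov, fit$aic, fit$log_lik, nrow(h2), n_groups,
      numeric(0), fit$converged, fit$separated, "newton", "binomial", model
    ))
  }

  dat <- tibble::as_tibble(as.data.frame(X, optional = TRUE), .name_repair = "minimal")
  safe <- gsub("[:()]", "_", colnames(X))
  names(dat) <- safe
  dat$.y <- y
  dat$.pid <- h2$participant_id
  dat$.mag_ratio <- h2$mag_ratio
  dat$.delay_ratio <- h2$delay_ratio
  re <- if (random_intercept) {
    "(1 + .mag_ratio + .delay_ratio | .pid)"
  } else {
    "(0 + .mag_ratio + .delay_ratio | .pid)"
  }
  form <- stats::as.formula(paste(
    ".y ~ 0 +", paste(sprintf("`%s`", safe), collapse = " + "), "+", re
  ))
  fit <- lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = nAGQ, ...)
  b <- lme4::fixef(fit)
  names(b) <- colnames(X)[match(names(b), safe)]
  vc <- as.matrix(stats::vcov(fit))
  dimnames(vc) <- list(names(b), names(b))
  terms <- .wald_terms(b, vc, logistic = TRUE)
  vc_re <- lme4::VarCorr(fit)$.pid
  re_names <- sub("^\\.", "", rownames(vc_re))
  re_var <- stats::setNames(diag(vc_re), re_names)
  .new_mcq_fit(
    terms, vc, stats::AIC(fit), as.numeric(stats::logLik(fit)),
    nrow(h2), n_groups, re_var, .lme4_converged(fit),
    lme4::isSingular(fit), "glmer", "binomial", model
  )
}

#' Compare fitted choice models by AIC
#'
#' Lower AIC indicates the preferred model, but a model is only preferred
#' outright when its AIC undercuts every rival's by at least `margin`
#' (default 4); otherwise the comparison returns `"no preference"`.
#'
#' @param fits Named list of `mcq_fit` objects fitted to the same
#'   observations (same rows); unnamed lists use each fit's model label.
#' @param margin Minimum AIC difference required to prefer a model.
#' @return An object of class `mcq_model_comparison`: a list with `table`
#'   (model, AIC, delta versus the minimum) and `preferred`.
#' @export
compare_aic <- function(fits, margin = 4) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  if (!all(vapply(fits, inherits, logical(1), "mcq_fit"))) {
    stop("`fits` must be a list of mcq_fit objects.", call. = FALSE)
  }
  labels <- names(fits)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(fits, `[[`, character(1), "label")
  }
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L) {
    stop("Models were fitted to differing numbers of observations (",
      paste(n_obs, collapse = ", "), "); AICs are not comparable.",
      call. = FALSE
    )
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  tab <- tibble::tibble(model = labels, aic = aic, delta = aic - min(aic))
  tab <- dplyr::arrange(tab, .data$aic)
  margins <- tab$aic[-1L] - tab$aic[1L]
  preferred <- if (length(margins) && all(margins >= margin)) {
    tab$model[1L]
  } else {
    "no preference"
  }
  structure(list(table = tab, preferred = preferred, margin = margin),
    class = "mcq_model_comparison"
  )
}

#' Paired test of the magnitude effect on log discount rates
#'
#' A paired t-test of within-participant differences in natural-log
#' discount rates between the small and large magnitude conditions
#' (`diff = ln k_small - ln k_large`): `t = mean(diff) / (sd(diff) / sqrt(n))`
#' on `n - 1` degrees of freedom, two-sided. The paired Cohen's d is
#' `mean(diff) / sd(diff)`.
#'
#' @param ln_k_small,ln_k_large Equal-length paired vectors of log discount
#'   rates.
#' @return One-row tibble with `t`, `df`, `p_value`, `mean_diff`, `sd_diff`,
#'   `cohens_d`, `n`.
#' @export
magnitude_effect_test <- function(ln_k_small, ln_k_large) {
  if (length(ln_k_small) != length(ln_k_large)) {
    stop("Paired vectors must have equal length.", call. = FALSE)
  }
  n <- length(ln_k_small)
  if (n < 2L) stop("Need at least two pairs.", call. = FALSE)
  d <- ln_k_small - ln_k_large
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("Differences have zero variance; the paired t statistic is undefined.",
      call. = FALSE
    )
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  tibble::tibble(
    t = t_stat, df = n - 1, p_value = 2 * stats::pt(-abs(t_stat), n - 1),
    mean_diff = mean(d), sd_diff = sd_d, cohens_d = mean(d) / sd_d, n = n
  )
}

#' Cohort-level data-quality summary
#'
#' Runs the paired magnitude-effect test on the scored log discount rates
#' and reports the proportion of participants with perfect consistency
#' (response patterns at consistency 1.0 when averaging the two magnitude
#' conditions). Because non-switching trial sets receive a boundary item
#' rate by convention rather than an estimate, the default excludes pairs
#' where either condition failed to switch from the t-test
#' (`boundary = "include"` keeps them, each contributing its assigned
#' endpoint rates).
#'
#' @param scored Output of [score_mcq()].
#' @param boundary `"exclude"` (default) or `"include"` non-switching trial
#'   sets in the paired test.
#' @return One-row tibble: the [magnitude_effect_test()] columns plus
#'   `perfect_consistency_prop` and `n_participants`.
#' @export
mcq_quality <- function(scored, boundary = c("exclude", "include")) {
  boundary <- match.arg(boundary)
  wide <- tidyr::pivot_wider(
    dplyr::select(
      scored, "participant_id", "magnitude", "ln_k",
      "consistency", "is_nonswitcher"
    ),
    names_from = "magnitude",
    values_from = c("ln_k", "consistency", "is_nonswitcher")
  )
  wide <- tidyr::drop_na(wide)
  perfect <- mean((wide$consistency_small + wide$consistency_large) / 2 == 1)
  pairs <- if (boundary == "exclude") {
    dplyr::filter(wide, !.data$is_nonswitcher_small, !.data$is_nonswitcher_large)
  } else {
    wide
  }
  test <- magnitude_effect_test(pairs$ln_k_small, pairs$ln_k_large)
  test$perfect_consistency_prop <- perfect
  test$n_participants <- nrow(wide)
  test
}
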