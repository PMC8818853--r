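# broom-style accessors and print methods for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficient table of a fitted model
#'
#' @param x An `mcq_fit` from [fit_dual_slopes()] or [fit_choice_model()].
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, Wald `conf_low`/`conf_high`, and
#'   `odds_ratio` for logistic fits.
#' @export
tidy.mcq_fit <- function(x, ...) {
  x$terms
}

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.mcq_fit
#' @return A tibble with `model`, `engine`, `n_obs`, `n_groups`, `aic`,
#'   `log_lik`, `converged`, `singular`.
#' @export
glance.mcq_fit <- function(x, ...) {
  tibble::tibble(
    model = x$label, engine = x$engine, n_obs = x$n_obs,
    n_groups = x$n_groups, aic = x$aic, log_lik = x$log_lik,
    converged = x$converged, singular = x$singular
  )
}

#' @method print mcq_fit
#' @export
print.mcq_fit <- function(x, ...) {
  cat(
    sprintf(
      "<mcq_fit> %s (%s, %s), %d obs / %d participants, AIC %.1f%s\n",
      x$label, x$engine, x$family, x$n_obs, x$n_groups, x$aic,
      if (!x$converged) " [NOT CONVERGED]" else if (x$singular) " [singular]" else ""
    )
  )
  print(x$terms, n = nrow(x$terms))
  if (length(x$ranef_var)) {
    cat("Random-effect variances:\n")
    print(round(x$ranef_var, 4))
  }
  invisible(x)
}

#' Tidy an AIC model comparison
#'
#' @param x An `mcq_model_comparison` from [compare_aic()].
#' @param ... Unused.
#' @return Tibble with `model`, `aic`, `delta` (versus the best model).
#' @export
tidy.mcq_model_comparison <- function(x, ...) {
  x$table
}

#' @method print mcq_model_comparison
#' @export
print.mcq_model_comparison <- function(x, ...) {
  cat(sprintf(
    "<mcq_model_comparison> preferred: %s (margin >= %g)\n",
    x$preferred, x$margin
  ))
  print(x$table)
  invisible(x)
}
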