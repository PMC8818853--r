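# Switch-centered figures: trial-level mean ambivalence with standard-error
# bars per magnitude-ambivalence pairing, overlaid with dual-slopes model
# predictions.

.h1_population_prediction <- function(fit, grid) {
  codes <- effects_code(grid$magnitude, grid$amb_condition)
  grid$pre_term <- pmin(grid$centered_trial, 0)
  grid$post_term <- pmax(grid$centered_trial, 0)
  b <- stats::setNames(fit$terms$estimate, fit$terms$term)
  cols <- list(
    "(Intercept)" = rep(1, nrow(grid)),
    "SmallMag" = codes$small_mag, "A1" = codes$a1, "A2" = codes$a2,
    "A3" = codes$a3, "Pre-Switch" = grid$pre_term,
    "Post-Switch" = grid$post_term
  )
  X <- vapply(fit$terms$term, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    Reduce(`*`, cols[parts])
  }, numeric(nrow(grid)))
  grid$predicted <- drop(X %*% b)
  grid
}

#' Plot switch-centered mean ambivalence with model predictions
#'
#' One panel per magnitude-ambivalence pairing: points are trial-level mean
#' ambivalence scores with standard-error bars across the switch-centered
#' trial positions retained by the sparse-cell filter; lines (when a fitted
#' model is supplied) are the population-level dual-slopes predictions for
#' that pairing.
#'
#' @param h1 Prepared table from [prepare_h1()].
#' @param fit Optional `mcq_fit` from [fit_dual_slopes()].
#' @return A ggplot object.
#' @export
plot_switch_centered <- function(h1, fit = NULL) {
  summ <- dplyr::summarise(
    dplyr::group_by(
      h1, .data$magnitude, .data$amb_condition,
      .data$centered_trial
    ),
    mean_amb = mean(.data$ambivalence),
    se = stats::sd(.data$ambivalence) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  summ$pairing <- paste0(
    toupper(substring(summ$magnitude, 1, 1)),
    substring(summ$magnitude, 2), "-", summ$amb_condition
  )
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$centered_trial, y = .data$mean_amb)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_amb - .data$se,
        ymax = .data$mean_amb + .data$se
      ),
      width = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pairing) +
    ggplot2::labs(
      x = "Trial (centered on switch trial)",
      y = "Ambivalence (0-10)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- dplyr::distinct(
      summ, .data$magnitude, .data$amb_condition,
      .data$pairing, .data$centered_trial
    )
    grid <- .h1_population_prediction(fit, grid)
    p <- p + ggplot2::geom_line(
      data = grid,
      ggplot2::aes(y = .data$predicted),
      colour = "grey55"
    )
  }
  p
}
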