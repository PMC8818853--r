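# End-to-end orchestration: cohort in (file, data frame, or simulated),
# scored estimates, prepared tables, dual-slopes and choice-model fits, AIC
# comparison, quality summary, optional figures and a written report bundle.

#' Read a long-format MCQ trial table
#'
#' @param path CSV file with the scoring-module schema (`participant_id`,
#'   `magnitude`, `k_rank`, `choice`, `raw_ambivalence`, `amb_condition`).
#' @return A validated tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("Cohort file not found: '", path, "'.", call. = FALSE)
  }
  .validate_records(readr::read_csv(path, show_col_types = FALSE))
}

#' Run the full ambivalence analysis pipeline
#'
#' Scores the cohort, prepares the switch-centered and trial-level tables,
#' fits the dual-slopes model, the three nested choice models with the AIC
#' comparison, the slope-asymmetry contrast and the magnitude-effect quality
#' check, logging record counts at each stage. With `dir` set, writes a
#' reproducible bundle (CSV tables, JSON fit summaries, the echoed
#' configuration, and the switch-centered figure).
#'
#' @param input A records data frame, a CSV path, or `NULL` to simulate a
#'   cohort from `config`.
#' @param config [sim_config()] used when simulating (and echoed into the
#'   bundle); its `seed` seeds the simulation.
#' @param dir Optional output directory for the report bundle.
#' @param threshold Sparse-cell threshold for [filter_sparse_cells()].
#' @param delay_convention Delay-ratio convention, see [compute_predictors()].
#' @param h1_engine,h2_engine Model engines, see [fit_dual_slopes()] and
#'   [fit_choice_model()].
#' @param choice_models Choice-model specifications to fit and compare.
#' @param verbose Log stage-boundary counts.
#' @return A list of class `mcq_report`: `records`, `truth` (simulated input
#'   only), `scored`, `quality`, `h1`, `h2`, `fit_h1`, `slope_contrast`,
#'   `fits_h2`, `comparison`, `counts`, `config`.
#' @export
run_pipeline <- function(input = NULL, config = sim_config(), dir = NULL,
                         threshold = 0.20, delay_convention = "offset1",
                         h1_engine = "lmer", h2_engine = "glmer",
                         choice_models = c("Base", "BaseAmbMag", "AmbMag"),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- NULL
  if (is.null(input)) {
    cohort <- generate_cohort(config)
    records <- cohort$records
    truth <- cohort$truth
    say(
      "simulated cohort: %d participants, %d records",
      config$n_participants, nrow(records)
    )
  } else if (is.character(input)) {
    records <- read_cohort(input)
    say("read cohort '%s': %d records", input, nrow(records))
  } else {
    records <- .validate_records(input)
    say("using supplied records: %d rows", nrow(records))
  }

  bank <- mcq_item_bank()
  scored <- score_mcq(records, bank)
  n_sets <- nrow(scored)
  n_nonswitch <- sum(scored$is_nonswitcher)
  say(
    "scored %d trial sets from %d participants (%d non-switching, %.1f%%)",
    n_sets, dplyr::n_distinct(scored$participant_id), n_nonswitch,
    100 * n_nonswitch / n_sets
  )
  quality <- mcq_quality(scored)

  h1 <- prepare_h1(records, bank, scored = scored, threshold = threshold)
  removed <- attr(h1, "removed_cells")
  say(
    "switch-centered table: %d observations (%d sparse cells removed)",
    nrow(h1), nrow(removed)
  )
  fit_h1 <- fit_dual_slopes(h1, engine = h1_engine)
  if (!fit_h1$converged) say("dual-slopes fit flagged as not converged")
  contrast <- slope_asymmetry_contrast(fit_h1)

  h2 <- prepare_h2(records, bank, convention = delay_convention)
  say("choice table: %d trials", nrow(h2))
  fits_h2 <- lapply(stats::setNames(choice_models, choice_models), function(m) {
    fit_choice_model(h2, model = m, engine = h2_engine)
  })
  comparison <- compare_aic(fits_h2)
  say("AIC comparison: preferred model = %s", comparison$preferred)

  out <- structure(
    list(
      records = records, truth = truth, scored = scored, quality = quality,
      h1 = h1, h2 = h2, fit_h1 = fit_h1, slope_contrast = contrast,
      fits_h2 = fits_h2, comparison = comparison,
      counts = list(
        n_trial_sets = n_sets, n_nonswitching_sets = n_nonswitch,
        n_h1_obs = nrow(h1), n_removed_cells = nrow(removed),
        n_h2_obs = nrow(h2)
      ),
      config = config
    ),
    class = "mcq_report"
  )
  if (!is.null(dir)) write_report(out, dir)
  out
}

.fit_json <- function(fit) {
  list(
    model = fit$label, engine = fit$engine, aic = fit$aic,
    log_lik = fit$log_lik, n_obs = fit$n_obs, n_groups = fit$n_groups,
    converged = fit$converged, singular = fit$singular,
    random_effect_variances = as.list(fit$ranef_var),
    terms = fit$terms
  )
}

#' Write a pipeline report bundle to disk
#'
#' Emits `scored.csv`, `quality.csv`, `h1_prepared.csv`, `h2_prepared.csv`,
#' `h1_fit.json`, `h2_fits.json`, `comparison.json`, the echoed
#' `config.yaml`, the simulated `truth.csv` when present, and the
#' switch-centered figure `switch_centered.png`. On failure, partial outputs
#' written by this call are removed.
#'
#' @param report An `mcq_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mcq_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    written <<- c(written, path)
  }
  tryCatch(
    {
      emit("scored.csv", function(p) readr::write_csv(report$scored, p))
      emit("quality.csv", function(p) readr::write_csv(report$quality, p))
      emit("h1_prepared.csv", function(p) readr::write_csv(report$h1, p))
      emit("h2_prepared.csv", function(p) readr::write_csv(report$h2, p))
      emit("h1_fit.json", function(p) {
        jsonlite::write_json(
          c(.fit_json(report$fit_h1),
            list(slope_asymmetry = report$slope_contrast)
          ),
          p,
          auto_unbox = TRUE, digits = NA
        )
      })
      emit("h2_fits.json", function(p) {
        jsonlite::write_json(lapply(report$fits_h2, .fit_json), p,
          auto_unbox = TRUE, digits = NA
        )
      })
      emit("comparison.json", function(p) {
        jsonlite::write_json(
          list(
            preferred = report$comparison$preferred,
            margin = report$comparison$margin,
            table = report$comparison$table
          ),
          p,
          auto_unbox = TRUE, digits = NA
        )
      })
      emit("config.yaml", function(p) yaml::write_yaml(unclass(report$config), p))
      if (!is.null(report$truth)) {
        emit("truth.csv", function(p) readr::write_csv(report$truth, p))
      }
      emit("switch_centered.png", function(p) {
        ggplot2::ggsave(p, plot_switch_centered(report$h1, report$fit_h1),
          width = 8, height = 6, dpi = 150
        )
      })
    },
    error = function(e) {
      unlink(written)
      stop("Failed writing report bundle to '", dir, "': ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  invisible(dir)
}

#' @method print mcq_report
#' @export
print.mcq_report <- function(x, ...) {
  cat("<mcq_report>\n")
  cat(sprintf(
    "  %d trial sets (%d non-switching); H1 obs %d; H2 trials %d\n",
    x$counts$n_trial_sets, x$counts$n_nonswitching_sets,
    x$counts$n_h1_obs, x$counts$n_h2_obs
  ))
  cat(sprintf(
    "  magnitude effect: mean diff %.3f (t = %.2f, d = %.2f); perfect consistency %.1f%%\n",
    x$quality$mean_diff, x$quality$t, x$quality$cohens_d,
    100 * x$quality$perfect_consistency_prop
  ))
  pre <- x$fit_h1$terms[x$fit_h1$terms$term == "Pre-Switch", ]
  post <- x$fit_h1$terms[x$fit_h1$terms$term == "Post-Switch", ]
  cat(sprintf(
    "  dual slopes: pre %.3f (p = %.2g), post %.3f (p = %.2g)\n",
    pre$estimate, pre$p_value, post$estimate, post$p_value
  ))
  cat(sprintf("  AIC preferred model: %s\n", x$comparison$preferred))
  invisible(x)
}
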