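# Switch-centered data preparation: non-switcher exclusion, within-person
# centering on the switch trial, sparse-cell filtering, effects coding, and
# the choice-model predictors.

#' Effects (sum-to-zero) codes for magnitude and ambivalence condition
#'
#' Magnitude is coded +1 for small and -1 for large. The four ambivalence
#' measurement conditions are coded as three sum-to-zero contrast columns
#' `a1`, `a2`, `a3` with A4 as the level carrying -1 on all three, matching
#' the convention of reporting A1-A3 terms only.
#'
#' @param magnitude Character vector, `"small"`/`"large"`.
#' @param amb_condition Character vector, `"A1"`-`"A4"`.
#' @return A tibble with columns `small_mag`, `a1`, `a2`, `a3`.
#' @examples
#' effects_code("small", "A4")
#' @export
effects_code <- function(magnitude, amb_condition) {
  if (!all(magnitude %in% c("small", "large"))) {
    stop("`magnitude` must be 'small' or 'large'.", call. = FALSE)
  }
  if (!all(amb_condition %in% .amb_conditions)) {
    stop("`amb_condition` must be one of A1-A4.", call. = FALSE)
  }
  n <- max(length(magnitude), length(amb_condition))
  magnitude <- rep_len(magnitude, n)
  amb_condition <- rep_len(amb_condition, n)
  code <- function(level) {
    ifelse(amb_condition == level, 1, ifelse(amb_condition == "A4", -1, 0))
  }
  tibble::tibble(
    small_mag = ifelse(magnitude == "small", 1, -1),
    a1 = code("A1"), a2 = code("A2"), a3 = code("A3")
  )
}

#' Partition scored trial sets into switchers and non-switchers
#'
#' Trial sets without a preference switch have no estimable switch trial and
#' are excluded from switch-centered analyses; the partition is at the trial
#' set (participant x magnitude) level, so a participant may contribute one
#' condition but not the other.
#'
#' @param scored Output of [score_mcq()].
#' @return A list with tibbles `included` and `excluded`.
#' @export
exclude_nonswitchers <- function(scored) {
  stopifnot(all(c("is_nonswitcher", "switch_rank") %in% names(scored)))
  list(
    included = dplyr::filter(scored, !.data$is_nonswitcher),
    excluded = dplyr::filter(scored, .data$is_nonswitcher)
  )
}

#' Center trial numbers on the switch trial
#'
#' Joins per-set switch ranks onto the trial table and recodes each trial's
#' k rank as a signed distance from the switch trial (0 = switch trial),
#' with the piecewise slope terms `pre_term = min(centered, 0)` and
#' `post_term = max(centered, 0)`.
#'
#' @param records Long trial table (scoring-module schema).
#' @param scored Output of [score_mcq()] for the same records.
#' @return Tibble of centered observations; non-switcher trial sets are
#'   dropped (an exclusion, not an error).
#' @export
center_on_switch <- function(records, scored) {
  records <- .validate_records(records)
  sets <- dplyr::select(
    exclude_nonswitchers(scored)$included,
    "participant_id", "magnitude", "switch_rank"
  )
  out <- dplyr::inner_join(records, sets, by = c("participant_id", "magnitude"))
  out$centered_trial <- out$k_rank - out$switch_rank
  out$pre_term <- pmin(out$centered_trial, 0)
  out$post_term <- pmax(out$centered_trial, 0)
  out
}

#' Remove sparse switch-centered cells
#'
#' Within each magnitude-ambivalence pairing, switch-centered trial positions
#' contributed by fewer than `threshold` (default 20%) of that pairing's
#' participants are removed; "fewer than" is strict, so a cell exactly at the
#' threshold is kept. The participant base is the number of participants
#' contributing at least one centered observation in the pairing.
#'
#' @param centered Centered observations from [center_on_switch()].
#' @param threshold Minimum cell size as a proportion of the pairing's
#'   participant count, in `(0, 1]`.
#' @return Filtered tibble; attribute `"removed_cells"` records what was cut.
#' @export
filter_sparse_cells <- function(centered, threshold = 0.20) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
    threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a single proportion in (0, 1].", call. = FALSE)
  }
  base <- dplyr::summarise(
    dplyr::group_by(centered, .data$magnitude, .data$amb_condition),
    n_participants = dplyr::n_distinct(.data$participant_id),
    .groups = "drop"
  )
  cells <- dplyr::summarise(
    dplyr::group_by(
      centered, .data$magnitude, .data$amb_condition,
      .data$centered_trial
    ),
    n = dplyr::n(), .groups = "drop"
  )
  cells <- dplyr::left_join(cells, base, by = c("magnitude", "amb_condition"))
  cells$keep <- cells$n >= threshold * cells$n_participants
  out <- dplyr::inner_join(
    centered,
    dplyr::select(
      dplyr::filter(cells, .data$keep),
      "magnitude", "amb_condition", "centered_trial"
    ),
    by = c("magnitude", "amb_condition", "centered_trial")
  )
  attr(out, "removed_cells") <- dplyr::select(
    dplyr::filter(cells, !.data$keep),
    "magnitude", "amb_condition", "centered_trial", "n", "n_participants"
  )
  out
}

#' Reward magnitude and delay sensitivity predictors
#'
#' The choice models use the natural-log larger-later/smaller-sooner ratios:
#' `mag_ratio = ln(ll_amount / ss_amount)` and, because the smaller-sooner
#' reward is delivered today (delay 0), a delay ratio with both delays offset
#' by one day, `delay_ratio = ln((ll_delay + 1) / (0 + 1)) = ln(ll_delay + 1)`
#' (`convention = "offset1"`, the default; over the item bank this spans
#' ln 8 to ln 187, about 2-5.2). `convention = "raw"` uses `ln(ll_delay)`.
#'
#' @param items Data frame with `ss_amount`, `ll_amount`, `ll_delay_days`.
#' @param convention `"offset1"` or `"raw"`.
#' @return A tibble with `mag_ratio` and `delay_ratio`.
#' @export
compute_predictors <- function(items, convention = c("offset1", "raw")) {
  convention <- match.arg(convention)
  tibble::tibble(
    mag_ratio = log(items$ll_amount / items$ss_amount),
    delay_ratio = if (convention == "offset1") {
      log(items$ll_delay_days + 1)
    } else {
      log(items$ll_delay_days)
    }
  )
}

#' Prepare the switch-centered ambivalence table for the dual-slopes model
#'
#' Scores the records (unless a scored table is supplied), excludes
#' non-switcher trial sets, centers trials on the switch trial, rescales
#' ambivalence to the common 0-10 scale, applies the sparse-cell filter, and
#' attaches effects codes.
#'
#' @inheritParams center_on_switch
#' @inheritParams filter_sparse_cells
#' @param bank Item bank.
#' @param scored Optional pre-computed [score_mcq()] output.
#' @return Tibble with one row per retained switch-centered trial:
#'   `participant_id`, `magnitude`, `amb_condition`, `k_rank`,
#'   `centered_trial`, `pre_term`, `post_term`, `ambivalence`, `small_mag`,
#'   `a1`, `a2`, `a3`. Attributes `"excluded_sets"` and `"removed_cells"`
#'   carry the exclusion bookkeeping.
#' @export
prepare_h1 <- function(records, bank = mcq_item_bank(), scored = NULL,
                       threshold = 0.20) {
  records <- .validate_records(records)
  if (is.null(scored)) scored <- score_mcq(records, bank)
  centered <- center_on_switch(records, scored)
  centered$ambivalence <- rescale_ambivalence(
    centered$raw_ambivalence, centered$amb_condition
  )
  filtered <- filter_sparse_cells(centered, threshold)
  codes <- effects_code(filtered$magnitude, filtered$amb_condition)
  out <- dplyr::bind_cols(
    dplyr::select(
      filtered, "participant_id", "magnitude", "amb_condition",
      "k_rank", "centered_trial", "pre_term", "post_term", "ambivalence"
    ),
    codes
  )
  attr(out, "excluded_sets") <- exclude_nonswitchers(scored)$excluded
  attr(out, "removed_cells") <- attr(filtered, "removed_cells")
  out
}

#' Prepare the trial-level choice table for the logistic models
#'
#' Attaches the magnitude/delay log-ratio predictors, the rescaled
#' ambivalence score, and effects codes to every trial (non-switchers are
#' retained: the choice models condition on trial-level predictors, not on a
#' switch trial).
#'
#' @inheritParams prepare_h1
#' @param convention Delay-ratio convention, see [compute_predictors()].
#' @return Tibble with `participant_id`, `magnitude`, `amb_condition`,
#'   `k_rank`, `choice_ll` (1 = larger-later), `mag_ratio`, `delay_ratio`,
#'   `amb_score`, `small_mag`, `a1`, `a2`, `a3`.
#' @export
prepare_h2 <- function(records, bank = mcq_item_bank(),
                       convention = c("offset1", "raw")) {
  convention <- match.arg(convention)
  records <- .validate_records(records)
  out <- dplyr::left_join(records, bank, by = c("magnitude", "k_rank"))
  if (any(is.na(out$ll_amount))) {
    stop("Records contain (magnitude, k_rank) pairs absent from the item bank.",
      call. = FALSE
    )
  }
  pred <- compute_predictors(out, convention)
  codes <- effects_code(out$magnitude, out$amb_condition)
  dplyr::bind_cols(
    tibble::tibble(
      participant_id = out$participant_id,
      magnitude = out$magnitude,
      amb_condition = out$amb_condition,
      k_rank = out$k_rank,
      choice_ll = as.integer(out$choice == "LL"),
      mag_ratio = pred$mag_ratio,
      delay_ratio = pred$delay_ratio,
      amb_score = rescale_ambivalence(out$raw_ambivalence, out$amb_condition)
    ),
    codes
  )
}
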