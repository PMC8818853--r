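# Consistency-based discount-rate scoring of 9-trial MCQ response patterns,
# switch-trial designation, and the maximum-ambivalence trial.

.mcq_magnitude_items <- function(bank, magnitude) {
  items <- bank[bank$magnitude == magnitude, , drop = FALSE]
  items <- items[order(items$k_rank), , drop = FALSE]
  if (nrow(items) != 9L || !identical(as.integer(items$k_rank), 1:9)) {
    stop("Item bank must contain ranks 1-9 exactly once for magnitude '",
      magnitude, "'.",
      call. = FALSE
    )
  }
  items
}

# The standard scoring grid: the two endpoint item rates plus the geometric
# means of adjacent item rates (10 candidates). A candidate between two item
# rates predicts SS below it and LL above it.
.candidate_grid <- function(k_indiff) {
  c(k_indiff[1L], sqrt(k_indiff[-9L] * k_indiff[-1L]), k_indiff[9L])
}

.check_pattern <- function(choices) {
  if (length(choices) != 9L || any(is.na(choices)) || !all(choices %in% c("SS", "LL"))) {
    stop("A response pattern must be 9 choices ('SS'/'LL'), one per k rank.",
      call. = FALSE
    )
  }
  invisible(choices)
}

#' Consistency of a response pattern with a candidate discount rate
#'
#' The fraction of the nine items whose observed choice agrees with the
#' deterministic choice implied by `candidate_k` as a preference threshold
#' (larger-later below the item's indifference rate, smaller-sooner above).
#' When the candidate coincides exactly with an item's indifference rate the
#' participant is indifferent there by construction, so either observed choice
#' counts as consistent on that item.
#'
#' @param choices Character vector of 9 `"SS"`/`"LL"` choices ordered by
#'   ascending k rank.
#' @param candidate_k Candidate discount rate (scalar).
#' @param k_indiff The 9 item indifference rates in ascending rank order, or a
#'   bank subset; defaults to the small-magnitude items.
#'
#' @return Proportion in `[0, 1]`.
#' @export
choice_consistency <- function(choices, candidate_k,
                               k_indiff = .mcq_magnitude_items(mcq_item_bank(), "small")$k_indiff) {
  .check_pattern(choices)
  stopifnot(length(candidate_k) == 1L, length(k_indiff) == 9L)
  consistent <- choices == predicted_choice(candidate_k, k_indiff) |
    candidate_k == k_indiff
  mean(consistent)
}

.estimate_k_pattern <- function(choices, k_indiff) {
  grid <- .candidate_grid(k_indiff)
  cons <- vapply(grid, function(k) {
    mean(choices == predicted_choice(k, k_indiff) | k == k_indiff)
  }, numeric(1))
  best <- which(cons == max(cons))
  k <- exp(mean(log(grid[best])))
  ll <- choices == "LL"
  n_switches <- sum(ll[-1L] != ll[-9L])
  # a non-switcher never moves from SS to LL as ranks ascend
  is_nonswitcher <- !any(!ll[-9L] & ll[-1L])
  list(
    k = k, ln_k = log(k), consistency = max(cons),
    n_switches = n_switches, is_nonswitcher = is_nonswitcher
  )
}

#' Estimate a discount rate from a 9-trial response pattern
#'
#' Scans the 10-candidate grid (endpoint item rates plus geometric means of
#' adjacent item rates) for the rate most consistent with the observed
#' pattern; equally consistent candidates are combined by their geometric
#' mean. Also classifies the switch structure of the pattern: `n_switches`
#' counts adjacent rank pairs with differing choices, and a pattern with no
#' SS-to-LL transition in ascending rank order (all-SS, all-LL) is a
#' non-switcher. All-LL responding lands on the lowest item rate and all-SS
#' on the highest, the boundary convention for patterns that never switch.
#'
#' @inheritParams choice_consistency
#' @return A one-row tibble with `k`, `ln_k`, `consistency`, `n_switches`,
#'   `is_nonswitcher` and `switch_rank` (`NA` for non-switchers).
#' @examples
#' bank <- mcq_item_bank()
#' ks <- bank$k_indiff[bank$magnitude == "small"]
#' estimate_k(c(rep("SS", 3), rep("LL", 6)), ks)
#' @export
estimate_k <- function(choices,
                       k_indiff = .mcq_magnitude_items(mcq_item_bank(), "small")$k_indiff) {
  .check_pattern(choices)
  est <- .estimate_k_pattern(choices, k_indiff)
  est$switch_rank <- .switch_rank(choices, est$k, est$is_nonswitcher, k_indiff)
  tibble::as_tibble(est[c(
    "k", "ln_k", "consistency", "n_switches",
    "is_nonswitcher", "switch_rank"
  )])
}

.switch_rank <- function(choices, k, is_nonswitcher, k_indiff) {
  if (is_nonswitcher) {
    return(NA_real_)
  }
  ll <- choices == "LL"
  first_ll <- match(TRUE, ll)
  single <- all(ll[seq(first_ll, 9L)]) && first_ll > 1L && !any(ll[seq_len(first_ll - 1L)])
  if (single) {
    return(as.numeric(first_ll))
  }
  above <- which(k_indiff > k)
  if (length(above)) as.numeric(min(above)) else 9
}

#' Designate the switch trial of a response pattern
#'
#' For a pattern with a single clean preference switch, the switch trial is
#' the first trial (by ascending k rank) on which the larger-later reward is
#' preferred. For patterns with multiple switch points, the estimated
#' discount rate decides: the switch trial is the lowest rank whose item
#' indifference rate strictly exceeds the estimate (capped at rank 9 when the
#' estimate sits on the top item rate). Non-switchers have no switch trial.
#'
#' @inheritParams choice_consistency
#' @param k Estimated discount rate for the pattern; computed from the
#'   pattern when omitted.
#' @return Switch rank (1-9) or `NA` for non-switchers.
#' @examples
#' ks <- mcq_item_bank()$k_indiff[1:9]
#' designate_switch_trial(c("SS", "LL", "SS", "LL", "LL", "LL", "LL", "LL", "LL"),
#'   k = 0.0019, k_indiff = ks
#' )
#' @export
designate_switch_trial <- function(choices, k = NULL,
                                   k_indiff = .mcq_magnitude_items(mcq_item_bank(), "small")$k_indiff) {
  .check_pattern(choices)
  est <- .estimate_k_pattern(choices, k_indiff)
  if (is.null(k)) k <- est$k
  .switch_rank(choices, k, est$is_nonswitcher, k_indiff)
}

#' Trial of maximum ambivalence
#'
#' The rank of the trial with the highest ambivalence score within a
#' magnitude condition; tied maxima are averaged, so the result may be
#' fractional.
#'
#' @param scores Numeric vector of 9 ambivalence scores in ascending rank
#'   order.
#' @return Real-valued trial index in `[1, 9]`.
#' @export
max_ambivalence_trial <- function(scores) {
  if (length(scores) != 9L || any(is.na(scores))) {
    stop("`scores` must be 9 non-missing ambivalence scores.", call. = FALSE)
  }
  mean(which(scores == max(scores)))
}

.required_record_cols <- c(
  "participant_id", "magnitude", "k_rank", "choice",
  "raw_ambivalence", "amb_condition"
)

.validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(.required_record_cols, names(records))
  if (length(missing)) {
    stop("Input records are missing column(s): ",
      paste(missing, collapse = ", "), ".",
      call. = FALSE
    )
  }
  if (!all(records$choice %in% c("SS", "LL"))) {
    stop("`choice` must be 'SS' or 'LL'.", call. = FALSE)
  }
  if (!all(records$magnitude %in% c("small", "large"))) {
    stop("`magnitude` must be 'small' or 'large'.", call. = FALSE)
  }
  records
}

#' Score an MCQ trial table into per-participant discount estimates
#'
#' Takes a long-format trial table (one row per participant, magnitude
#' condition and k rank) and returns one row per participant and magnitude
#' condition with the consistency-based discount-rate estimate, switch
#' classification, designated switch trial, and the maximum-ambivalence
#' trial computed from the rescaled 0-10 ambivalence scores.
#'
#' @param records Data frame with columns `participant_id`, `magnitude`,
#'   `k_rank`, `choice` (`"SS"`/`"LL"`), `raw_ambivalence`, `amb_condition`.
#' @param bank Item bank, by default [mcq_item_bank()].
#'
#' @return Tibble with columns `participant_id`, `magnitude`,
#'   `amb_condition`, `k`, `ln_k`, `consistency`, `n_switches`,
#'   `is_nonswitcher`, `switch_rank`, `max_amb_trial`.
#' @export
score_mcq <- function(records, bank = mcq_item_bank()) {
  records <- .validate_records(records)
  records <- dplyr::arrange(records, .data$participant_id, .data$magnitude, .data$k_rank)
  records$amb_score <- rescale_ambivalence(records$raw_ambivalence, records$amb_condition)

  grouped <- dplyr::group_by(records, .data$participant_id, .data$magnitude)
  sizes <- dplyr::summarise(grouped, n = dplyr::n(), .groups = "drop")
  if (any(sizes$n != 9L)) {
    bad <- sizes[sizes$n != 9L, , drop = FALSE]
    stop("Incomplete response pattern(s): expected 9 trials per participant x ",
      "magnitude, e.g. participant '", bad$participant_id[1L], "' (",
      bad$magnitude[1L], ") has ", bad$n[1L], ".",
      call. = FALSE
    )
  }

  per_set <- dplyr::summarise(
    grouped,
    amb_condition = dplyr::first(.data$amb_condition),
    pattern = paste(ifelse(.data$choice[order(.data$k_rank)] == "LL", "L", "S"),
      collapse = ""
    ),
    n_ranks = dplyr::n_distinct(.data$k_rank),
    max_amb_trial = max_ambivalence_trial(.data$amb_score[order(.data$k_rank)]),
    .groups = "drop"
  )
  if (any(per_set$n_ranks != 9L)) {
    stop("Each participant x magnitude set must contain k ranks 1-9 exactly once.",
      call. = FALSE
    )
  }

  # score each distinct pattern once per magnitude condition, then join back
  scored <- purrr::map_dfr(c("small", "large"), function(mag) {
    sets <- per_set[per_set$magnitude == mag, , drop = FALSE]
    if (!nrow(sets)) {
      return(NULL)
    }
    ks <- .mcq_magnitude_items(bank, mag)$k_indiff
    pats <- unique(sets$pattern)
    ests <- purrr::map_dfr(pats, function(p) {
      choices <- ifelse(strsplit(p, "")[[1L]] == "L", "LL", "SS")
      estimate_k(choices, ks)
    })
    ests$pattern <- pats
    ests$magnitude <- mag
    dplyr::left_join(sets, ests, by = c("magnitude", "pattern"))
  })

  dplyr::select(
    dplyr::arrange(scored, .data$participant_id, .data$magnitude),
    "participant_id", "magnitude", "amb_condition", "k", "ln_k",
    "consistency", "n_switches", "is_nonswitcher", "switch_rank",
    "max_amb_trial"
  )
}
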