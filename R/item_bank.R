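# Abbreviated 18-item Monetary Choice Questionnaire: small ($25-$35 LL) and
# large ($75-$85 LL) magnitude conditions, nine trials each, rank-ordered by
# the discount rate at which the two rewards have equal present value.

.mcq_items <- local({
  small <- data.frame(
    ss_amount = c(34, 28, 22, 25, 19, 24, 14, 15, 11),
    ll_amount = c(35, 30, 25, 30, 25, 35, 25, 35, 30),
    ll_delay_days = c(186, 179, 136, 80, 53, 29, 19, 13, 7),
    k_rank = 1:9,
    magnitude = "small"
  )
  large <- data.frame(
    ss_amount = c(78, 80, 67, 69, 55, 54, 41, 33, 31),
    ll_amount = c(80, 85, 75, 85, 75, 80, 75, 80, 85),
    ll_delay_days = c(162, 157, 119, 91, 61, 30, 20, 14, 7),
    k_rank = 1:9,
    magnitude = "large"
  )
  rbind(small, large)
})

#' Discount rate at indifference for a smaller-sooner / larger-later pair
#'
#' Under Mazur's hyperbolic model, \eqn{V = A / (1 + kD)}, an immediate reward
#' of `ss` and a reward of `ll` delivered after `delay` days have equal present
#' value at the per-day discount rate \eqn{k = (ll/ss - 1) / delay}. Each MCQ
#' item carries one such rate; a participant discounting more steeply than an
#' item's rate should prefer the smaller-sooner reward on that item.
#'
#' @param ss Smaller-sooner amount in dollars (positive).
#' @param ll Larger-later amount in dollars (strictly greater than `ss`).
#' @param delay Delay to the larger-later reward in days (positive).
#'
#' @return Numeric vector of per-day discount rates.
#' @examples
#' k_at_indifference(34, 35, 186) # ~0.00016
#' k_at_indifference(28, 30, 179) # ~0.00040
#' @export
k_at_indifference <- function(ss, ll, delay) {
  if (any(!is.finite(ss)) || any(!is.finite(ll)) || any(!is.finite(delay))) {
    stop("`ss`, `ll` and `delay` must be finite numbers.", call. = FALSE)
  }
  if (any(ss <= 0) || any(delay <= 0)) {
    stop("`ss` and `delay` must be strictly positive.", call. = FALSE)
  }
  if (any(ll <= ss)) {
    stop("`ll` must exceed `ss`: no finite positive discount rate exists otherwise.",
      call. = FALSE
    )
  }
  (ll / ss - 1) / delay
}

#' The abbreviated 18-item MCQ item bank
#'
#' Returns the nine small-magnitude ($25-$35 larger-later) and nine
#' large-magnitude ($75-$85 larger-later) items of the Monetary Choice
#' Questionnaire, rank-ordered 1-9 within each magnitude condition by the
#' discount rate at indifference. `k_indiff` is computed at full precision
#' from the amounts and delay; the instrument's published table prints these
#' at two significant figures.
#'
#' @return A tibble with one row per item and columns `ss_amount`,
#'   `ll_amount`, `ll_delay_days`, `k_indiff`, `k_rank`, `magnitude`.
#' @examples
#' bank <- mcq_item_bank()
#' dplyr::count(bank, magnitude)
#' @export
mcq_item_bank <- function() {
  out <- tibble::as_tibble(.mcq_items)
  out$k_indiff <- k_at_indifference(out$ss_amount, out$ll_amount, out$ll_delay_days)
  out[, c(
    "ss_amount", "ll_amount", "ll_delay_days",
    "k_indiff", "k_rank", "magnitude"
  )]
}

#' Deterministic choice predicted by the hyperbolic model
#'
#' A participant with discount rate `k_participant` prefers the larger-later
#' reward on items whose indifference rate exceeds their own, and the
#' smaller-sooner reward on items whose rate falls below it. Exact equality is
#' resolved toward the later option ("LL"), a fixed convention applied
#' consistently throughout scoring.
#'
#' @param k_participant Non-negative participant discount rate(s) per day.
#' @param k_indiff Item indifference rate(s), e.g. from [mcq_item_bank()].
#'
#' @return Character vector of `"SS"` / `"LL"`.
#' @export
predicted_choice <- function(k_participant, k_indiff) {
  if (any(k_participant < 0)) {
    stop("`k_participant` must be non-negative.", call. = FALSE)
  }
  ifelse(k_participant <= k_indiff, "LL", "SS")
}
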