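# The four ambivalence measurement conditions use different raw scales and
# polarities; all are brought onto a common 0 (least ambivalent) to 10 (most
# ambivalent) scale before analysis.

.amb_conditions <- c("A1", "A2", "A3", "A4")

#' Rescale raw ambivalence responses to the common 0-10 scale
#'
#' Each measurement condition phrases the trial-level follow-up differently
#' and therefore needs its own mapping to a shared scale on which 0 is least
#' and 10 is most ambivalent:
#' \describe{
#'   \item{A1 (certainty), A2 (counterfactual unhappiness)}{0-10 Likert,
#'     flipped about the midpoint: `10 - raw`.}
#'   \item{A3 (indecision)}{0-10 Likert, already oriented: `raw`.}
#'   \item{A4 (preference slider)}{0-100 slider where 0 and 100 are the
#'     strongest smaller-sooner / larger-later preferences and 50 is maximal
#'     ambivalence; folded distance from the midpoint: `||raw - 50| - 50| / 5`.}
#' }
#'
#' @param raw Numeric vector of raw responses.
#' @param condition Character vector (recycled) of measurement conditions,
#'   `"A1"`, `"A2"`, `"A3"` or `"A4"`.
#'
#' @return Numeric vector of ambivalence scores in `[0, 10]`.
#' @examples
#' rescale_ambivalence(10, "A1") # complete certainty -> 0
#' rescale_ambivalence(50, "A4") # slider midpoint -> 10
#' @export
rescale_ambivalence <- function(raw, condition) {
  n <- max(length(raw), length(condition))
  raw <- rep_len(raw, n)
  condition <- rep_len(as.character(condition), n)
  bad_cond <- !condition %in% .amb_conditions
  if (any(bad_cond)) {
    stop(
      "Unknown ambivalence condition(s): ",
      paste(unique(condition[bad_cond]), collapse = ", "),
      call. = FALSE
    )
  }
  likert <- condition %in% c("A1", "A2", "A3")
  bad_likert <- likert & (is.na(raw) | raw < 0 | raw > 10 | raw != round(raw))
  if (any(bad_likert)) {
    stop(
      "A1/A2/A3 responses must be integers on the 0-10 Likert scale; got ",
      paste(utils::head(unique(raw[bad_likert]), 5), collapse = ", "), ".",
      call. = FALSE
    )
  }
  bad_slider <- !likert & (is.na(raw) | raw < 0 | raw > 100)
  if (any(bad_slider)) {
    stop(
      "A4 responses must lie on the 0-100 slider scale; got ",
      paste(utils::head(unique(raw[bad_slider]), 5), collapse = ", "), ".",
      call. = FALSE
    )
  }
  out <- numeric(n)
  flip <- condition %in% c("A1", "A2")
  out[flip] <- 10 - raw[flip]
  out[condition == "A3"] <- raw[condition == "A3"]
  a4 <- condition == "A4"
  out[a4] <- abs(abs(raw[a4] - 50) - 50) / 5
  out
}
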