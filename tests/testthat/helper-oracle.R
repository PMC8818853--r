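# Independent brute-force oracle for consistency-based k estimation, written
# as plain loops against the 10-candidate grid so the scoring implementation
# can be checked pattern-by-pattern.

oracle_grid <- function(ks) {
  cands <- numeric(0)
  for (i in 1:8) cands <- c(cands, sqrt(ks[i] * ks[i + 1]))
  c(ks[1], cands, ks[9])
}

oracle_consistency <- function(choices, cand, ks) {
  hits <- 0
  for (i in 1:9) {
    pred <- if (cand <= ks[i]) "LL" else "SS"
    if (choices[i] == pred || cand == ks[i]) hits <- hits + 1
  }
  hits / 9
}

oracle_estimate <- function(choices, ks) {
  cands <- oracle_grid(ks)
  cons <- numeric(10)
  for (j in 1:10) cons[j] <- oracle_consistency(choices, cands[j], ks)
  tied <- cands[cons == max(cons)]
  list(k = exp(mean(log(tied))), consistency = max(cons), tied = tied)
}

# all 512 response patterns as a 512 x 9 character matrix
all_patterns <- function() {
  grid <- expand.grid(rep(list(c("SS", "LL")), 9), stringsAsFactors = FALSE)
  as.matrix(grid)
}

# choices implied by a participant rate under the boundary convention
pattern_for_k <- function(k, ks) ifelse(k <= ks, "LL", "SS")

small_ks <- function() {
  bank <- mcq_item_bank()
  bank$k_indiff[bank$magnitude == "small"]
}

# quick records table for a single participant from explicit patterns
records_from_patterns <- function(small, large, amb_small = "A3", amb_large = "A4",
                                  id = "P1") {
  tibble::tibble(
    participant_id = id,
    magnitude = rep(c("small", "large"), each = 9),
    k_rank = rep(1:9, 2),
    choice = c(small, large),
    raw_ambivalence = rep(c(5, 50), each = 9),
    amb_condition = rep(c(amb_small, amb_large), each = 9)
  )
}
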