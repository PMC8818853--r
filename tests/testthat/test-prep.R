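test_that("effects coding is sum-to-zero with A4 and large as reference levels", {
  expect_equal(
    unlist(effects_code("small", "A4")),
    c(small_mag = 1, a1 = -1, a2 = -1, a3 = -1)
  )
  expect_equal(
    unlist(effects_code("large", "A2")),
    c(small_mag = -1, a1 = 0, a2 = 1, a3 = 0)
  )
  # balanced design -> all columns sum to zero
  balanced <- tidyr::crossing(
    magnitude = c("small", "large"),
    amb_condition = c("A1", "A2", "A3", "A4")
  )
  codes <- effects_code(balanced$magnitude, balanced$amb_condition)
  expect_equal(unname(colSums(codes)), rep(0, 4))
  expect_error(effects_code("medium", "A1"), "magnitude")
  expect_error(effects_code("small", "B1"), "A1-A4")
})

test_that("centering places 0 on the switch trial with split slope terms", {
  recs <- records_from_patterns(
    small = c(rep("SS", 5), rep("LL", 4)), # switch at rank 6
    large = rep("LL", 9) # non-switcher, dropped
  )
  scored <- score_mcq(recs)
  centered <- center_on_switch(recs, scored)
  expect_equal(unique(centered$magnitude), "small")
  expect_equal(sort(centered$centered_trial), -5:3)
  row4 <- centered[centered$k_rank == 4, ]
  expect_equal(
    c(row4$centered_trial, row4$pre_term, row4$post_term),
    c(-2, -2, 0)
  )
  row6 <- centered[centered$k_rank == 6, ]
  expect_equal(
    c(row6$centered_trial, row6$pre_term, row6$post_term),
    c(0, 0, 0)
  )
  row9 <- centered[centered$k_rank == 9, ]
  expect_equal(
    c(row9$centered_trial, row9$pre_term, row9$post_term),
    c(3, 0, 3)
  )
  # exclusion happens at the trial-set level, not the participant level
  parts <- exclude_nonswitchers(scored)
  expect_equal(parts$included$magnitude, "small")
  expect_equal(parts$excluded$magnitude, "large")
})

test_that("the 20% cell filter is strict and idempotent", {
  # 100 participants in one pairing; position -3 contributed by 19, -2 by 20
  base <- tidyr::crossing(
    participant_id = sprintf("P%03d", 1:100),
    centered_trial = 0:1
  )
  sparse <- tibble::tibble(
    participant_id = c(sprintf("P%03d", 1:19), sprintf("P%03d", 1:20)),
    centered_trial = rep(c(-3, -2), c(19, 20))
  )
  cells <- dplyr::bind_rows(base, sparse)
  cells$magnitude <- "small"
  cells$amb_condition <- "A1"
  out <- filter_sparse_cells(cells, threshold = 0.20)
  expect_setequal(unique(out$centered_trial), c(-2, 0, 1))
  removed <- attr(out, "removed_cells")
  expect_equal(removed$centered_trial, -3)
  expect_equal(removed$n, 19L)
  # re-running the filter removes nothing further
  again <- filter_sparse_cells(out, threshold = 0.20)
  expect_equal(nrow(again), nrow(out))
  expect_equal(nrow(attr(again, "removed_cells")), 0L)
  expect_error(filter_sparse_cells(cells, threshold = 0), "proportion")
  expect_error(filter_sparse_cells(cells, threshold = 1.2), "proportion")
})

test_that("choice predictors match the worked log-ratios and printed ranges", {
  expect_equal(
    compute_predictors(
      tibble::tibble(ss_amount = 15, ll_amount = 35, ll_delay_days = 13)
    )$mag_ratio,
    log(35 / 15)
  )
  bank <- mcq_item_bank()
  pred <- compute_predictors(bank)
  # shallowest ratios: $34 vs $35 among small items, $78 vs $80 overall
  small_pred <- compute_predictors(bank[bank$magnitude == "small", ])
  expect_equal(min(small_pred$mag_ratio), log(35 / 34))
  expect_equal(min(pred$mag_ratio), log(80 / 78))
  expect_true(all(pred$mag_ratio > 0 & pred$mag_ratio <= 1.01))
  expect_equal(min(pred$delay_ratio), log(8))
  expect_equal(max(pred$delay_ratio), log(187))
  raw <- compute_predictors(bank, convention = "raw")
  expect_equal(min(raw$delay_ratio), log(7))
})

test_that("prepared tables satisfy the piecewise-term identities", {
  cohort <- generate_cohort(sim_config(n_participants = 120, seed = 21))
  h1 <- prepare_h1(cohort$records)
  expect_true(all(h1$pre_term * h1$post_term == 0))
  expect_true(all(h1$pre_term + h1$post_term == h1$centered_trial))
  expect_true(all(h1$ambivalence >= 0 & h1$ambivalence <= 10))
  # every surviving cell meets the 20% rule within its pairing
  base <- dplyr::summarise(
    dplyr::group_by(h1, magnitude, amb_condition),
    n_part = dplyr::n_distinct(participant_id), .groups = "drop"
  )
  cells <- dplyr::count(h1, magnitude, amb_condition, centered_trial)
  cells <- dplyr::left_join(cells, base, by = c("magnitude", "amb_condition"))
  expect_true(all(cells$n >= 0.20 * cells$n_part))
  # exactly one centered-zero observation per included trial set
  zero <- dplyr::filter(h1, centered_trial == 0)
  sets <- dplyr::distinct(h1, participant_id, magnitude)
  expect_equal(nrow(zero), nrow(sets))

  h2 <- prepare_h2(cohort$records)
  expect_equal(nrow(h2), nrow(cohort$records))
  expect_setequal(unique(h2$choice_ll), c(0L, 1L))
  expect_true(all(abs(h2$small_mag) == 1))
})

test_that("prepare_h2 refuses records that do not match the item bank", {
  recs <- records_from_patterns(rep("SS", 9), rep("LL", 9))
  recs$k_rank[1] <- 12
  expect_error(prepare_h2(recs), "absent from the item bank")
})
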