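test_that("configuration validation names every offending field", {
  expect_s3_class(sim_config(), "mcq_sim_config")
  err <- tryCatch(
    sim_config(sigma_ln_k = -1, p_flat_ambivalence = 2, amb_width = 0),
    error = identity
  )
  expect_match(conditionMessage(err), "sigma_ln_k")
  expect_match(conditionMessage(err), "p_flat_ambivalence")
  expect_match(conditionMessage(err), "amb_width")
})

test_that("cohorts are deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 24, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(sim_config(n_participants = 24, seed = 43))
  expect_false(identical(a$records, c2$records))
})

test_that("cohort structure: 9 + 9 records per participant, counterbalanced pairings", {
  cohort <- generate_cohort(sim_config(n_participants = 16, seed = 1))
  counts <- dplyr::count(cohort$records, participant_id, magnitude)
  expect_true(all(counts$n == 9L))
  expect_equal(nrow(cohort$records), 16 * 18)
  # one ambivalence condition per magnitude per participant; both arms used
  per <- dplyr::distinct(
    cohort$records, participant_id, magnitude, amb_condition
  )
  expect_equal(nrow(per), 32L)
  wide <- tidyr::pivot_wider(per,
    names_from = magnitude,
    values_from = amb_condition
  )
  expect_true(all(wide$small != wide$large))
  likert_arm <- wide$small %in% c("A1", "A2")
  expect_true(all(likert_arm == (wide$large %in% c("A1", "A2"))))
  # round-robin over 8 slots -> the 4 distinct condition pairs appear equally
  combos <- dplyr::count(wide, small, large)
  expect_equal(nrow(combos), 4L)
  expect_true(all(combos$n == 4L))
})

test_that("degenerate variances pin the magnitude shift exactly", {
  cfg <- sim_config(
    n_participants = 30, seed = 2, sigma_ln_k = 1e-9,
    magnitude_shift_sd = 0, p_extreme = 0
  )
  truth <- withr::with_seed(2, sample_participants(cfg))
  expect_equal(truth$ln_k_small - truth$ln_k_large, rep(0.66, 30))
})

test_that("sampled shifts obey the law of large numbers", {
  cfg <- sim_config(n_participants = 10000, seed = 9, p_extreme = 0)
  truth <- withr::with_seed(9, sample_participants(cfg))
  shift <- truth$ln_k_small - truth$ln_k_large
  expect_lt(abs(mean(shift) - 0.66), 3 * 0.48 / sqrt(10000))
  expect_lt(abs(sd(shift) - 0.48), 0.02)
})

test_that("choice rule recovers the deterministic pattern at low noise", {
  # participant k between ranks 3 and 4 -> SS on ranks 1-3, LL on 4-9
  cfg <- sim_config(
    n_participants = 1, seed = 4, choice_noise = 1e4,
    p_extreme = 0, sigma_ln_k = 1e-12, mu_ln_k_large = log(0.0019),
    magnitude_shift_sd = 0, magnitude_shift_mean = 0
  )
  cohort <- generate_cohort(cfg)
  small <- cohort$records[cohort$records$magnitude == "small", ]
  expect_equal(
    small$choice[order(small$k_rank)],
    c(rep("SS", 3), rep("LL", 6))
  )
  # zero inverse temperature: pure coin flips
  cfg0 <- sim_config(n_participants = 400, seed = 5, choice_noise = 0, p_extreme = 0)
  cohort0 <- generate_cohort(cfg0)
  expect_lt(abs(mean(cohort0$records$choice == "LL") - 0.5), 0.02)
})

test_that("raw ambivalence encodings invert the rescaling", {
  grid <- seq(0, 10, by = 0.25)
  # A4 is exact before rounding, for either choice side
  for (choice in c("SS", "LL")) {
    raw <- 50 + ifelse(choice == "LL", 1, -1) * (50 - 5 * grid)
    expect_equal(rescale_ambivalence(raw, "A4"), grid)
  }
  # Likert conditions round to within half a point
  for (cond in c("A1", "A2", "A3")) {
    raw <- if (cond == "A3") floor(grid + 0.5) else floor(10 - grid + 0.5)
    back <- rescale_ambivalence(raw, cond)
    expect_true(all(abs(back - grid) <= 0.5))
  }
})

test_that("flat-ambivalence and extreme-responder fractions follow the config", {
  cfg <- sim_config(n_participants = 50, seed = 6, p_flat_ambivalence = 1)
  truth <- withr::with_seed(6, sample_participants(cfg))
  expect_true(all(truth$is_flat))
  cfg2 <- sim_config(n_participants = 600, seed = 7, p_extreme = 1)
  cohort <- generate_cohort(cfg2)
  scored <- score_mcq(cohort$records)
  expect_gt(mean(scored$is_nonswitcher), 0.9)
})

test_that("default cohort: non-switcher fraction in the plausible 10-25% band", {
  cohort <- generate_cohort(sim_config(n_participants = 1000, seed = 8))
  scored <- score_mcq(cohort$records)
  frac <- mean(scored$is_nonswitcher)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.25)
})

test_that("scored magnitude effect recovers the configured shift at n = 1000", {
  cohort <- generate_cohort(sim_config(n_participants = 1000, seed = 10))
  scored <- score_mcq(cohort$records)
  q <- mcq_quality(scored)
  expect_lt(abs(q$mean_diff - 0.66), 0.10)
})

test_that("generate_cohort writes a schema-valid, reproducible bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_participants = 8, seed = 12)
  generate_cohort(cfg, dir = file.path(dir, "a"))
  generate_cohort(cfg, dir = file.path(dir, "b"))
  expect_identical(
    readLines(file.path(dir, "a", "cohort.csv")),
    readLines(file.path(dir, "b", "cohort.csv"))
  )
  back <- read_cohort(file.path(dir, "a", "cohort.csv"))
  expect_equal(nrow(score_mcq(back)), 16L)
  expect_true(file.exists(file.path(dir, "a", "truth.csv")))
  expect_true(file.exists(file.path(dir, "a", "config.yaml")))
})
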