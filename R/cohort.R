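# Seeded synthetic MCQ cohorts with the population structure the analysis
# assumes: log-normal discount rates with a magnitude effect, stochastic
# single-switch choice patterns plus extreme (never-switching) responders,
# ambivalence peaking at the participant's indifference point with a
# flat-ambivalence subpopulation, and the four raw response formats.

# counterbalanced rotation of magnitude-ambivalence pairings: four slots in
# the A1/A2 arm, four in the A3/A4 arm
.pairing_slots <- data.frame(
  slot = 1:8,
  amb_small = c("A1", "A2", "A2", "A1", "A3", "A3", "A4", "A4"),
  amb_large = c("A2", "A1", "A1", "A2", "A4", "A4", "A3", "A3")
)

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe the study population the analysis pipeline is designed
#' for: 370 participants; large-magnitude discount rates log-normal around
#' k = 0.006 with SD 1.2 on the log scale; a within-person magnitude effect
#' of 0.66 (SD 0.48) log units (small discounted more steeply); roughly 15%
#' extreme responders who never switch preference; 20% of participants with
#' flat (peakless) ambivalence.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed used by [generate_cohort()]; `NULL` leaves the
#'   RNG state untouched.
#' @param mu_ln_k_large,sigma_ln_k Mean and SD of ln k in the large-magnitude
#'   condition.
#' @param magnitude_shift_mean,magnitude_shift_sd Per-participant
#'   ln k(small) - ln k(large) shift distribution.
#' @param choice_noise Inverse temperature tau of the rank-based choice rule
#'   `P(LL) = logistic(tau * (ln k_item - ln k_participant))`; larger values
#'   give cleaner single-switch patterns.
#' @param p_extreme Probability of an extreme responder whose latent ln k
#'   sits `extreme_offset` log units outside the item range (half below,
#'   half above), yielding all-LL / all-SS trial sets.
#' @param extreme_offset Log-unit distance of extreme responders beyond the
#'   item-rate range.
#' @param amb_peak_height_range Range of the per-participant peak
#'   ambivalence height (uniform draw), on the 0-10 scale.
#' @param amb_width Width (SD, in ln-k units) of the Gaussian ambivalence
#'   peak around the participant's indifference point.
#' @param amb_noise_sd Trial-level Gaussian noise SD added to latent
#'   ambivalence before truncation to `[0, 10]`.
#' @param p_flat_ambivalence Probability of a flat-ambivalence participant
#'   (constant latent ambivalence, no peak).
#' @param flat_level_range Range of the constant level for flat participants.
#' @param amb_shape `"gaussian"` (default study condition) or `"linear"`, a
#'   piecewise-linear peak in rank distance from the true switch rank used by
#'   the dual-slopes parameter-recovery suite.
#' @param amb_slope_pre,amb_slope_post Slopes (per rank) of the linear shape
#'   before and after the switch rank.
#' @param sensitivity_mode `"rank_based"` (threshold rule above) or
#'   `"sensitivity_based"` (logistic in the magnitude and delay log-ratios).
#' @param beta_mag,beta_delay Fixed magnitude- and delay-sensitivity
#'   coefficients of the sensitivity-based choice rule.
#' @param beta_delay_small Additional delay sensitivity in the
#'   small-magnitude condition (effects-coded), the generative magnitude
#'   effect on delay sensitivity.
#' @param sensitivity_sd_mag,sensitivity_sd_delay SDs of per-participant
#'   normal deviations around `beta_mag` / `beta_delay`.
#' @param gamma_amb_delay Ambivalence x delay-sensitivity coupling in
#'   `[0, ~1]`: the delay coefficient is multiplied by `1 - gamma * A / 10`,
#'   so choices of highly ambivalent trials depend less on the delay ratio.
#' @param amb_width_eta Width of the Gaussian ambivalence peak on the
#'   linear-predictor scale in sensitivity-based mode.
#' @param delay_convention Delay-ratio convention passed through to
#'   predictor construction, see [compute_predictors()].
#'
#' @return A list of class `mcq_sim_config`.
#' @export
sim_config <- function(n_participants = 370L,
                       seed = NULL,
                       mu_ln_k_large = log(0.006),
                       sigma_ln_k = 1.2,
                       magnitude_shift_mean = 0.66,
                       magnitude_shift_sd = 0.48,
                       choice_noise = 2.3,
                       p_extreme = 0.15,
                       extreme_offset = 1.5,
                       amb_peak_height_range = c(4, 9),
                       amb_width = 1.8,
                       amb_noise_sd = 1,
                       p_flat_ambivalence = 0.20,
                       flat_level_range = c(0, 5),
                       amb_shape = c("gaussian", "linear"),
                       amb_slope_pre = 0.4,
                       amb_slope_post = -0.5,
                       sensitivity_mode = c("rank_based", "sensitivity_based"),
                       beta_mag = 12.95,
                       beta_delay = -1.25,
                       beta_delay_small = -0.11,
                       sensitivity_sd_mag = 0,
                       sensitivity_sd_delay = 0,
                       gamma_amb_delay = 0.6,
                       amb_width_eta = 2,
                       delay_convention = "offset1") {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = seed,
    mu_ln_k_large = mu_ln_k_large, sigma_ln_k = sigma_ln_k,
    magnitude_shift_mean = magnitude_shift_mean,
    magnitude_shift_sd = magnitude_shift_sd,
    choice_noise = choice_noise,
    p_extreme = p_extreme, extreme_offset = extreme_offset,
    amb_peak_height_range = amb_peak_height_range,
    amb_width = amb_width, amb_noise_sd = amb_noise_sd,
    p_flat_ambivalence = p_flat_ambivalence,
    flat_level_range = flat_level_range,
    amb_shape = match.arg(amb_shape),
    amb_slope_pre = amb_slope_pre, amb_slope_post = amb_slope_post,
    sensitivity_mode = match.arg(sensitivity_mode),
    beta_mag = beta_mag, beta_delay = beta_delay,
    beta_delay_small = beta_delay_small,
    sensitivity_sd_mag = sensitivity_sd_mag,
    sensitivity_sd_delay = sensitivity_sd_delay,
    gamma_amb_delay = gamma_amb_delay, amb_width_eta = amb_width_eta,
    delay_convention = delay_convention
  )
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_participants >= 1L, "n_participants must be >= 1")
  chk(cfg$sigma_ln_k > 0, "sigma_ln_k must be > 0")
  chk(cfg$magnitude_shift_sd >= 0, "magnitude_shift_sd must be >= 0")
  chk(cfg$choice_noise >= 0, "choice_noise must be >= 0")
  chk(cfg$p_extreme >= 0 && cfg$p_extreme <= 1, "p_extreme must be in [0, 1]")
  chk(
    cfg$p_flat_ambivalence >= 0 && cfg$p_flat_ambivalence <= 1,
    "p_flat_ambivalence must be in [0, 1]"
  )
  chk(cfg$amb_width > 0, "amb_width must be > 0")
  chk(cfg$amb_noise_sd >= 0, "amb_noise_sd must be >= 0")
  chk(
    length(cfg$amb_peak_height_range) == 2L &&
      all(cfg$amb_peak_height_range >= 0) &&
      all(cfg$amb_peak_height_range <= 10) &&
      diff(cfg$amb_peak_height_range) >= 0,
    "amb_peak_height_range must be an ordered interval within [0, 10]"
  )
  chk(cfg$gamma_amb_delay >= 0, "gamma_amb_delay must be >= 0")
  chk(cfg$sensitivity_sd_mag >= 0, "sensitivity_sd_mag must be >= 0")
  chk(cfg$sensitivity_sd_delay >= 0, "sensitivity_sd_delay must be >= 0")
  if (length(problems)) {
    stop("Invalid simulation configuration:\n  - ",
      paste(problems, collapse = "\n  - "),
      call. = FALSE
    )
  }
  structure(cfg, class = "mcq_sim_config")
}

#' Draw the per-participant generating parameters of a cohort
#'
#' Samples latent discount rates (large-magnitude ln k plus a per-participant
#' magnitude shift), extreme-responder and flat-ambivalence flags, peak
#' heights, per-participant reward sensitivities, and the counterbalanced
#' magnitude-ambivalence pairing assignment.
#'
#' @param config An [sim_config()] object. The caller controls the RNG state;
#'   [generate_cohort()] seeds it from `config$seed`.
#' @param bank Item bank used to anchor extreme responders outside the item
#'   rate range.
#' @return A tibble with one row per participant (the "truth" table).
#' @export
sample_participants <- function(config = sim_config(), bank = mcq_item_bank()) {
  stopifnot(inherits(config, "mcq_sim_config"))
  n <- config$n_participants
  ln_k_large <- stats::rnorm(n, config$mu_ln_k_large, config$sigma_ln_k)
  shift <- stats::rnorm(n, config$magnitude_shift_mean, config$magnitude_shift_sd)

  is_extreme <- stats::runif(n) < config$p_extreme
  extreme_side <- ifelse(stats::runif(n) < 0.5, "low", "high")
  extreme_side[!is_extreme] <- NA_character_
  lo <- log(min(bank$k_indiff)) - config$extreme_offset
  hi <- log(max(bank$k_indiff)) + config$extreme_offset
  ln_k_large[is_extreme & extreme_side == "low"] <- lo
  ln_k_large[is_extreme & extreme_side == "high"] <- hi
  ln_k_small <- ln_k_large + shift

  is_flat <- stats::runif(n) < config$p_flat_ambivalence
  peak_height <- stats::runif(
    n, config$amb_peak_height_range[1L],
    config$amb_peak_height_range[2L]
  )
  flat_level <- stats::runif(
    n, config$flat_level_range[1L],
    config$flat_level_range[2L]
  )
  sens_mag <- config$beta_mag + stats::rnorm(n, 0, config$sensitivity_sd_mag)
  sens_delay <- config$beta_delay + stats::rnorm(n, 0, config$sensitivity_sd_delay)

  slot <- ((seq_len(n) - 1L) %% 8L) + 1L
  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    ln_k_large = ln_k_large,
    ln_k_small = ln_k_small,
    is_extreme = is_extreme,
    extreme_side = extreme_side,
    is_flat = is_flat,
    peak_height = peak_height,
    flat_level = flat_level,
    sens_mag = sens_mag,
    sens_delay = sens_delay,
    slot = slot,
    amb_small = .pairing_slots$amb_small[slot],
    amb_large = .pairing_slots$amb_large[slot]
  )
}

# long trial frame: one row per participant x item, with the participant's
# latent ln k and ambivalence condition for that item's magnitude condition
.trial_frame <- function(truth, bank) {
  trials <- tidyr::crossing(
    participant_id = truth$participant_id,
    bank[, c("magnitude", "k_rank")]
  )
  trials <- dplyr::left_join(trials, bank,
    by = c("magnitude", "k_rank")
  )
  trials <- dplyr::left_join(trials, truth, by = "participant_id")
  trials$ln_k_p <- ifelse(trials$magnitude == "small",
    trials$ln_k_small, trials$ln_k_large
  )
  trials$amb_condition <- ifelse(trials$magnitude == "small",
    trials$amb_small, trials$amb_large
  )
  dplyr::arrange(trials, .data$participant_id, .data$magnitude, .data$k_rank)
}

#' Simulate trial-level choices for a cohort
#'
#' In `rank_based` mode the probability of choosing the larger-later reward
#' is `logistic(tau * (ln k_item - ln k_participant))`, producing noisy
#' single-switch patterns centered on the participant's indifference rank.
#' In `sensitivity_based` mode choices follow a logistic model in the
#' magnitude and delay log-ratios; latent ambivalence is first derived from
#' the base linear predictor and the choice is then redrawn with the delay
#' sensitivity attenuated by `1 - gamma * A / 10`, so that ambivalent trials
#' weigh the delay ratio less (the two-stage construction avoids defining
#' ambivalence circularly from the final choice).
#'
#' @inheritParams sample_participants
#' @param truth Truth table from [sample_participants()].
#' @return Tibble of trials with `choice` and, in sensitivity-based mode, the
#'   `latent_amb` used for the attenuation.
#' @export
simulate_choices <- function(truth, bank = mcq_item_bank(), config = sim_config()) {
  stopifnot(inherits(config, "mcq_sim_config"))
  trials <- .trial_frame(truth, bank)
  n <- nrow(trials)
  if (config$sensitivity_mode == "rank_based") {
    p_ll <- stats::plogis(config$choice_noise * (log(trials$k_indiff) - trials$ln_k_p))
    trials$choice <- ifelse(stats::runif(n) < p_ll, "LL", "SS")
    trials$latent_amb <- NA_real_
  } else {
    pred <- compute_predictors(trials, convention = config$delay_convention)
    small_code <- ifelse(trials$magnitude == "small", 1, -1)
    b_delay <- trials$sens_delay + config$beta_delay_small * small_code
    eta_base <- trials$sens_mag * pred$mag_ratio + b_delay * pred$delay_ratio
    lat <- ifelse(trials$is_flat,
      trials$flat_level,
      trials$peak_height * exp(-eta_base^2 / (2 * config$amb_width_eta^2))
    )
    lat <- lat + stats::rnorm(n, 0, config$amb_noise_sd)
    trials$latent_amb <- pmin(10, pmax(0, lat))
    atten <- 1 - config$gamma_amb_delay * trials$latent_amb / 10
    eta <- trials$sens_mag * pred$mag_ratio + b_delay * atten * pred$delay_ratio
    trials$choice <- ifelse(stats::runif(n) < stats::plogis(eta), "LL", "SS")
  }
  trials
}

# round half away from zero (all scores are non-negative here)
.round_half_up <- function(x) floor(x + 0.5)

#' Simulate raw ambivalence responses
#'
#' Latent ambivalence follows a Gaussian peak over the distance between the
#' item's indifference rate and the participant's discount rate on the log
#' scale (`gaussian` shape), a piecewise-linear peak in rank distance from
#' the true switch rank (`linear` shape), or a constant for flat-ambivalence
#' participants; trial noise is added and the result truncated to `[0, 10]`.
#' The latent score is then encoded into each measurement condition's raw
#' format as the exact inverse of [rescale_ambivalence()]: Likert conditions
#' round to integers (A1/A2 flipped about the midpoint), the A4 slider stays
#' continuous with the side of the midpoint set by the simulated choice.
#'
#' @inheritParams simulate_choices
#' @param choices Trial tibble from [simulate_choices()].
#' @return `choices` with columns `latent_amb` and `raw_ambivalence` filled.
#' @export
simulate_ambivalence <- function(truth, choices, bank = mcq_item_bank(),
                                 config = sim_config()) {
  stopifnot(inherits(config, "mcq_sim_config"))
  trials <- choices
  n <- nrow(trials)
  if (config$sensitivity_mode == "rank_based") {
    if (config$amb_shape == "gaussian") {
      dist <- log(trials$k_indiff) - trials$ln_k_p
      shape <- trials$peak_height * exp(-dist^2 / (2 * config$amb_width^2))
    } else {
      # true switch rank: lowest rank whose item rate exceeds the latent k
      sw <- dplyr::group_by(trials, .data$participant_id, .data$magnitude)
      sw <- dplyr::mutate(sw,
        true_switch = {
          ab <- which(log(.data$k_indiff) > .data$ln_k_p[1L])
          if (length(ab)) min(ab) else 9L
        }
      )
      trials <- dplyr::ungroup(sw)
      d <- trials$k_rank - trials$true_switch
      shape <- trials$peak_height +
        config$amb_slope_pre * pmin(d, 0) +
        config$amb_slope_post * pmax(d, 0)
    }
    lat <- ifelse(trials$is_flat, trials$flat_level, shape)
    lat <- lat + stats::rnorm(n, 0, config$amb_noise_sd)
    trials$latent_amb <- pmin(10, pmax(0, lat))
  }
  a <- trials$latent_amb
  cond <- trials$amb_condition
  raw <- numeric(n)
  flip <- cond %in% c("A1", "A2")
  raw[flip] <- .round_half_up(10 - a[flip])
  raw[cond == "A3"] <- .round_half_up(a[cond == "A3"])
  a4 <- cond == "A4"
  sign_ll <- ifelse(trials$choice[a4] == "LL", 1, -1)
  raw[a4] <- 50 + sign_ll * (50 - 5 * a[a4])
  trials$raw_ambivalence <- raw
  trials
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_participants()], [simulate_choices()] and
#' [simulate_ambivalence()] under a single seed and returns the long trial
#' table in the scoring-module schema together with the generating truth.
#'
#' @inheritParams sample_participants
#' @param seed Integer seed; defaults to `config$seed`.
#' @param dir Optional directory; when given, writes `cohort.csv`,
#'   `truth.csv` and `config.yaml` there.
#' @return A list of class `mcq_cohort` with elements `records` (scoring
#'   schema: `participant_id`, `magnitude`, `k_rank`, `choice`,
#'   `raw_ambivalence`, `amb_condition`), `truth` and `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 8, seed = 1))
#' nrow(cohort$records) # 8 x 18
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed, dir = NULL) {
  stopifnot(inherits(config, "mcq_sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  bank <- mcq_item_bank()
  truth <- sample_participants(config, bank)
  trials <- simulate_choices(truth, bank, config)
  trials <- simulate_ambivalence(truth, trials, bank, config)
  records <- dplyr::select(
    trials, "participant_id", "magnitude", "k_rank",
    "choice", "raw_ambivalence", "amb_condition"
  )
  out <- structure(
    list(records = records, truth = truth, config = config),
    class = "mcq_cohort"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tryCatch(
      {
        readr::write_csv(records, file.path(dir, "cohort.csv"))
        readr::write_csv(truth, file.path(dir, "truth.csv"))
        cfg <- unclass(config)
        cfg$seed <- if (is.null(seed)) NULL else as.integer(seed)
        yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
      },
      error = function(e) {
        stop("Failed writing cohort files to '", dir, "': ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
  }
  out
}
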