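# fabricate a minimal mcq_fit for comparison-logic tests
fake_fit <- function(label, aic, n_obs = 100) {
  structure(
    list(
      terms = tibble::tibble(), vcov = matrix(0, 0, 0), aic = aic,
      log_lik = -aic / 2, n_obs = n_obs, n_groups = 10,
      ranef_var = numeric(0), converged = TRUE, singular = FALSE,
      engine = "newton", family = "binomial", label = label
    ),
    class = "mcq_fit"
  )
}

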