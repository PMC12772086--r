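# Shared fixtures built in code.

# Independent penalized log-likelihood for the Firth oracle checks:
# l(beta) + 0.5 * log det(X' W X), evaluated directly.
penalized_loglik_oracle <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(X * sqrt(pmax(p * (1 - p), 1e-300)))
  ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

# Ten-row questionnaire fixture with known filter violations.
filter_fixture <- function() {
  data.frame(
    dog_id = sprintf("d%02d", 1:10),
    age_years = c(0.5, 1, 19, 20, 5, 5, 5, 0.9, 5, 18.9),
    bcs_owner_9pt = c(5, 5, 5, 6, NA, 3, 2, 3, 4, 9)
  )
}

# One questionnaire row as a named list of answers; helpers to build rows
# for the hand-scored fixture.
answer_row <- function(...) {
  row <- stats::setNames(as.list(rep(NA_character_, 26)),
                         sprintf("item_%02d", 1:26))
  override <- list(...)
  row[names(override)] <- override
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Small EHR-style cohort fitted without interactions, used by several
# model-surgery tests.
small_bcs_model <- function(seed = 5, n = 1200, n_breeds = 4) {
  cfg <- sim_config(n_dogs = 50, n_breeds = n_breeds, ehr_n_dogs = n,
                    seed = seed)
  g <- generate_ehr_cohort(cfg)
  rec <- select_random_visit(g$data, seed = seed)
  rec$bcs_category <- merge_bcs_5pt(rec$bcs_5pt)
  fit_bcs_multinomial(rec, interactions = FALSE)
}
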