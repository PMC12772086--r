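test_that("intercept-only Firth fits match the (k + 1/2)/(n + 1) closed form", {
  X <- matrix(1, nrow = 10, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  # balanced: symmetry forces the intercept to zero
  f5 <- fit_firth_logistic(X, rep(c(0, 1), each = 5))
  expect_true(f5$converged)
  expect_equal(unname(f5$coefficients), 0, tolerance = 1e-8)

  # all successes: penalized mode p-hat = 10.5/11, finite despite k = n
  f10 <- fit_firth_logistic(X, rep(1, 10))
  expect_equal(unname(f10$coefficients), log(10.5 / 0.5), tolerance = 1e-6)
  expect_equal(stats::plogis(unname(f10$coefficients)), 10.5 / 11,
               tolerance = 1e-6)
  # 1-D maximization of the independently coded penalized log-likelihood
  oracle <- stats::optimize(function(b) penalized_loglik_oracle(b, X, rep(1, 10)),
                            c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(f10$coefficients), oracle, tolerance = 1e-6)

  for (k in c(1, 3, 7)) {
    y <- c(rep(1, k), rep(0, 10 - k))
    fk <- fit_firth_logistic(X, y)
    expect_equal(stats::plogis(unname(fk$coefficients)), (k + 0.5) / 11,
                 tolerance = 1e-6)
  }
})

test_that("complete separation yields the finite grid-search maximizer", {
  X <- cbind(`(Intercept)` = 1, x = rep(c(0, 1), each = 5))
  y <- rep(c(0, 1), each = 5)   # x = 0 all failures, x = 1 all successes
  fit <- fit_firth_logistic(X, y)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))

  oracle <- stats::optim(c(0, 0),
                         function(b) -penalized_loglik_oracle(b, X, y),
                         control = list(reltol = 1e-15, maxit = 10000))
  expect_equal(unname(fit$coefficients), oracle$par, tolerance = 1e-4)
  # the per-cell Jeffreys modes: p = 0.5/6 and 5.5/6
  expect_equal(stats::plogis(unname(fit$coefficients[1])), 0.5 / 6,
               tolerance = 1e-6)
  expect_equal(stats::plogis(sum(fit$coefficients)), 5.5 / 6,
               tolerance = 1e-6)
})

test_that("penalized estimates approach ML away from separation", {
  set.seed(7)
  n <- 20000
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = runif(n))
  eta <- -0.3 + 0.5 * d$x1 - 0.8 * d$x2 + 0.4 * d$x3
  d$y <- rbinom(n, 1, stats::plogis(eta))
  X <- stats::model.matrix(~ x1 + x2 + x3, d)
  firth <- fit_firth_logistic(X, d$y)
  ml <- stats::glm(y ~ x1 + x2 + x3, data = d, family = stats::binomial())
  expect_lt(max(abs(firth$coefficients - stats::coef(ml))), 0.02)
  # covariance agrees with the ML information at this n
  expect_lt(max(abs(firth$covariance - stats::vcov(ml))), 1e-4)
})

test_that("fit diagnostics and error contracts hold", {
  X <- cbind(`(Intercept)` = 1, a = c(0, 1, 0, 1, 0, 1), b = c(0, 2, 0, 2, 0, 2))
  expect_error(fit_firth_logistic(X, c(0, 1, 0, 1, 1, 0)), "aliased.*b")
  expect_error(fit_firth_logistic(X[, 1:2], c(0, 1, 2, 1, 0, 1)), "binary")

  # penalized log-likelihood at the estimate is no worse than at the start
  Xs <- cbind(1, rnorm(50))
  set.seed(1)
  ys <- rbinom(50, 1, 0.5)
  fit <- fit_firth_logistic(Xs, ys)
  expect_gte(fit$penalized_loglik, penalized_loglik_oracle(c(0, 0), Xs, ys))
  # covariance is symmetric positive definite
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("merged binomials form a proper probability triple", {
  expect_equal(unname(merge_binomials(0, 0)[1, ]), rep(1 / 3, 3))
  p <- merge_binomials(-20, 0)
  expect_equal(unname(p[1, ]), c(0, 0.5, 0.5), tolerance = 1e-8)
  set.seed(2)
  etas <- matrix(rnorm(600, sd = 5), ncol = 2)
  trip <- merge_binomials(etas[, 1], etas[, 2])
  expect_true(all(abs(rowSums(trip) - 1) < 1e-12))
  expect_true(all(trip >= 0 & trip <= 1))
  # consistency with each conditional binomial
  expect_equal(trip[, "underweight"] / (trip[, "underweight"] + trip[, "ideal"]),
               stats::plogis(etas[, 1]), tolerance = 1e-10)
})

test_that("standardized probabilities reduce correctly in known cases", {
  model <- small_bcs_model()

  # null model: zero coefficients give (1/3, 1/3, 1/3) for any weights
  null_model <- model
  null_model$fit_under$coefficients[] <- 0
  null_model$fit_over$coefficients[] <- 0
  ages <- as.numeric(names(model$data_age_distribution))
  odd_w <- stats::setNames(seq_along(ages) / sum(seq_along(ages)), ages)
  tab <- standardized_breed_probabilities(null_model, odd_w)
  expect_true(all(abs(tab$p_underweight - 1 / 3) < 1e-12))
  expect_true(all(abs(tab$p_overweight_obese - 1 / 3) < 1e-12))
  expect_true(all(abs(tab$p_underweight + tab$p_ideal +
                        tab$p_overweight_obese - 1) < 1e-10))

  # point mass at one age equals the two-sex average at that age
  a5 <- stats::setNames(1, "5")
  tab5 <- standardized_breed_probabilities(model, a5)
  grid <- expand.grid(breed = model$breeds, age_years = 5,
                      sex = model$sexes, stringsAsFactors = FALSE)
  grid$age <- grid$age_years
  p <- merge_binomials(predict_eta(model$fit_under, grid),
                       predict_eta(model$fit_over, grid))
  manual <- rowsum(p * 0.5, grid$breed)[model$breeds, ]
  expect_equal(tab5$p_overweight_obese, unname(manual[, "overweight_obese"]),
               tolerance = 1e-12)

  expect_error(standardized_breed_probabilities(model,
                                                stats::setNames(c(0.6, 0.6), c(1, 2))),
               "sum to 1")
})

test_that("standardization equals a hand-weighted enumeration", {
  model <- small_bcs_model(n_breeds = 2)
  # hand-set coefficients; coding is (Intercept), breed_02, age, sex
  expect_equal(model$fit_under$term_names,
               c("(Intercept)", "breedbreed_02", "age", "sex1"))
  model$fit_under$coefficients[] <- c(-1.0, 0.3, 0.05, -0.2)
  model$fit_over$coefficients[] <- c(0.2, 0.6, -0.1, 0.4)
  w_age <- c(`2` = 0.25, `9` = 0.75)
  tab <- standardized_breed_probabilities(model, w_age)

  eta_by_hand <- function(co, breed2, age, sex) {
    co[1] + co[2] * breed2 + co[3] * age + co[4] * sex
  }
  cu <- model$fit_under$coefficients
  co <- model$fit_over$coefficients
  for (b2 in c(0, 1)) {
    acc <- c(0, 0, 0)
    for (age in c(2, 9)) for (sex in c(0, 1)) {
      trip <- merge_binomials(eta_by_hand(cu, b2, age, sex),
                              eta_by_hand(co, b2, age, sex))
      acc <- acc + w_age[as.character(age)] * 0.5 * trip[1, ]
    }
    row <- tab[tab$breed == c("breed_01", "breed_02")[b2 + 1], ]
    expect_equal(unname(c(row$p_underweight, row$p_ideal,
                          row$p_overweight_obese)),
                 unname(acc), tolerance = 1e-12)
  }
})

test_that("recoding the sex reference leaves standardized probabilities unchanged", {
  cfg <- sim_config(n_dogs = 50, n_breeds = 4, ehr_n_dogs = 1600, seed = 8)
  g <- generate_ehr_cohort(cfg)
  rec <- select_random_visit(g$data, seed = 8)
  rec$bcs_category <- merge_bcs_5pt(rec$bcs_5pt)
  m1 <- fit_bcs_multinomial(rec, interactions = FALSE)
  rec2 <- rec
  rec2$sex <- ifelse(rec$sex == 1, "a_male", "b_female")  # flips the reference
  m2 <- fit_bcs_multinomial(rec2, interactions = FALSE)
  expect_false(isTRUE(all.equal(m1$fit_over$coefficients,
                                m2$fit_over$coefficients)))
  t1 <- standardized_breed_probabilities(m1)
  t2 <- standardized_breed_probabilities(m2)
  expect_equal(t1$p_overweight_obese, t2$p_overweight_obese, tolerance = 1e-10)
  expect_equal(t1$p_underweight, t2$p_underweight, tolerance = 1e-10)
})

test_that("simulation intervals are reproducible and degenerate correctly", {
  model <- small_bcs_model()
  ci_a <- simulate_confidence_intervals(model, n_draws = 150, seed = 42)
  ci_b <- simulate_confidence_intervals(model, n_draws = 150, seed = 42)
  expect_equal(ci_a, ci_b)
  ci_c <- simulate_confidence_intervals(model, n_draws = 150, seed = 43)
  expect_false(isTRUE(all.equal(ci_a$ci_low_overweight_obese,
                                ci_c$ci_low_overweight_obese)))
  expect_true(all(ci_a$ci_low_overweight_obese <= ci_a$p_overweight_obese +
                    1e-12))
  expect_true(all(ci_a$ci_high_overweight_obese >= ci_a$p_overweight_obese -
                    1e-12))

  # zero covariance collapses the interval onto the point estimate
  degen <- model
  degen$fit_under$covariance[] <- 0
  degen$fit_over$covariance[] <- 0
  ci_d <- suppressWarnings(simulate_confidence_intervals(degen, n_draws = 99,
                                                         seed = 1))
  expect_equal(ci_d$ci_low_overweight_obese, ci_d$p_overweight_obese,
               tolerance = 1e-10)
  expect_equal(ci_d$ci_high_overweight_obese, ci_d$p_overweight_obese,
               tolerance = 1e-10)
  expect_warning(simulate_confidence_intervals(model, n_draws = 50, seed = 1),
                 "fewer than 100")
})
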