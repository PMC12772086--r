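test_that("OLS wrapper reproduces the normal-equations solution", {
  d <- data.frame(x = 1:5)
  d$y <- 2 * d$x
  fit <- suppressWarnings(fit_ols(y ~ x, d))
  expect_equal(unname(fit$coefficients["x"]), 2)
  expect_equal(fit$r_squared, 1)

  # constant covariate is aliased, reported as an error
  d$z <- 3
  expect_error(fit_ols(y ~ x + z, d), "aliased.*z")

  # 6-row hand dataset against solve(X'X, X'y)
  h <- data.frame(x1 = c(1, 2, 3, 4, 5, 6), x2 = c(0, 1, 0, 1, 1, 0),
                  y = c(1.2, 2.1, 2.9, 4.4, 5.1, 5.8))
  X <- cbind(1, h$x1, h$x2)
  beta_oracle <- drop(solve(crossprod(X), crossprod(X, h$y)))
  fit_h <- fit_ols(y ~ x1 + x2, h)
  expect_equal(unname(fit_h$coefficients), beta_oracle, tolerance = 1e-10)
  rss <- sum((h$y - drop(X %*% beta_oracle))^2)
  tss <- sum((h$y - mean(h$y))^2)
  expect_equal(fit_h$r_squared, 1 - rss / tss, tolerance = 1e-10)
})

test_that("stepwise AIC matches exhaustive search and is a fixed point", {
  set.seed(31)
  n <- 400
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1.5 * d$x1 + rnorm(n)
  sel <- stepwise_aic(y ~ x1 + x2, d)
  # exhaustive oracle over the four submodels: the selection must land on
  # the global AIC minimum and keep the true signal
  forms <- list(`1` = y ~ 1, x1 = y ~ x1, x2 = y ~ x2, x1_x2 = y ~ x1 + x2)
  aics <- vapply(forms, function(f) stats::AIC(stats::lm(f, d)), numeric(1))
  expect_equal(sel$aic, unname(min(aics)), tolerance = 1e-8)
  best_terms <- attr(stats::terms(forms[[which.min(aics)]]), "term.labels")
  expect_setequal(attr(stats::terms(sel$model), "term.labels"), best_terms)
  expect_true("x1" %in% attr(stats::terms(sel$model), "term.labels"))

  # an already-minimal model is returned unchanged
  sel2 <- stepwise_aic(stats::formula(sel$model), d)
  expect_equal(sel2$coefficients, sel$coefficients)
})

test_that("marginality is respected: main effects stay while interactions remain", {
  set.seed(5)
  n <- 2000
  d <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 1, 15))
  d$y <- 0.05 * d$sex * d$age + rnorm(n, sd = 0.3)  # pure interaction signal
  sel <- stepwise_aic(y ~ sex * age, d)
  tl <- attr(stats::terms(sel$model), "term.labels")
  expect_true("sex:age" %in% tl)
  expect_true(all(c("sex", "age") %in% tl))
})

test_that("breed-adjusted food motivation centers covariates at breed means", {
  d <- data.frame(breed = c("a", "a", "a", "a"),
                  sex = c(0, 1, 0, 1), neuter = c(0, 0, 1, 1),
                  fms = c(0.4, 0.5, 0.6, 0.7))
  null_fit <- list(coefficients = c(sex = 0, neuter = 0, `sex:neuter` = 0))
  expect_equal(adjusted_fms(d, null_fit), d$fms)

  fit <- list(coefficients = c(sex = 0.1, neuter = 0, `sex:neuter` = 0))
  # breed mean sex = 0.5: females gain 0.05, males lose 0.05
  expect_equal(adjusted_fms(d, fit),
               c(0.4 + 0.05, 0.5 - 0.05, 0.6 + 0.05, 0.7 - 0.05))

  # a dog at its breed's covariate means keeps its raw score
  d2 <- data.frame(breed = "b", sex = 0.5, neuter = 0.5, fms = 0.55)
  fit2 <- list(coefficients = c(sex = 0.2, neuter = -0.1, `sex:neuter` = 0.3))
  expect_equal(adjusted_fms(d2, fit2), 0.55)

  # full hand example with all three coefficients
  d3 <- data.frame(breed = rep("c", 4), sex = c(0, 1, 1, 0),
                   neuter = c(0, 1, 0, 1), fms = c(0.5, 0.6, 0.4, 0.7))
  fit3 <- list(coefficients = c(sex = 0.1, neuter = 0.2, `sex:neuter` = 0.4))
  # means: sex 0.5, neuter 0.5, interaction 0.25
  expect_equal(adjusted_fms(d3, fit3),
               c(0.5 - 0.1 * (0 - 0.5) - 0.2 * (0 - 0.5) - 0.4 * (0 - 0.25),
                 0.6 - 0.1 * (1 - 0.5) - 0.2 * (1 - 0.5) - 0.4 * (1 - 0.25),
                 0.4 - 0.1 * (1 - 0.5) - 0.2 * (0 - 0.5) - 0.4 * (0 - 0.25),
                 0.7 - 0.1 * (0 - 0.5) - 0.2 * (1 - 0.5) - 0.4 * (0 - 0.25)))
})

test_that("tertile effect extraction is a pure reparameterization", {
  set.seed(77)
  n <- 900
  d <- data.frame(
    owner_intervention = runif(n), restriction_human_food = runif(n),
    exercise_taken = runif(n), sex = rbinom(n, 1, 0.5),
    neuter = rbinom(n, 1, 0.6), age_years = runif(n, 1, 15),
    fms_tertile = factor(sample(c("low", "medium", "high"), n, TRUE),
                         levels = c("low", "medium", "high"))
  )
  slopes <- c(low = -0.4, medium = -0.9, high = -1.6)
  d$bcs_owner_9pt <- 5 + slopes[as.character(d$fms_tertile)] *
    d$owner_intervention - 0.5 * d$restriction_human_food +
    0.3 * d$sex + 0.05 * d$age_years + rnorm(n, sd = 0.6)

  res <- extract_tertile_effects(d)
  eff <- res$effects
  oi <- eff[eff$term == "owner_intervention", ]
  # per-tertile slopes recovered within ~3 standard errors
  for (g in names(slopes)) {
    row <- oi[oi$tertile == g, ]
    expect_lt(abs(row$beta - slopes[[g]]), 3 * row$std_error)
  }
  # monotone ordering of the recovered management effect
  expect_true(oi$beta[oi$tertile == "high"] < oi$beta[oi$tertile == "low"])

  # algebraic identity: releveled main effect = base slope + interaction
  d$.tert <- d$fms_tertile
  base <- stats::lm(bcs_owner_9pt ~ owner_intervention * .tert +
                      restriction_human_food * .tert + exercise_taken * .tert +
                      sex * .tert + neuter * .tert + sex * neuter + age_years,
                    d)
  cf <- stats::coef(base)
  expect_equal(oi$beta[oi$tertile == "low"],
               unname(cf["owner_intervention"]), tolerance = 1e-10)
  expect_equal(oi$beta[oi$tertile == "medium"],
               unname(cf["owner_intervention"] +
                        cf["owner_intervention:.tertmedium"]),
               tolerance = 1e-10)
  expect_equal(oi$beta[oi$tertile == "high"],
               unname(cf["owner_intervention"] +
                        cf["owner_intervention:.terthigh"]),
               tolerance = 1e-10)

  expect_error(extract_tertile_effects(d[d$fms_tertile != "high", ]),
               "empty tertile")
})

test_that("correlation, ANOVA and Holm comparisons match hand arithmetic", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  res <- pearson_cor(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-10)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p, 2 * stats::pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "at least 3")

  # 3-group ANOVA against hand sums of squares
  g <- rep(c("a", "b", "c"), each = 4)
  v <- c(1, 2, 3, 2, 4, 5, 6, 5, 2, 3, 2, 3)
  means <- tapply(v, g, mean); grand <- mean(v)
  ssb <- sum(4 * (means - grand)^2)
  ssw <- sum((v - means[g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  res_a <- one_way_anova(v, g)
  expect_equal(res_a$f, f_hand, tolerance = 1e-10)
  expect_equal(res_a$p, stats::pf(f_hand, 2, 9, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical data across groups
  flat <- one_way_anova(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$f, 0)
  # constant groups with distinct means: degenerate infinite F, flagged
  degen <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(degen$degenerate)
  expect_equal(degen$f, Inf)

  # Holm step-down against explicit pooled-t arithmetic
  vals <- c(4.1, 3.9, 4.3, 4.0, 5.2, 5.0, 5.5, 5.1, 4.6, 4.4, 4.9, 4.5)
  grp <- rep(c("a", "b", "c"), each = 4)
  adj <- pairwise_t_holm(vals, grp)
  s2_pool <- sum((vals - tapply(vals, grp, mean)[grp])^2) / (12 - 3)
  t_stat <- function(g1, g2) {
    (mean(vals[grp == g1]) - mean(vals[grp == g2])) /
      sqrt(s2_pool * (1 / 4 + 1 / 4))
  }
  raw <- c(ab = 2 * stats::pt(abs(t_stat("a", "b")), 9, lower.tail = FALSE),
           ac = 2 * stats::pt(abs(t_stat("a", "c")), 9, lower.tail = FALSE),
           bc = 2 * stats::pt(abs(t_stat("b", "c")), 9, lower.tail = FALSE))
  ord <- order(raw)
  holm <- raw
  holm[ord] <- pmin(1, cummax((3:1) * raw[ord]))
  expect_equal(adj["b", "a"], unname(holm["ab"]), tolerance = 1e-10)
  expect_equal(adj["c", "a"], unname(holm["ac"]), tolerance = 1e-10)
  expect_equal(adj["c", "b"], unname(holm["bc"]), tolerance = 1e-10)
  # dominance: adjusted never below raw
  expect_true(all(c(adj["b", "a"], adj["c", "a"], adj["c", "b"]) >=
                    unname(raw[c("ab", "ac", "bc")]) - 1e-12))
  # identical groups give adjusted p of 1
  same <- pairwise_t_holm(rep(c(1, 2, 1, 2), 3), rep(c("a", "b", "c"), each = 4))
  expect_true(all(same == 1, na.rm = TRUE))
})

test_that("model comparison orders nested fits correctly", {
  set.seed(12)
  n <- 500
  d <- data.frame(x = rnorm(n), b = factor(sample(letters[1:5], n, TRUE)))
  d$y <- 0.5 * d$x + c(a = -1, b = 0, c = 1, d = 2, e = -2)[d$b] + rnorm(n)
  f1 <- fit_ols(y ~ x, d)
  f2 <- fit_ols(y ~ x + b, d)
  cmp <- compare_models(list(base = f1, with_group = f2))
  expect_gte(cmp$r_squared[2], cmp$r_squared[1])
  expect_equal(cmp$delta_r_squared[1], 0)
  expect_equal(cmp$delta_aic[1], 0)
  same <- compare_models(list(m1 = f1, m2 = f1))
  expect_equal(same$delta_r_squared[2], 0)
  expect_equal(same$delta_aic[2], 0)

  cm <- correlation_matrix(d, c("x", "y"))
  expect_equal(cm$r["x", "y"], stats::cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(diag(cm$r), c(x = 1, y = 1))
})
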