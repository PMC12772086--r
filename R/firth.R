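#' Firth bias-reduced logistic regression
#'
#' Fits a binary logistic regression by maximizing the penalized
#' log-likelihood \eqn{l(\beta) + \frac{1}{2}\log\det I(\beta)}, where
#' \eqn{I(\beta) = X^\top W X} is the Fisher information and
#' \eqn{W = \mathrm{diag}\{\pi_i(1-\pi_i)\}}. The penalty (Jeffreys prior)
#' removes the leading-order bias of maximum likelihood and, crucially for
#' sparse factor combinations, keeps estimates finite under complete or
#' quasi-complete separation. The estimate solves the modified score
#' equations
#' \deqn{U^*_j(\beta) = \sum_i \{y_i - \pi_i + h_i(1/2 - \pi_i)\} x_{ij} = 0,}
#' with \eqn{h_i} the hat-matrix diagonals
#' \eqn{h = \mathrm{diag}\{W^{1/2}X(X^\top W X)^{-1}X^\top W^{1/2}\}}.
#' Newton iterations start from \eqn{\beta = 0} with step-halving whenever a
#' step would decrease the penalized log-likelihood.
#'
#' @param design Numeric design matrix (including the intercept column);
#'   must be full column rank.
#' @param y Binary response vector (0/1), `length(y) == nrow(design)`.
#' @param tol Convergence tolerance on the maximum absolute modified score
#'   (default `1e-8`).
#' @param max_iter Maximum Newton iterations (default 200; under quasi-separation the modified-score iteration converges linearly rather than quadratically, so generous caps are appropriate).
#'
#' @return An object of class `firth_fit`: list with `coefficients`,
#'   `covariance` (inverse Fisher information at the estimate),
#'   `penalized_loglik`, `n_iterations`, `converged`, `term_names`, `n`.
#' @references Firth, D. (1993) Bias reduction of maximum likelihood
#'   estimates. Biometrika 80, 27-38.
#' @export
fit_firth_logistic <- function(design, y, tol = 1e-8, max_iter = 200L) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(design)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  p <- ncol(X)
  beta <- rep(0, p)
  state <- .firth_state(X, y, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(state$score)) < tol) { converged <- TRUE; break }
    delta <- solve(state$info, state$score)
    # accept any step that does not decrease the penalized log-likelihood
    # beyond floating-point resolution at its magnitude
    slack <- 1e-9 * (1 + abs(state$pll))
    step <- 1
    repeat {
      cand <- .firth_state(X, y, beta + step * delta)
      if (cand$pll >= state$pll - slack || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * delta
    state <- cand
  }
  if (!converged && max(abs(state$score)) < tol) converged <- TRUE
  if (!converged) {
    warning("Firth fit did not converge in ", max_iter,
            " iterations (max |modified score| = ",
            format(max(abs(state$score))), ")")
  }

  cov <- solve(state$info)
  cov <- (cov + t(cov)) / 2
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    covariance = cov,
    penalized_loglik = state$pll,
    n_iterations = iter,
    converged = converged,
    term_names = colnames(X),
    n = nrow(X)
  ), class = "firth_fit")
}

# Penalized log-likelihood, modified score and Fisher information at beta.
.firth_state <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pmax(pi * (1 - pi), .Machine$double.eps)
  XtWX <- crossprod(X * sqrt(w))
  ch <- chol(XtWX)
  # h_i = w_i * x_i' (X'WX)^{-1} x_i
  Xi <- backsolve(ch, t(X), transpose = TRUE)     # p x n
  h <- w * colSums(Xi^2)
  score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  pll <- ll + sum(log(diag(ch)))                  # + 0.5 log det(X'WX)
  list(pi = pi, w = w, info = XtWX, score = score, pll = pll, h = h)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth bias-reduced logistic regression\n")
  cat("  n =", x$n, " terms =", length(x$coefficients),
      " iterations =", x$n_iterations,
      " converged =", x$converged, "\n")
  cat("  penalized log-likelihood:", format(x$penalized_loglik), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
vcov.firth_fit <- function(object, ...) object$covariance

#' Formula interface to the Firth logistic fit
#'
#' Builds the design matrix with [stats::model.matrix()] (treatment coding,
#' alphabetically first level as reference) and calls
#' [fit_firth_logistic()]. The terms object and factor levels are stored so
#' that prediction grids use identical coding.
#'
#' @param formula Model formula with a 0/1 (or two-level factor) response.
#' @param data Data.frame holding the variables.
#' @inheritParams fit_firth_logistic
#' @return A `firth_fit` with additional fields `terms` and `xlevels`.
#' @export
fit_firth <- function(formula, data, tol = 1e-8, max_iter = 200L) {
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- fit_firth_logistic(X, y, tol = tol, max_iter = max_iter)
  fit$terms <- stats::delete.response(stats::terms(mf))
  fit$xlevels <- stats::.getXlevels(stats::terms(mf), mf)
  fit
}

#' Linear predictor of a Firth fit on new data
#' @param fit A `firth_fit` from [fit_firth()].
#' @param newdata Data.frame of covariates.
#' @return Numeric vector of linear predictors (log-odds).
#' @export
predict_eta <- function(fit, newdata) {
  if (is.null(fit$terms)) {
    stop("fit has no stored terms; use fit_firth() for prediction",
         call. = FALSE)
  }
  mf <- stats::model.frame(fit$terms, newdata, xlev = fit$xlevels)
  X <- stats::model.matrix(fit$terms, mf)
  if (!identical(colnames(X), fit$term_names)) {
    stop("prediction design does not match fit coding", call. = FALSE)
  }
  drop(X %*% fit$coefficients)
}

#' Merge two reference-category binomial fits into a probability triple
#'
#' The three-category body-condition model is assembled from two binomial
#' logistic fits against the shared reference category `ideal`
#' (underweight vs ideal; overweight/obese vs ideal). Treating the two
#' binomial linear predictors \eqn{\eta_U} and \eqn{\eta_O} as multinomial
#' logits gives
#' \deqn{p_{ideal} = 1/(1 + e^{\eta_U} + e^{\eta_O}),\quad
#'       p_{under} = e^{\eta_U} p_{ideal},\quad
#'       p_{over} = e^{\eta_O} p_{ideal},}
#' the unique multinomial whose conditional two-category models reproduce
#' each binomial fit.
#'
#' @param eta_under,eta_over Numeric vectors of linear predictors from the
#'   two fits (recycled to common length).
#' @return Matrix with columns `underweight`, `ideal`, `overweight_obese`;
#'   rows sum to 1.
#' @export
merge_binomials <- function(eta_under, eta_over) {
  n <- max(length(eta_under), length(eta_over))
  eta_u <- rep_len(eta_under, n)
  eta_o <- rep_len(eta_over, n)
  # stabilized softmax over logits (0, eta_u, eta_o)
  m <- pmax(0, eta_u, eta_o)
  d <- exp(-m) + exp(eta_u - m) + exp(eta_o - m)
  p_ideal <- exp(-m) / d
  p_under <- exp(eta_u - m) / d
  p_over <- exp(eta_o - m) / d
  cbind(underweight = p_under, ideal = p_ideal, overweight_obese = p_over)
}

#' Fit the three-category body condition model for breeds
#'
#' Fits the two Firth binomial regressions (underweight vs ideal,
#' overweight/obese vs ideal) on a one-record-per-dog table. The default
#' model uses terms Breed, Year of Age and Sex, optionally with Breed:Sex
#' and Breed:Age interactions; age enters as a numeric whole-year term by
#' default (a categorical option is provided).
#'
#' @param data Data.frame with columns `breed`, `sex`, `age_years` and
#'   `bcs_category` (a factor with levels `underweight`, `ideal`,
#'   `overweight_obese`, as from [merge_bcs_5pt()]).
#' @param interactions Include Breed:Sex and Breed:Age terms (default TRUE).
#' @param age_categorical Treat age as a factor rather than numeric
#'   (default FALSE).
#' @inheritParams fit_firth_logistic
#' @return Object of class `bcs_multinomial`: list with `fit_under`,
#'   `fit_over`, `breeds`, `data_age_distribution` (empirical whole-
#'   population age weights), and the call options.
#' @export
fit_bcs_multinomial <- function(data, interactions = TRUE,
                                age_categorical = FALSE,
                                tol = 1e-8, max_iter = 200L) {
  needed <- c("breed", "sex", "age_years", "bcs_category")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("input lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data$breed <- factor(as.character(data$breed))
  data$sex <- factor(as.character(data$sex))
  data$age <- if (age_categorical) factor(data$age_years) else data$age_years

  rhs <- if (interactions) {
    ~ breed + age + sex + breed:sex + breed:age
  } else {
    ~ breed + age + sex
  }

  fit_one <- function(level) {
    sub <- data[data$bcs_category %in% c(level, "ideal"), , drop = FALSE]
    sub$y <- as.integer(sub$bcs_category == level)
    fit_firth(stats::update(rhs, y ~ .), sub, tol = tol, max_iter = max_iter)
  }
  fit_under <- fit_one("underweight")
  fit_over <- fit_one("overweight_obese")

  age_tab <- table(data$age_years)
  age_dist <- stats::setNames(as.numeric(age_tab) / sum(age_tab),
                              names(age_tab))
  structure(list(
    fit_under = fit_under,
    fit_over = fit_over,
    breeds = levels(data$breed),
    sexes = levels(data$sex),
    data_age_distribution = age_dist,
    interactions = interactions,
    age_categorical = age_categorical
  ), class = "bcs_multinomial")
}

#' @export
print.bcs_multinomial <- function(x, ...) {
  cat("Merged three-category body condition model\n")
  cat("  breeds:", length(x$breeds), " terms per binomial:",
      length(x$fit_under$coefficients), "\n")
  cat("  underweight-vs-ideal fit converged:", x$fit_under$converged,
      "; overweight-vs-ideal:", x$fit_over$converged, "\n")
  invisible(x)
}

# Standardization grid (one row per breed x age x sex) and its weights
# (age weight x equal sex weight), plus the two design matrices.
.standardization_grid <- function(model, age_distribution, sex_ratio) {
  ages <- as.numeric(names(age_distribution))
  if (abs(sum(age_distribution) - 1) > 1e-8) {
    stop("age distribution weights must sum to 1", call. = FALSE)
  }
  grid <- expand.grid(breed = model$breeds, age_years = ages,
                      sex = model$sexes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTR = FALSE)
  grid$age <- if (model$age_categorical) factor(grid$age_years) else grid$age_years
  w_age <- as.numeric(age_distribution)[match(grid$age_years, ages)]
  w_sex <- sex_ratio[match(grid$sex, model$sexes)]
  list(grid = grid, weights = w_age * w_sex,
       X_under = .grid_design(model$fit_under, grid),
       X_over = .grid_design(model$fit_over, grid))
}

.grid_design <- function(fit, grid) {
  mf <- stats::model.frame(fit$terms, grid, xlev = fit$xlevels)
  stats::model.matrix(fit$terms, mf)
}

#' Covariate-standardized breed probabilities
#'
#' For each breed, the underweight / ideal / overweight-obese probability
#' triple is averaged over a fixed reference covariate distribution: the
#' whole-population age distribution (by default the empirical distribution
#' of the fitting data) and a 50:50 sex ratio. This makes breeds comparable
#' regardless of their observed age or sex composition.
#'
#' @param model A `bcs_multinomial` from [fit_bcs_multinomial()].
#' @param age_distribution Named numeric vector mapping age (years) to
#'   weight, summing to 1; default: empirical population distribution.
#' @param sex_ratio Length-2 weights over the sex levels (default 50:50).
#' @return Data.frame (`breed_probability_table`) with one row per breed and
#'   columns `breed`, `p_underweight`, `p_ideal`, `p_overweight_obese`.
#' @export
standardized_breed_probabilities <- function(model,
                                             age_distribution = NULL,
                                             sex_ratio = c(0.5, 0.5)) {
  if (is.null(age_distribution)) age_distribution <- model$data_age_distribution
  sg <- .standardization_grid(model, age_distribution, sex_ratio)
  p <- merge_binomials(drop(sg$X_under %*% model$fit_under$coefficients),
                       drop(sg$X_over %*% model$fit_over$coefficients))
  agg <- rowsum(p * sg$weights, group = sg$grid$breed)
  agg <- agg[model$breeds, , drop = FALSE]
  out <- data.frame(breed = model$breeds,
                    p_underweight = agg[, "underweight"],
                    p_ideal = agg[, "ideal"],
                    p_overweight_obese = agg[, "overweight_obese"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("breed_probability_table", "data.frame")
  out
}

#' Simulation confidence intervals for standardized breed probabilities
#'
#' Draws coefficient vectors from the multivariate normal implied by each
#' binomial fit (mean = estimates, covariance = inverse Fisher information),
#' independently for the two fits, recomputes the standardized probabilities
#' for every draw, and reports empirical quantile intervals.
#'
#' @inheritParams standardized_breed_probabilities
#' @param n_draws Number of coefficient draws (default 1000; fewer than 100
#'   triggers a warning).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed for the draws.
#' @return The [standardized_breed_probabilities()] table with added columns
#'   `ci_low_*` and `ci_high_*` per category and `n_draws`.
#' @export
simulate_confidence_intervals <- function(model, age_distribution = NULL,
                                          sex_ratio = c(0.5, 0.5),
                                          n_draws = 1000L, level = 0.95,
                                          seed = 1L) {
  if (n_draws < 100L) warning("fewer than 100 draws; intervals will be noisy")
  if (!model$fit_under$converged || !model$fit_over$converged) {
    stop("cannot simulate intervals from a non-converged fit", call. = FALSE)
  }
  if (is.null(age_distribution)) age_distribution <- model$data_age_distribution
  point <- standardized_breed_probabilities(model, age_distribution, sex_ratio)
  sg <- .standardization_grid(model, age_distribution, sex_ratio)

  draw_coefs <- function(fit, seed_offset) {
    ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      stop("fit covariance is not positive semi-definite", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed + seed_offset)
    MASS::mvrnorm(n_draws, mu = fit$coefficients, Sigma = fit$covariance)
  }
  B_under <- draw_coefs(model$fit_under, 0L)
  B_over <- draw_coefs(model$fit_over, 1L)

  eta_u <- sg$X_under %*% t(B_under)       # grid x draws
  eta_o <- sg$X_over %*% t(B_over)
  m <- pmax(0, eta_u, eta_o)
  d <- exp(-m) + exp(eta_u - m) + exp(eta_o - m)
  p_under <- exp(eta_u - m) / d
  p_ideal <- exp(-m) / d
  p_over <- exp(eta_o - m) / d

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  w <- sg$weights
  ci_for <- function(p_cat) {
    agg <- rowsum(p_cat * w, group = sg$grid$breed)[model$breeds, , drop = FALSE]
    t(apply(agg, 1L, stats::quantile, probs = probs, names = FALSE))
  }
  ci_u <- ci_for(p_under); ci_i <- ci_for(p_ideal); ci_o <- ci_for(p_over)
  point$ci_low_underweight <- ci_u[, 1]; point$ci_high_underweight <- ci_u[, 2]
  point$ci_low_ideal <- ci_i[, 1]; point$ci_high_ideal <- ci_i[, 2]
  point$ci_low_overweight_obese <- ci_o[, 1]
  point$ci_high_overweight_obese <- ci_o[, 2]
  point$n_draws <- n_draws
  point
}
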