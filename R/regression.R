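#' Ordinary least-squares fit with aliasing check
#'
#' Thin wrapper around [stats::lm()] that errors (rather than silently
#' dropping) when terms are collinear, and returns the summaries used
#' throughout the analysis: coefficients, multiple R-squared, AIC, n and
#' residual variance. Sex and neuter status are expected as 0/1 codings
#' (0 = female, 1 = male; 0 = entire, 1 = neutered) when they appear.
#'
#' @param formula Model formula.
#' @param data Data.frame holding the variables.
#' @return Object of class `linear_fit`: list with `term_names`,
#'   `coefficients`, `r_squared`, `aic`, `n`, `residual_variance`, `p_values`
#'   and the underlying `lm` object (`model`).
#' @export
fit_ols <- function(formula, data) {
  m <- stats::lm(formula, data = data)
  cf <- stats::coef(m)
  if (anyNA(cf)) {
    stop("aliased (collinear) term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  s <- summary(m)
  structure(list(
    term_names = names(cf),
    coefficients = cf,
    r_squared = s$r.squared,
    aic = stats::AIC(m),
    n = length(stats::residuals(m)),
    residual_variance = s$sigma^2,
    p_values = s$coefficients[, "Pr(>|t|)"],
    std_errors = s$coefficients[, "Std. Error"],
    model = m
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear model:", deparse(stats::formula(x$model)), "\n")
  cat(sprintf("  n = %d  R^2 = %.4f  AIC = %.2f\n", x$n, x$r_squared, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Stepwise AIC minimal model
#'
#' Backward stepwise elimination with [stats::step()] from a full model with
#' the stated two-way interactions, stopping at the local AIC minimum.
#' `step()` respects marginality: a main effect is never dropped while one
#' of its interactions remains.
#'
#' @param formula Full (initial) model formula including interactions.
#' @param data Data.frame holding the variables.
#' @param direction Passed to [stats::step()] (default `"backward"`).
#' @return A `linear_fit` of the selected minimal model.
#' @export
stepwise_aic <- function(formula, data, direction = "backward") {
  full <- stats::lm(formula, data = data)
  sel <- stats::step(full, direction = direction, trace = 0)
  fit_ols(stats::formula(sel), data)
}

#' Breed-adjusted food motivation score
#'
#' Removes the population-level effects of sex, neuter status and their
#' interaction from each dog's Food Motivation Score before breed averaging,
#' centering each covariate at its breed mean:
#' \deqn{FMS_{adj} = FMS - \beta_{sex}(sex_i - \bar{sex}_{breed})
#'   - \beta_{neuter}(neuter_i - \bar{neuter}_{breed})
#'   - \beta_{sex:neuter}(sex_i \cdot neuter_i -
#'     \overline{sex \cdot neuter}_{breed}),}
#' so that a dog at its breed's covariate means keeps its raw score and the
#' adjustment vanishes when all three coefficients are zero.
#'
#' @param data Data.frame with 0/1 `sex` and `neuter` columns, a `breed`
#'   column and the raw score column `fms_col`.
#' @param fit A `linear_fit` whose coefficients include `sex`, `neuter` and
#'   `sex:neuter`.
#' @param fms_col Name of the raw score column (default `"fms"`).
#' @return Numeric vector of adjusted scores, one per row of `data`.
#' @export
adjusted_fms <- function(data, fit, fms_col = "fms") {
  cf <- fit$coefficients
  pick <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else 0
  b_sex <- pick("sex"); b_neuter <- pick("neuter")
  b_int <- if ("sex:neuter" %in% names(cf)) unname(cf["sex:neuter"]) else pick("neuter:sex")
  sex <- as.numeric(data$sex); neuter <- as.numeric(data$neuter)
  int <- sex * neuter
  mean_by_breed <- function(v) stats::ave(v, data$breed, FUN = mean)
  data[[fms_col]] -
    b_sex * (sex - mean_by_breed(sex)) -
    b_neuter * (neuter - mean_by_breed(neuter)) -
    b_int * (int - mean_by_breed(int))
}

#' Owner-management effects by food-motivation tertile
#'
#' Fits the minimal interaction model for owner-reported body condition
#' \deqn{BCS \sim OI*tertile + RHF*tertile + EX*tertile + sex*tertile
#'   + neuter*tertile + sex*neuter + age,}
#' then refits it once per tertile with that tertile as the reference level,
#' so each management slope (and the sex/neuter effects) can be read off as
#' a main-effect coefficient for the corresponding group. The three refits
#' are reparameterizations of one model: fitted values, R-squared and AIC
#' are identical across runs.
#'
#' @param data Data.frame with columns `bcs_owner_9pt`,
#'   `owner_intervention`, `restriction_human_food`, `exercise_taken`,
#'   `sex`, `neuter`, `age_years` and a tertile factor column.
#' @param tertile_col Name of the tertile column (default `"fms_tertile"`).
#' @return List with `effects` (data.frame: `tertile`, `term`, `beta`,
#'   `std_error`, `p_value`), `r_squared`, `aic`, `n`.
#' @export
extract_tertile_effects <- function(data, tertile_col = "fms_tertile") {
  needed <- c("bcs_owner_9pt", "owner_intervention", "restriction_human_food",
              "exercise_taken", "sex", "neuter", "age_years", tertile_col)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("input lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tert <- factor(as.character(data[[tertile_col]]),
                 levels = c("low", "medium", "high"))
  if (any(table(tert) == 0L)) stop("empty tertile group", call. = FALSE)
  d <- data
  d$.tert <- tert
  base_formula <- bcs_owner_9pt ~ owner_intervention * .tert +
    restriction_human_food * .tert + exercise_taken * .tert +
    sex * .tert + neuter * .tert + sex * neuter + age_years

  terms_wanted <- c("owner_intervention", "restriction_human_food",
                    "exercise_taken", "sex", "neuter", "age_years")
  rows <- list(); fits <- list()
  for (ref in levels(tert)) {
    d$.tert <- stats::relevel(factor(d$.tert, ordered = FALSE), ref = ref)
    fit <- fit_ols(base_formula, d)
    fits[[ref]] <- fit
    s <- summary(fit$model)$coefficients
    for (tm in terms_wanted) {
      rows[[length(rows) + 1L]] <- data.frame(
        tertile = ref, term = tm,
        beta = unname(s[tm, "Estimate"]),
        std_error = unname(s[tm, "Std. Error"]),
        p_value = unname(s[tm, "Pr(>|t|)"]),
        stringsAsFactors = FALSE)
    }
  }
  fitted_vals <- lapply(fits, function(f) unname(stats::fitted(f$model)))
  max_dev <- max(abs(fitted_vals[[1]] - fitted_vals[[2]]),
                 abs(fitted_vals[[1]] - fitted_vals[[3]]))
  if (max_dev > 1e-6) {
    stop("releveled refits disagree; model is not a pure reparameterization",
         call. = FALSE)
  }
  list(effects = do.call(rbind, rows),
       r_squared = fits[[1]]$r_squared,
       aic = fits[[1]]$aic,
       n = fits[[1]]$n)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return List with `r`, `p` and `n` (complete pairs).
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' One-way analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (coerced).
#' @return List with `f`, `p`, `df_between`, `df_within`. Degenerate inputs
#'   with zero within-group variance but distinct group means return
#'   `f = Inf`, `p = 0` with a `degenerate = TRUE` flag.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  if (ss_within < .Machine$double.eps * max(1, ss_between)) {
    if (ss_between < .Machine$double.eps) {
      return(list(f = 0, p = 1, df_between = df_b, df_within = df_w,
                  degenerate = TRUE))
    }
    return(list(f = Inf, p = 0, df_between = df_b, df_within = df_w,
                degenerate = TRUE))
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w, degenerate = FALSE)
}

#' Pairwise t-tests with Holm correction
#'
#' Post-hoc comparisons of group means using pooled-variance pairwise
#' t-tests with Holm step-down adjustment of the p-values.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (coerced).
#' @param pool_sd Use the pooled standard deviation (default TRUE); set
#'   FALSE for Welch comparisons.
#' @return Lower-triangular matrix of Holm-adjusted p-values, as from
#'   [stats::pairwise.t.test()].
#' @export
pairwise_t_holm <- function(values, groups, pool_sd = TRUE) {
  groups <- factor(groups)
  res <- stats::pairwise.t.test(values, groups, p.adjust.method = "holm",
                                pool.sd = pool_sd)
  res$p.value
}

#' Compare fitted linear models by R-squared and AIC
#'
#' @param fits Named list of `linear_fit` objects; deltas are relative to
#'   the first model.
#' @return Data.frame with `model`, `n`, `r_squared`, `aic`,
#'   `delta_r_squared`, `delta_aic`.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model_", seq_along(fits))
  }
  out <- data.frame(
    model = names(fits),
    n = vapply(fits, function(f) f$n, integer(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE)
  out$delta_r_squared <- out$r_squared - out$r_squared[1]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param data Data.frame; `vars` selects the numeric columns.
#' @param vars Character vector of column names.
#' @return List of matrices `r` and `p` (pairwise complete observations).
#' @export
correlation_matrix <- function(data, vars) {
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- length(vars)
  r <- matrix(1, k, k, dimnames = list(vars, vars))
  p <- matrix(0, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- pearson_cor(data[[vars[i]]], data[[vars[j]]])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p
    }
  }
  list(r = r, p = p)
}

#' Group descriptives with Holm-adjusted pairwise comparisons
#'
#' Mean, SD and n of each variable by group, plus the one-way ANOVA and the
#' Holm-adjusted pooled-variance pairwise t-tests, as used to contrast
#' food-motivation tertile groups.
#'
#' @param data Data.frame with a grouping column and the variables.
#' @param group_col Name of the grouping column.
#' @param vars Character vector of variable names.
#' @return List keyed by variable: each entry has `descriptives`
#'   (group, n, mean, sd), `anova` and `pairwise_holm`.
#' @export
group_comparisons <- function(data, group_col, vars) {
  g <- factor(data[[group_col]])
  lapply(stats::setNames(vars, vars), function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    desc <- do.call(rbind, lapply(levels(g), function(lev) {
      xi <- x[ok & g == lev]
      data.frame(group = lev, n = length(xi), mean = mean(xi),
                 sd = stats::sd(xi), stringsAsFactors = FALSE)
    }))
    list(descriptives = desc,
         anova = one_way_anova(x[ok], g[ok]),
         pairwise_holm = pairwise_t_holm(x[ok], g[ok]))
  })
}
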