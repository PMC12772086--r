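#' Apply questionnaire cohort inclusion filters
#'
#' Retains dogs strictly older than `age_min` years, strictly younger than
#' `age_max` years, with a non-missing owner-reported body condition score
#' strictly above `bcs_min` (scores of 3 and below on the 9-point scale are
#' clinically underweight). The report itemizes exclusions per rule; a record
#' can fail several rules, so per-rule counts can sum to more than the number
#' of rows removed.
#'
#' @param scored Data.frame with columns `age_years` and `bcs_owner_9pt`.
#' @param age_min,age_max Exclusive age bounds in years (defaults 1 and 19).
#' @param bcs_min Exclusive lower bound on owner BCS (default 3, i.e. keep
#'   scores of 4 and above).
#'
#' @return A list with `data` (the retained rows) and `report`, a
#'   `filter_report` containing `n_input`, `n_retained` and
#'   `n_excluded_by_rule` (rules `age_too_low`, `age_too_high`,
#'   `bcs_missing`, `bcs_too_low`).
#' @export
apply_questionnaire_filters <- function(scored, age_min = 1, age_max = 19,
                                        bcs_min = 3) {
  needed <- c("age_years", "bcs_owner_9pt")
  missing <- setdiff(needed, names(scored))
  if (length(missing)) {
    stop("input lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  age <- scored$age_years
  bcs <- scored$bcs_owner_9pt
  fail <- cbind(
    age_too_low  = !is.na(age) & age <= age_min,
    age_too_high = !is.na(age) & age >= age_max,
    bcs_missing  = is.na(bcs),
    bcs_too_low  = !is.na(bcs) & bcs <= bcs_min
  )
  age_missing <- is.na(age)
  keep <- !age_missing & rowSums(fail) == 0
  report <- structure(list(
    n_input = nrow(scored),
    n_excluded_by_rule = c(colSums(fail), age_missing = sum(age_missing)),
    n_retained = sum(keep)
  ), class = "filter_report")
  list(data = scored[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Cohort filter report\n")
  cat("  rows in:      ", x$n_input, "\n")
  cat("  rows retained:", x$n_retained, "\n")
  for (rule in names(x$n_excluded_by_rule)) {
    cat(sprintf("  excluded by %-12s %d\n", paste0(rule, ":"),
                x$n_excluded_by_rule[[rule]]))
  }
  invisible(x)
}

#' Select one visit per dog at random
#'
#' Clinic records hold repeat visits; a single visit per dog is drawn
#' uniformly at random to avoid correlated residuals in downstream models.
#' Selection is reproducible given `seed` and invariant to the input row
#' order (rows are ordered by `dog_id` and `visit_id` before drawing).
#'
#' @param visits Data.frame with columns `dog_id` and `visit_id`.
#' @param seed Integer seed for the draw.
#' @return A data.frame with exactly one row per `dog_id`.
#' @export
select_random_visit <- function(visits, seed) {
  needed <- c("dog_id", "visit_id")
  missing <- setdiff(needed, names(visits))
  if (length(missing)) {
    stop("input lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(visits) == 0L) return(visits)
  ord <- order(visits$dog_id, visits$visit_id)
  visits <- visits[ord, , drop = FALSE]
  runs <- rle(as.character(visits$dog_id))
  counts <- runs$lengths
  u <- local_runif(length(counts), seed)
  pick_within <- pmin(floor(u * counts) + 1L, counts)
  first_row <- cumsum(c(1L, counts[-length(counts)]))
  out <- visits[first_row + pick_within - 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Uniform draws from a private RNG stream; leaves the caller's RNG state
# untouched.
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' Collapse the 5-point clinic body condition scale to three categories
#'
#' The 5-point scale scores dogs 1 (thin), 2 (underweight), 3 (ideal),
#' 4 (overweight), 5 (obese). The rarely used extremes are merged with their
#' neighbours for model stability: 1 and 2 become `underweight`, 3 stays
#' `ideal`, 4 and 5 become `overweight_obese`.
#'
#' @param bcs_5pt Integer vector with values in 1..5.
#' @return Factor with levels `underweight`, `ideal`, `overweight_obese`.
#' @export
merge_bcs_5pt <- function(bcs_5pt) {
  bad <- !is.na(bcs_5pt) & (!bcs_5pt %in% 1:5)
  if (any(bad)) {
    stop("BCS value(s) outside 1..5: ",
         paste(unique(bcs_5pt[bad]), collapse = ", "), call. = FALSE)
  }
  labels <- c("underweight", "underweight", "ideal",
              "overweight_obese", "overweight_obese")
  factor(labels[bcs_5pt],
         levels = c("underweight", "ideal", "overweight_obese"))
}

#' Assign food-motivation tertiles
#'
#' Splits a numeric vector into `low` / `medium` / `high` thirds by rank.
#' Ranks use a stable order on (value, position); records tied with the value
#' at a tertile boundary are placed in the lower tertile, so group sizes can
#' differ by at most the number of boundary ties.
#'
#' @param fms Numeric vector (missing values allowed; they get `NA` labels).
#' @return Ordered factor with levels `low < medium < high`.
#' @export
assign_tertiles <- function(fms) {
  ok <- which(!is.na(fms))
  n <- length(ok)
  if (n < 3L) stop("need at least 3 non-missing values", call. = FALSE)
  x <- fms[ok]
  if (length(unique(x)) == 1L) {
    warning("all values identical; assigning a single 'low' group")
    out <- rep(NA_character_, length(fms))
    out[ok] <- "low"
    return(factor(out, levels = c("low", "medium", "high"), ordered = TRUE))
  }
  ord <- order(x, seq_len(n))
  sizes <- diff(floor(seq(0, n, length.out = 4L)))
  grp <- rep(1:3, times = sizes)  # in sorted order
  # boundary ties fall to the lower tertile
  for (g in 1:2) {
    if (!any(grp == g)) next
    boundary_value <- x[ord[max(which(grp == g))]]
    tied_above <- which(grp == g + 1L & x[ord] == boundary_value)
    if (length(tied_above)) grp[tied_above] <- g
  }
  out <- rep(NA_character_, length(fms))
  out[ok[ord]] <- c("low", "medium", "high")[grp]
  factor(out, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Breed-level summary of a numeric column
#'
#' Mean and standard deviation per breed, restricted to breeds with more
#' than `min_n` dogs (strictly), since small-breed averages are unstable.
#'
#' @param data Data.frame with a `breed` column.
#' @param value_col Name of the numeric column to summarize.
#' @param min_n Strict minimum breed size (default 10: breeds need more than
#'   10 dogs).
#' @return Data.frame with columns `breed`, `n`, `mean_value`, `sd_value`,
#'   one row per retained breed, ordered by breed.
#' @export
breed_average <- function(data, value_col, min_n = 10) {
  if (!"breed" %in% names(data)) {
    stop("input lacks a `breed` column", call. = FALSE)
  }
  if (!value_col %in% names(data)) {
    stop("value column not found: ", value_col, call. = FALSE)
  }
  keep <- !is.na(data[[value_col]]) & !is.na(data$breed)
  data <- data[keep, , drop = FALSE]
  breeds <- sort(unique(as.character(data$breed)))
  out <- do.call(rbind, lapply(breeds, function(b) {
    v <- data[[value_col]][data$breed == b]
    data.frame(breed = b, n = length(v), mean_value = mean(v),
               sd_value = stats::sd(v), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(breed = character(), n = integer(),
                      mean_value = numeric(), sd_value = numeric()))
  }
  out <- out[out$n > min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}
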