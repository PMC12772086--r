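# Likert response labels and their published numeric scores. The 4-option
# scale uses the truncated decimals 0.6667/0.3333 as printed in the scoring
# protocol, so reversed scores are 0.3333/0.6667 rather than exact thirds.
.likert_maps <- list(
  `4` = c("definitely true" = 1, "mainly true" = 0.6667,
          "somewhat true" = 0.3333, "not at all true" = 0),
  `5` = c("always" = 1, "often" = 0.75, "sometimes" = 0.50,
          "rarely" = 0.25, "never" = 0)
)

#' Names of the six questionnaire factors
#'
#' Three dog-behaviour factors feed the Food Motivation Score and three
#' owner-management factors feed the Owner Control Score.
#'
#' @return Character vector of the six factor identifiers.
#' @export
factor_names <- function() {
  c("responsiveness_satiety", "lack_fussiness", "interest_in_food",
    "owner_intervention", "restriction_human_food", "exercise_taken")
}

#' Convert a Likert answer label to its numeric score
#'
#' Maps a verbal Likert response onto the unit interval using the published
#' scoring protocol: 4-option items score 1 / 0.6667 / 0.3333 / 0
#' ("definitely true" through "not at all true") and 5-option items score
#' 1 / 0.75 / 0.5 / 0.25 / 0 ("always" through "never"). For reverse-keyed
#' items the scores run in the opposite direction (reversed score is
#' `1 - score` at the printed precision).
#'
#' @param answer_label Character vector of response labels. Matching is
#'   case-insensitive after trimming whitespace. `NA` propagates as `NA`.
#' @param n_options Number of response options, 4 or 5.
#' @param reversed Logical; is this a reverse-keyed item?
#' @param item_id Optional item identifier used in error messages.
#'
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' map_likert("definitely true", 4)        # 1
#' map_likert("often", 5)                  # 0.75
#' map_likert("definitely true", 4, TRUE)  # 0
#' @export
map_likert <- function(answer_label, n_options, reversed = FALSE,
                       item_id = NULL) {
  if (!n_options %in% c(4L, 5L)) {
    stop("`n_options` must be 4 or 5, got ", n_options, call. = FALSE)
  }
  map <- .likert_maps[[as.character(n_options)]]
  key <- tolower(trimws(as.character(answer_label)))
  score <- unname(map[key])
  bad <- !is.na(key) & key != "" & is.na(score)
  if (any(bad)) {
    stop("unknown Likert label(s) ",
         paste(sprintf("'%s' (row %d)", answer_label[bad], which(bad)),
               collapse = ", "),
         if (!is.null(item_id)) paste0(" for item '", item_id, "'"),
         call. = FALSE)
  }
  if (reversed) score <- 1 - score
  score
}

#' Score one questionnaire factor
#'
#' A factor score is the sum of its item scores divided by the sum of the
#' item maxima (each item maximum is 1), i.e. the mean item score. Missing
#' answers are dropped from both numerator and denominator; a factor with no
#' answered items is unscoreable (`NA`).
#'
#' @param item_scores Numeric vector of item scores in `[0, 1]`, possibly
#'   containing `NA`.
#' @return A single value in `[0, 1]`, or `NA_real_` if all items are missing.
#' @examples
#' score_factor(c(1, 0.5, 0.25))  # 1.75 / 3
#' @export
score_factor <- function(item_scores) {
  if (length(item_scores) == 0L) {
    stop("cannot score a factor with no items", call. = FALSE)
  }
  answered <- item_scores[!is.na(item_scores)]
  if (length(answered) == 0L) return(NA_real_)
  sum(answered) / length(answered)
}

#' Food Motivation Score from its three factor scores
#'
#' Weighted composite of the dog-behaviour factors, weights equal to the
#' number of items per factor:
#' `(7 * responsiveness_satiety + 3 * lack_fussiness + 3 * interest_in_food) / 13`.
#'
#' @param rs Responsiveness-and-satiety factor score in `[0, 1]`.
#' @param lf Lack-of-fussiness factor score in `[0, 1]`.
#' @param intf Interest-in-food factor score in `[0, 1]`.
#' @return Food Motivation Score in `[0, 1]`; `NA` if any input is missing.
#' @export
compute_fms <- function(rs, lf, intf) {
  .check_unit(rs, "rs"); .check_unit(lf, "lf"); .check_unit(intf, "intf")
  (7 * rs + 3 * lf + 3 * intf) / 13
}

#' Owner Control Score from its three factor scores
#'
#' Weighted composite of the owner-management factors:
#' `(4 * owner_intervention + 4 * restriction_human_food + 5 * exercise_taken) / 13`.
#'
#' @param oi Owner-intervention factor score in `[0, 1]`.
#' @param rhf Restriction-of-human-food factor score in `[0, 1]`.
#' @param ex Exercise-taken factor score in `[0, 1]`.
#' @return Owner Control Score in `[0, 1]`; `NA` if any input is missing.
#' @export
compute_ocs <- function(oi, rhf, ex) {
  .check_unit(oi, "oi"); .check_unit(rhf, "rhf"); .check_unit(ex, "ex")
  (4 * oi + 4 * rhf + 5 * ex) / 13
}

.check_unit <- function(x, name) {
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Default item definitions
#'
#' The shipped item key: 13 dog-behaviour items (factors with 7/3/3 items,
#' 4-option truth-rated responses) and 13 owner-management items (factors
#' with 4/4/5 items, 5-option frequency-rated responses), with a small number
#' of reverse-keyed items. The published composites fix the factor structure
#' and weights; the per-item assignment is instrument-specific, so this
#' synthetic key can be replaced by a user-supplied YAML/JSON key with the
#' same columns (see [read_item_definitions()]).
#'
#' @return A data.frame with columns `item_id`, `column`, `factor`,
#'   `n_options`, `reversed`.
#' @export
default_item_definitions <- function() {
  ids <- sprintf("item_%02d", 1:26)
  fac <- c(rep("responsiveness_satiety", 7), rep("lack_fussiness", 3),
           rep("interest_in_food", 3), rep("owner_intervention", 4),
           rep("restriction_human_food", 4), rep("exercise_taken", 5))
  nopt <- c(rep(4L, 13), rep(5L, 13))
  rev <- ids %in% c("item_08", "item_20")
  data.frame(item_id = ids, column = ids, factor = fac,
             n_options = nopt, reversed = rev, stringsAsFactors = FALSE)
}

#' Read item definitions from a YAML or JSON key file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file containing a list of
#'   records with fields `item_id`, `column`, `factor`, `n_options`,
#'   `reversed`.
#' @return A validated item-definition data.frame (see
#'   [default_item_definitions()]).
#' @export
read_item_definitions <- function(path) {
  if (!file.exists(path)) stop("item key file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported item key format: .", ext, call. = FALSE))
  items <- do.call(rbind, lapply(raw, function(r) {
    data.frame(item_id = as.character(r$item_id),
               column = as.character(if (is.null(r$column)) r$item_id else r$column),
               factor = as.character(r$factor),
               n_options = as.integer(r$n_options),
               reversed = isTRUE(r$reversed),
               stringsAsFactors = FALSE)
  }))
  validate_item_definitions(items)
  items
}

#' @keywords internal
validate_item_definitions <- function(items) {
  needed <- c("item_id", "column", "factor", "n_options", "reversed")
  missing <- setdiff(needed, names(items))
  if (length(missing)) {
    stop("item definitions missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_fac <- setdiff(unique(items$factor), factor_names())
  if (length(bad_fac)) {
    stop("unknown factor(s) in item definitions: ",
         paste(bad_fac, collapse = ", "), call. = FALSE)
  }
  if (!all(items$n_options %in% c(4L, 5L))) {
    stop("`n_options` must be 4 or 5 for every item", call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("duplicated item_id in item definitions", call. = FALSE)
  }
  invisible(items)
}

#' Score a questionnaire cohort
#'
#' Maps every Likert answer column to its numeric score, computes the six
#' factor scores, and the Food Motivation and Owner Control composites.
#' Rows are never dropped: factors with more than half their items missing
#' are flagged (and scored over the answered items), factors with no answered
#' items are `NA`, and a composite is `NA` whenever any of its three factors
#' is `NA`.
#'
#' @param raw Data.frame with one row per dog/owner dyad, containing the
#'   answer columns named in `items$column` plus any covariate columns
#'   (passed through unchanged).
#' @param items Item definitions, as from [default_item_definitions()].
#'
#' @return The input covariate columns plus one column per factor score,
#'   `fms`, `ocs`, and `scoring_flags` (comma-separated factors with >50%
#'   missing items, `""` when clean).
#' @export
score_cohort <- function(raw, items = default_item_definitions()) {
  validate_item_definitions(items)
  missing_cols <- setdiff(items$column, names(raw))
  if (length(missing_cols)) {
    stop("answer column(s) absent from input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  covars <- raw[, setdiff(names(raw), items$column), drop = FALSE]
  n <- nrow(raw)

  item_scores <- matrix(NA_real_, nrow = n, ncol = nrow(items),
                        dimnames = list(NULL, items$item_id))
  for (j in seq_len(nrow(items))) {
    item_scores[, j] <- map_likert(raw[[items$column[j]]],
                                   items$n_options[j], items$reversed[j],
                                   item_id = items$item_id[j])
  }

  facs <- factor_names()
  fac_scores <- matrix(NA_real_, nrow = n, ncol = length(facs),
                       dimnames = list(NULL, facs))
  flagged <- matrix(FALSE, nrow = n, ncol = length(facs),
                    dimnames = list(NULL, facs))
  for (f in facs) {
    cols <- items$item_id[items$factor == f]
    sub <- item_scores[, cols, drop = FALSE]
    n_answered <- rowSums(!is.na(sub))
    fac_scores[, f] <- ifelse(n_answered > 0,
                              rowSums(sub, na.rm = TRUE) / pmax(n_answered, 1),
                              NA_real_)
    flagged[, f] <- n_answered < length(cols) / 2
  }

  out <- cbind(covars, as.data.frame(fac_scores))
  out$fms <- (7 * fac_scores[, "responsiveness_satiety"] +
              3 * fac_scores[, "lack_fussiness"] +
              3 * fac_scores[, "interest_in_food"]) / 13
  out$ocs <- (4 * fac_scores[, "owner_intervention"] +
              4 * fac_scores[, "restriction_human_food"] +
              5 * fac_scores[, "exercise_taken"]) / 13
  out$scoring_flags <- apply(flagged, 1L, function(fl) {
    paste(facs[fl], collapse = ",")
  })
  if (n == 0L) out$scoring_flags <- character(0)
  rownames(out) <- NULL
  out
}
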