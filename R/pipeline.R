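#' Read a delimited table with schema validation
#'
#' Reads CSV (`.csv`) or TSV (`.tsv`/`.txt`) with a header row, UTF-8, with
#' `""` and `"NA"` as missing-value tokens, and optionally checks a schema.
#'
#' @param path File path.
#' @param required_cols Character vector of column names that must be
#'   present; a typed error lists any that are missing.
#' @return A data.frame.
#' @export
read_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing)) {
      stop("file ", path, " lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write a table as CSV or TSV
#'
#' @param table Data.frame to write.
#' @param path Output path; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Configuration for the full analysis pipeline
#'
#' @param sim A [sim_config()] describing the synthetic cohorts (or `NULL`
#'   when `questionnaire_path`/`ehr_path` point at real tables).
#' @param questionnaire_path,ehr_path Optional paths to CSV/TSV inputs; when
#'   given they replace the corresponding synthetic arm.
#' @param items Item definitions (default [default_item_definitions()]).
#' @param min_breed_n Strict minimum breed size for breed averages
#'   (default 10).
#' @param n_draws Coefficient draws for the simulation confidence intervals
#'   (default 1000).
#' @param breed_interactions Include Breed:Sex and Breed:Age terms in the
#'   clinic model (default TRUE).
#' @param seed Root seed for visit selection and interval simulation.
#' @param output_dir Optional directory; when given, all report tables and a
#'   JSON manifest are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), questionnaire_path = NULL,
                            ehr_path = NULL,
                            items = default_item_definitions(),
                            min_breed_n = 10, n_draws = 1000L,
                            breed_interactions = TRUE,
                            seed = 1L, output_dir = NULL) {
  for (p in c(questionnaire_path, ehr_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(sim = sim, questionnaire_path = questionnaire_path,
                 ehr_path = ehr_path, items = items,
                 min_breed_n = min_breed_n, n_draws = n_draws,
                 breed_interactions = breed_interactions,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full behavioural-susceptibility analysis
#'
#' Orchestrates both arms end to end. Questionnaire arm: Likert scoring,
#' inclusion filters, the stepwise-AIC minimal model for food motivation,
#' breed-adjusted food motivation and its breed averages, one-way ANOVA
#' across breeds. Clinic arm: one random visit per dog, 5-point to
#' 3-category recoding, the merged Firth multinomial, standardized breed
#' probabilities with simulation confidence intervals. The arms join on
#' breed for the breed-level association between average food motivation
#' and overweight/obesity probability; individual-level correlations, the
#' tertile interaction model and tertile group comparisons complete the
#' report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `analysis_report` (see Details). When
#'   `config$output_dir` is set, report tables and `manifest.json` are also
#'   written there.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  seed <- config$seed

  # --- questionnaire arm -------------------------------------------------
  if (!is.null(config$questionnaire_path)) {
    qdata <- read_table(config$questionnaire_path,
                        required_cols = c("dog_id", "breed", "sex", "neuter",
                                          "age_years", "bcs_owner_9pt"))
    truth_q <- NULL
  } else {
    gen <- generate_questionnaire_cohort(config$sim)
    qdata <- gen$data
    truth_q <- gen$truth
  }
  scored <- score_cohort(qdata, config$items)
  filt <- apply_questionnaire_filters(scored)
  cohort <- filt$data

  fm_minimal <- stepwise_aic(
    fms ~ sex * neuter + sex * age_years + neuter * age_years, cohort)
  cohort$fms_adjusted <- adjusted_fms(cohort, fm_minimal)
  breed_fms <- breed_average(cohort, "fms_adjusted",
                             min_n = config$min_breed_n)
  breed_anova <- one_way_anova(
    cohort$fms_adjusted[cohort$breed %in% breed_fms$breed],
    cohort$breed[cohort$breed %in% breed_fms$breed])

  model_comparison <- compare_models(list(
    covariates_only = fit_ols(bcs_owner_9pt ~ sex * neuter +
                                neuter * age_years + sex * age_years, cohort),
    covariates_fms = fit_ols(bcs_owner_9pt ~ sex * neuter +
                               neuter * age_years + sex * age_years + fms,
                             cohort),
    covariates_breed = fit_ols(bcs_owner_9pt ~ sex * neuter +
                                 neuter * age_years + sex * age_years + breed,
                               cohort)))

  # --- clinic (EHR) arm --------------------------------------------------
  if (!is.null(config$ehr_path)) {
    visits <- read_table(config$ehr_path,
                         required_cols = c("visit_id", "dog_id", "breed",
                                           "sex", "age_years", "bcs_5pt"))
    truth_ehr <- NULL
  } else {
    gen <- generate_ehr_cohort(config$sim)
    visits <- gen$data
    truth_ehr <- gen$truth
  }
  records <- select_random_visit(visits, seed = seed)
  records$bcs_category <- merge_bcs_5pt(records$bcs_5pt)
  bcs_model <- fit_bcs_multinomial(records,
                                   interactions = config$breed_interactions)
  breed_probs <- simulate_confidence_intervals(bcs_model,
                                               n_draws = config$n_draws,
                                               seed = seed + 1L)

  # --- breed-level join (association of the two arms) --------------------
  joined <- merge(breed_fms[, c("breed", "n", "mean_value")],
                  breed_probs[, c("breed", "p_overweight_obese")],
                  by = "breed")
  unmatched <- setdiff(union(breed_fms$breed, breed_probs$breed),
                       joined$breed)
  if (nrow(joined) >= 3) {
    assoc_cor <- pearson_cor(joined$mean_value, joined$p_overweight_obese)
    assoc_lm <- fit_ols(p_overweight_obese ~ mean_value, joined)
  } else {
    assoc_cor <- list(r = NA_real_, p = NA_real_, n = nrow(joined))
    assoc_lm <- NULL
  }

  # --- individual-level associations and tertile models ------------------
  cors <- correlation_matrix(cohort,
                             c("bcs_owner_9pt", "fms", "ocs",
                               "owner_intervention", "restriction_human_food",
                               "exercise_taken"))
  cohort$fms_tertile <- assign_tertiles(cohort$fms)
  tertile_effects <- extract_tertile_effects(cohort)
  tertile_groups <- group_comparisons(
    cohort, "fms_tertile",
    c("bcs_owner_9pt", "fms", "age_years", "ocs", "owner_intervention",
      "restriction_human_food", "exercise_taken"))

  report <- structure(list(
    n_scored = nrow(scored),
    filter_report = filt$report,
    fm_minimal_model = fm_minimal,
    breed_fms = breed_fms,
    breed_anova = breed_anova,
    model_comparison = model_comparison,
    breed_probabilities = breed_probs,
    breed_association = list(r = assoc_cor$r, p = assoc_cor$p,
                             n_breeds = assoc_cor$n,
                             r_squared = if (!is.null(assoc_lm))
                               assoc_lm$r_squared else NA_real_,
                             unmatched_breeds = unmatched),
    correlations = cors,
    tertile_effects = tertile_effects,
    tertile_groups = tertile_groups,
    seed = seed,
    truth = list(questionnaire = truth_q, ehr = truth_ehr)
  ), class = "analysis_report")

  if (!is.null(config$output_dir)) {
    .write_report(report, config)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Behavioural-susceptibility analysis report\n")
  cat("  scored dyads:      ", x$n_scored, "\n")
  cat("  retained by filters:", x$filter_report$n_retained, "\n")
  cat("  breeds with averages:", nrow(x$breed_fms), "\n")
  cat("  breeds with clinic probabilities:", nrow(x$breed_probabilities), "\n")
  cat(sprintf("  breed-level association: r = %.3f (n = %d breeds, R^2 = %.3f)\n",
              x$breed_association$r, x$breed_association$n_breeds,
              x$breed_association$r_squared))
  invisible(x)
}

.write_report <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  write_table(report$breed_fms, out("breed_food_motivation.csv"))
  write_table(report$breed_probabilities, out("breed_probabilities.csv"))
  write_table(report$tertile_effects$effects, out("tertile_effects.csv"))
  write_table(report$model_comparison, out("model_comparison.csv"))
  write_table(as.data.frame(report$correlations$r), out("correlations_r.csv"))
  jsonlite::write_json(
    list(n_input = report$filter_report$n_input,
         n_retained = report$filter_report$n_retained,
         n_excluded_by_rule = as.list(report$filter_report$n_excluded_by_rule)),
    out("filter_report.json"), auto_unbox = TRUE, digits = NA)

  files <- c("breed_food_motivation.csv", "breed_probabilities.csv",
             "tertile_effects.csv", "model_comparison.csv",
             "correlations_r.csv", "filter_report.json")
  cfg_tmp <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_tmp))
  jsonlite::write_json(
    list(sim = unclass(config$sim), min_breed_n = config$min_breed_n,
         n_draws = config$n_draws, seed = config$seed,
         breed_interactions = config$breed_interactions),
    cfg_tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "caninefm",
    version = as.character(utils::packageVersion("caninefm")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    breed_association = report$breed_association[
      c("r", "p", "n_breeds", "r_squared")],
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(out(f)))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}
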