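#' Configuration for the synthetic cohort generator
#'
#' Bundles every generative parameter for the two synthetic tables: the
#' questionnaire cohort (one row per dog/owner dyad with 26 Likert answers
#' and an owner-reported 9-point body condition score) and the clinic (EHR)
#' cohort (repeat visits with a 5-point body condition score). Defaults
#' emulate the empirical structure of the study populations at desk scale:
#' 46 breeds shared between arms, breed-level variation in latent food
#' motivation, small sex/neuter/age effects on food motivation relative to
#' the breed signal, owner BCS driven by food motivation, owner control and
#' their interaction, and breed overweight propensity correlated 0.7 with
#' breed latent food motivation.
#'
#' @param n_dogs Questionnaire dyads (default 2000).
#' @param n_breeds Number of breeds, shared across both arms (default 46).
#' @param breed_fm_mean Grand mean of latent food motivation, unit scale
#'   (default 0.5).
#' @param breed_fm_sd SD of breed-level latent food motivation (default 0.08).
#' @param dog_fm_sd SD of dog-level latent noise around the breed mean
#'   (default 0.15).
#' @param beta_sex,beta_neuter,beta_age Main covariate effects on latent
#'   food motivation (defaults 0.02, 0.03, 0; sex 0 = female, 1 = male,
#'   neuter 0 = entire, 1 = neutered, age in years).
#' @param beta_sex_neuter,beta_sex_age,beta_neuter_age Two-way interaction
#'   effects on latent food motivation (defaults 0.02, 0.004, 0.004).
#' @param item_noise_sd SD of item-level latent noise (default 0.1).
#' @param likert_width Spacing of the Likert discretization thresholds
#'   (default 0.12); thresholds are placed so a latent at the construct's
#'   grand mean falls in the middle response category.
#' @param oc_mean,oc_sd Mean and SD of the latent owner-control construct
#'   (defaults 0.55, 0.12).
#' @param fm_oc_rho Latent correlation between food motivation and owner
#'   control (default 0.3; the instrument's published correlates are of this
#'   order and the joint distribution is otherwise unconstrained).
#' @param bcs_intercept,bcs_fm_slope,bcs_control_slope,bcs_interaction_slope
#'   Linear predictor of owner BCS on centred latent food motivation and
#'   owner control (defaults 5, 1.4, -1.4, -2; chosen so the measured
#'   composites reproduce correlations of the order reported for real
#'   dyads, about +0.19 with food motivation and -0.12 with owner control,
#'   and so owner management matters most for the most food-motivated dogs
#'   — the negative interaction makes the management slope on body
#'   condition steepest in the high-motivation tertile).
#' @param bcs_noise_sd SD of owner BCS noise before rounding (default 0.85).
#' @param bcs_missing_rate Fraction of missing owner BCS (default 0.02).
#' @param age_shape,age_rate Gamma parameters for questionnaire age in years
#'   (defaults 2.65, 0.49: mean ~5.4, SD ~3.3), clamped to [0.5, 21] so the
#'   age filters are exercised.
#' @param neuter_rate Probability of being neutered (default 0.68).
#' @param ehr_n_dogs Dogs in the EHR arm (default 9200, about 200 per breed).
#' @param ehr_age_range Whole-year age range of EHR visits (default c(1, 15)).
#' @param breed_n_min,breed_n_max Range of the log-uniform EHR breed-size
#'   weights (defaults 50, 400), mimicking heavy breed imbalance at reduced
#'   scale.
#' @param obesity_breed_corr Target correlation between breed latent food
#'   motivation and breed overweight propensity (default 0.7).
#' @param obesity_propensity_sd SD of breed overweight propensity on the
#'   log-odds scale (default 0.5).
#' @param ehr_under_intercept,ehr_over_intercept Baseline log-odds of
#'   underweight and overweight/obese vs ideal (defaults -1.9, -0.05).
#' @param ehr_age_under,ehr_age_over,ehr_sex_under,ehr_sex_over Additive
#'   age (per year, centred at the range midpoint) and sex (male vs female)
#'   effects on the two log-odds (defaults -0.02, 0.05, 0, 0.1).
#' @param ehr_visits_max Maximum visits per dog (default 4, uniform 1..max).
#' @param p_thin_given_under,p_obese_given_over Probability of the extreme
#'   5-point score within each merged category (defaults 0.25, 0.3).
#' @param seed Root integer seed; child streams are derived per table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_dogs = 2000L, n_breeds = 46L,
                       breed_fm_mean = 0.5, breed_fm_sd = 0.08,
                       dog_fm_sd = 0.15,
                       beta_sex = 0.02, beta_neuter = 0.03, beta_age = 0,
                       beta_sex_neuter = 0.02, beta_sex_age = 0.004,
                       beta_neuter_age = 0.004,
                       item_noise_sd = 0.1, likert_width = 0.12,
                       oc_mean = 0.55, oc_sd = 0.12, fm_oc_rho = 0.3,
                       bcs_intercept = 5, bcs_fm_slope = 1.4,
                       bcs_control_slope = -1.4,
                       bcs_interaction_slope = -2,
                       bcs_noise_sd = 0.85, bcs_missing_rate = 0.02,
                       age_shape = 2.65, age_rate = 0.49,
                       neuter_rate = 0.68,
                       ehr_n_dogs = 9200L, ehr_age_range = c(1L, 15L),
                       breed_n_min = 50, breed_n_max = 400,
                       obesity_breed_corr = 0.7,
                       obesity_propensity_sd = 0.5,
                       ehr_under_intercept = -1.9,
                       ehr_over_intercept = -0.05,
                       ehr_age_under = -0.02, ehr_age_over = 0.05,
                       ehr_sex_under = 0, ehr_sex_over = 0.1,
                       ehr_visits_max = 4L,
                       p_thin_given_under = 0.25,
                       p_obese_given_over = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid sim_config field `", field, "`: ", why,
                  call. = FALSE)
  }
  chk(cfg$n_dogs >= 0, "n_dogs", "must be >= 0")
  chk(cfg$n_breeds >= 1, "n_breeds", "must be >= 1")
  chk(cfg$ehr_n_dogs >= 0, "ehr_n_dogs", "must be >= 0")
  for (f in c("breed_fm_sd", "dog_fm_sd", "item_noise_sd", "oc_sd",
              "bcs_noise_sd", "obesity_propensity_sd")) {
    chk(cfg[[f]] >= 0, f, "must be >= 0")
  }
  chk(cfg$breed_fm_mean >= 0 && cfg$breed_fm_mean <= 1, "breed_fm_mean",
      "must lie in [0, 1]")
  chk(abs(cfg$fm_oc_rho) <= 1, "fm_oc_rho", "must lie in [-1, 1]")
  chk(abs(cfg$obesity_breed_corr) <= 1, "obesity_breed_corr",
      "must lie in [-1, 1]")
  chk(length(cfg$ehr_age_range) == 2 &&
      cfg$ehr_age_range[1] >= 1 && cfg$ehr_age_range[2] <= 15 &&
      cfg$ehr_age_range[1] <= cfg$ehr_age_range[2],
      "ehr_age_range", "must be within [1, 15] with low <= high")
  chk(cfg$breed_n_min > 0 && cfg$breed_n_max >= cfg$breed_n_min,
      "breed_n_max", "need 0 < breed_n_min <= breed_n_max")
  chk(cfg$bcs_missing_rate >= 0 && cfg$bcs_missing_rate < 1,
      "bcs_missing_rate", "must lie in [0, 1)")
  chk(cfg$ehr_visits_max >= 1, "ehr_visits_max", "must be >= 1")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

# Child seed for an independent stream; keeps results reproducible from one
# root seed while decoupling the tables.
.child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1009L + 7919L * stream
}

# Runs expr with a private RNG stream, restoring the caller's RNG state.
.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.child_seed(seed, stream))
  force(expr)
}

# Breed-level ground truth shared by both arms: latent food motivation,
# overweight propensity (log-odds offset, correlated with latent FM at the
# configured target), and size weights for both tables. All draws come from
# one breed-level stream so the questionnaire and EHR generators agree.
.breed_truth <- function(cfg) {
  .with_stream(cfg$seed, 1L, {
    breeds <- sprintf("breed_%02d", seq_len(cfg$n_breeds))
    z_fm <- stats::rnorm(cfg$n_breeds)
    e <- stats::rnorm(cfg$n_breeds)
    q_w <- exp(stats::runif(cfg$n_breeds, log(cfg$breed_n_min),
                            log(cfg$breed_n_max)))
    ehr_w <- exp(stats::runif(cfg$n_breeds, log(cfg$breed_n_min),
                              log(cfg$breed_n_max)))
    rho <- cfg$obesity_breed_corr
    z_prop <- rho * z_fm + sqrt(1 - rho^2) * e
    list(
      breeds = breeds,
      latent_fm = stats::setNames(cfg$breed_fm_mean + cfg$breed_fm_sd * z_fm,
                                  breeds),
      obesity_propensity = stats::setNames(
        cfg$ehr_over_intercept + cfg$obesity_propensity_sd * z_prop, breeds),
      q_weights = q_w / sum(q_w),
      ehr_weights = ehr_w / sum(ehr_w)
    )
  })
}

# Deterministic per-breed sizes proportional to weights, summing to n.
.apportion <- function(weights, n) {
  raw <- weights / sum(weights) * n
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

.likert_labels <- list(
  `4` = c("not at all true", "somewhat true", "mainly true",
          "definitely true"),   # ascending score order
  `5` = c("never", "rarely", "sometimes", "often", "always")
)

# Discretize item latents at fixed thresholds centred on the construct's
# grand mean; a latent exactly at the grand mean lands in the middle
# category (upper-middle for the even 4-option scale).
.likert_answer <- function(latent, n_options, reversed, grand, width) {
  cuts <- grand + width * (seq_len(n_options - 1L) - (n_options + 1L) / 2 + 0.5)
  cat_idx <- findInterval(latent, cuts) + 1L
  labels <- .likert_labels[[as.character(n_options)]]
  if (reversed) cat_idx <- n_options + 1L - cat_idx
  labels[cat_idx]
}

#' Generate a synthetic questionnaire cohort with known ground truth
#'
#' One row per dog/owner dyad: breed, sex, age, neuter status, 26 Likert
#' answers and an owner-reported 9-point body condition score. Each dog's
#' latent food motivation is its breed mean plus configured sex / neuter /
#' age effects (with two-way interactions) plus dog-level noise; Likert
#' answers arise by thresholding item latents; owner BCS is
#' `round(clamp(lp + noise, 1, 9))` with a linear predictor in latent food
#' motivation, latent owner control and their interaction. Ages deliberately
#' span [0.5, 21] years so downstream inclusion filters are exercised.
#'
#' @param config A [sim_config()].
#' @return List with `data` (the questionnaire table) and `truth`, a
#'   `sim_truth` holding breed-level latents and all generative
#'   coefficients.
#' @export
generate_questionnaire_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  bt <- .breed_truth(cfg)
  items <- default_item_definitions()
  n <- cfg$n_dogs

  out <- .with_stream(cfg$seed, 2L, {
    breed_idx <- if (n > 0) {
      sample.int(cfg$n_breeds, n, replace = TRUE, prob = bt$q_weights)
    } else integer(0)
    sex <- stats::rbinom(n, 1L, 0.5)
    neuter <- stats::rbinom(n, 1L, cfg$neuter_rate)
    age <- round(pmin(pmax(stats::rgamma(n, cfg$age_shape, cfg$age_rate),
                           0.5), 21), 1)
    dog_noise <- stats::rnorm(n, 0, cfg$dog_fm_sd)
    latent_fm <- bt$latent_fm[breed_idx] + cfg$beta_sex * sex +
      cfg$beta_neuter * neuter + cfg$beta_age * age +
      cfg$beta_sex_neuter * sex * neuter +
      cfg$beta_sex_age * sex * age +
      cfg$beta_neuter_age * neuter * age + dog_noise

    lat_sd <- sqrt(cfg$breed_fm_sd^2 + cfg$dog_fm_sd^2)
    z_fm <- if (lat_sd > 0) {
      (bt$latent_fm[breed_idx] - cfg$breed_fm_mean + dog_noise) / lat_sd
    } else rep(0, n)
    latent_oc <- cfg$oc_mean + cfg$oc_sd *
      (cfg$fm_oc_rho * z_fm +
       sqrt(1 - cfg$fm_oc_rho^2) * stats::rnorm(n))

    answers <- matrix(NA_character_, nrow = n, ncol = nrow(items),
                      dimnames = list(NULL, items$column))
    for (j in seq_len(nrow(items))) {
      dog_item <- items$factor[j] %in%
        c("responsiveness_satiety", "lack_fussiness", "interest_in_food")
      construct <- if (dog_item) latent_fm else latent_oc
      grand <- if (dog_item) cfg$breed_fm_mean else cfg$oc_mean
      intercept_j <- ((j - 1L) %% 5L - 2L) * 0.02
      item_latent <- construct + intercept_j +
        stats::rnorm(n, 0, cfg$item_noise_sd)
      answers[, j] <- .likert_answer(item_latent, items$n_options[j],
                                     items$reversed[j], grand,
                                     cfg$likert_width)
    }

    lp <- cfg$bcs_intercept +
      cfg$bcs_fm_slope * (latent_fm - cfg$breed_fm_mean) +
      cfg$bcs_control_slope * (latent_oc - cfg$oc_mean) +
      cfg$bcs_interaction_slope * (latent_fm - cfg$breed_fm_mean) *
        (latent_oc - cfg$oc_mean)
    bcs <- as.integer(round(pmin(pmax(lp + stats::rnorm(n, 0, cfg$bcs_noise_sd),
                                      1), 9)))
    if (cfg$bcs_missing_rate > 0 && n > 0) {
      bcs[stats::runif(n) < cfg$bcs_missing_rate] <- NA_integer_
    }

    df <- data.frame(
      dog_id = if (n > 0) sprintf("dog_%05d", seq_len(n)) else character(0),
      breed = bt$breeds[breed_idx],
      sex = sex, neuter = neuter, age_years = age,
      bcs_owner_9pt = bcs,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(answers, stringsAsFactors = FALSE))
    list(df = df, latent_fm = unname(latent_fm), latent_oc = latent_oc)
  })

  truth <- structure(list(
    breed_latent_fm = bt$latent_fm,
    breed_obesity_propensity = bt$obesity_propensity,
    dog_latent_fm = out$latent_fm,
    dog_latent_oc = out$latent_oc,
    coefficients = config[c("beta_sex", "beta_neuter", "beta_age",
                            "beta_sex_neuter", "beta_sex_age",
                            "beta_neuter_age", "bcs_intercept",
                            "bcs_fm_slope", "bcs_control_slope",
                            "bcs_interaction_slope")],
    config = unclass(config)
  ), class = "sim_truth")
  list(data = out$df, truth = truth)
}

#' Generate a synthetic clinic (EHR) cohort with known ground truth
#'
#' Visit-level table: `visit_id`, `dog_id`, `breed`, `sex`, `age_years`
#' (whole years), `bcs_5pt`. Each dog gets 1 to `ehr_visits_max` visits.
#' The three-category body condition outcome follows multinomial logits
#' against the ideal category: the overweight/obese log-odds carry a
#' breed-level propensity correlated with breed latent food motivation at
#' the configured target, plus additive age and sex effects; the 5-point
#' score then splits each merged category at the configured extreme-score
#' rates. Breed sizes are drawn log-uniform between `breed_n_min` and
#' `breed_n_max` to mimic heavy breed imbalance.
#'
#' @param config A [sim_config()].
#' @return List with `data` (the visit table) and `truth` (a `sim_truth`).
#' @export
generate_ehr_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  bt <- .breed_truth(cfg)
  n <- cfg$ehr_n_dogs
  age_mid <- mean(cfg$ehr_age_range)

  df <- .with_stream(cfg$seed, 3L, {
    sizes <- if (n > 0) .apportion(bt$ehr_weights, n) else integer(cfg$n_breeds)
    breed_idx <- rep(seq_len(cfg$n_breeds), times = sizes)
    n_eff <- length(breed_idx)
    sex <- stats::rbinom(n_eff, 1L, 0.5)
    ages <- cfg$ehr_age_range[1]:cfg$ehr_age_range[2]
    age <- if (length(ages) == 1L) rep(ages, n_eff) else
      sample(ages, n_eff, replace = TRUE)
    n_visits <- if (cfg$ehr_visits_max == 1L) rep(1L, n_eff) else
      sample.int(cfg$ehr_visits_max, n_eff, replace = TRUE)

    row_dog <- rep(seq_len(n_eff), times = n_visits)
    eta_u <- cfg$ehr_under_intercept +
      cfg$ehr_age_under * (age - age_mid) + cfg$ehr_sex_under * sex
    eta_o <- unname(bt$obesity_propensity[breed_idx]) +
      cfg$ehr_age_over * (age - age_mid) + cfg$ehr_sex_over * sex
    p <- merge_binomials(eta_u[row_dog], eta_o[row_dog])

    u <- stats::runif(length(row_dog))
    cat3 <- ifelse(u < p[, "underweight"], 1L,
            ifelse(u < p[, "underweight"] + p[, "ideal"], 2L, 3L))
    u2 <- stats::runif(length(row_dog))
    bcs5 <- integer(length(row_dog))
    bcs5[cat3 == 1L] <- ifelse(u2[cat3 == 1L] < cfg$p_thin_given_under, 1L, 2L)
    bcs5[cat3 == 2L] <- 3L
    bcs5[cat3 == 3L] <- ifelse(u2[cat3 == 3L] < cfg$p_obese_given_over, 5L, 4L)

    visit_seq <- sequence(n_visits)
    data.frame(
      visit_id = sprintf("visit_%06d_%d", row_dog, visit_seq),
      dog_id = sprintf("ehr_%06d", row_dog),
      breed = bt$breeds[breed_idx[row_dog]],
      sex = sex[row_dog],
      age_years = age[row_dog],
      bcs_5pt = bcs5,
      stringsAsFactors = FALSE)
  })

  truth <- structure(list(
    breed_latent_fm = bt$latent_fm,
    breed_obesity_propensity = bt$obesity_propensity,
    coefficients = list(
      ehr_under_intercept = cfg$ehr_under_intercept,
      ehr_age_under = cfg$ehr_age_under, ehr_age_over = cfg$ehr_age_over,
      ehr_sex_under = cfg$ehr_sex_under, ehr_sex_over = cfg$ehr_sex_over,
      age_center = age_mid),
    config = unclass(config)
  ), class = "sim_truth")
  list(data = df, truth = truth)
}

#' True three-category probabilities for given covariates
#'
#' Recomputes, from a `sim_truth`, the generative probability triple of any
#' EHR row (breed, whole-year age, 0/1 sex) — the quantity the fitted model
#' is trying to recover.
#'
#' @param truth A `sim_truth` from [generate_ehr_cohort()].
#' @param breed,age_years,sex Vectors of covariates (recycled).
#' @return Matrix with columns `underweight`, `ideal`, `overweight_obese`.
#' @export
ehr_row_probabilities <- function(truth, breed, age_years, sex) {
  co <- truth$coefficients
  eta_u <- co$ehr_under_intercept +
    co$ehr_age_under * (age_years - co$age_center) + co$ehr_sex_under * sex
  eta_o <- unname(truth$breed_obesity_propensity[as.character(breed)]) +
    co$ehr_age_over * (age_years - co$age_center) + co$ehr_sex_over * sex
  merge_binomials(eta_u, eta_o)
}

#' True standardized breed probabilities
#'
#' The generative analogue of [standardized_breed_probabilities()]: for each
#' breed, the true probability triple averaged over an age distribution and
#' a 50:50 sex ratio. Used to assess coverage of the simulation confidence
#' intervals.
#'
#' @param truth A `sim_truth` from [generate_ehr_cohort()].
#' @param age_distribution Named weight vector over whole-year ages; default
#'   uniform over the configured EHR age range.
#' @return Data.frame with `breed`, `p_underweight`, `p_ideal`,
#'   `p_overweight_obese`.
#' @export
true_standardized_probabilities <- function(truth, age_distribution = NULL) {
  cfg <- truth$config
  if (is.null(age_distribution)) {
    ages <- cfg$ehr_age_range[1]:cfg$ehr_age_range[2]
    age_distribution <- stats::setNames(rep(1 / length(ages), length(ages)),
                                        ages)
  }
  breeds <- names(truth$breed_obesity_propensity)
  grid <- expand.grid(breed = breeds,
                      age_years = as.numeric(names(age_distribution)),
                      sex = c(0, 1), stringsAsFactors = FALSE)
  w <- as.numeric(age_distribution)[match(grid$age_years,
                                          as.numeric(names(age_distribution)))] * 0.5
  p <- ehr_row_probabilities(truth, grid$breed, grid$age_years, grid$sex)
  agg <- rowsum(p * w, group = grid$breed)[breeds, , drop = FALSE]
  data.frame(breed = breeds,
             p_underweight = agg[, "underweight"],
             p_ideal = agg[, "ideal"],
             p_overweight_obese = agg[, "overweight_obese"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  payload <- list(
    breed_latent_fm = as.list(truth$breed_latent_fm),
    breed_obesity_propensity = as.list(truth$breed_obesity_propensity),
    coefficients = truth$coefficients,
    config = truth$config[!vapply(truth$config, is.function, logical(1))]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
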