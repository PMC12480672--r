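#' Specification of a synthetic longitudinal COPD cohort
#'
#' Defines the ground truth for a simulated cohort of participants observed
#' daily: z-scaled sensor features, a latent daily severity built from
#' planted fixed effects, feature-by-moderator interaction (moderation)
#' effects, per-participant random intercepts and demographic confounder
#' effects, and a symptom diary generated from that severity through
#' per-symptom logistic links (major symptoms get steeper links, so
#' high-score days concentrate at high severity).
#'
#' Feature and covariate names use the package's canonical snake-case
#' vocabulary (e.g. `abs_jitter`, `hrv_pnn20`, `pa_steps`); interaction
#' effects are named `"feature:moderator"`.
#'
#' @param n_participants number of participants (>= 2).
#' @param n_days days of follow-up per participant (>= 3).
#' @param features character vector of feature columns to draw (i.i.d.
#'   standard normal on the z-scale). Moderator covariates
#'   `hrv_mean_nn`, `hrv_sdnn`, `hrv_pnn20`, `pa_steps` are always included.
#' @param fixed_effects named numeric: coefficient of each feature on latent
#'   severity (per SD of the feature).
#' @param interaction_effects named numeric, names `"feature:moderator"`:
#'   coefficient of the product term on latent severity.
#' @param random_intercept_sd SD of the per-participant severity intercept.
#' @param confounder_effects named numeric with elements `age` (per scaled
#'   decade), `sex_female`, `smoking_ex`, `smoking_active`.
#' @param noise_sd SD of the i.i.d. daily severity noise.
#' @param missingness_rates named numeric in \[0, 1\]: per-day missing
#'   probability for streams `speech`, `hrv`, `steps`, `diary`
#'   (independent across streams).
#' @param exacerbation_threshold daily symptom score at or above which a day
#'   can count towards an exacerbation (default 6).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20, n_days = 100,
                        features = c("abs_jitter", "apq3_shimmer",
                                     "mean_f0", "mean_f2"),
                        fixed_effects = c(abs_jitter = -0.3),
                        interaction_effects = c("abs_jitter:hrv_pnn20" = -0.5),
                        random_intercept_sd = 0.5,
                        confounder_effects = c(age = 0.2, sex_female = -0.2,
                                               smoking_ex = 0.3,
                                               smoking_active = 0.6),
                        noise_sd = 1,
                        missingness_rates = c(speech = 0.25, hrv = 0.3,
                                              steps = 0.1, diary = 0.05),
                        exacerbation_threshold = 6,
                        seed = 1L) {
  stopifnot(n_participants >= 2, n_days >= 3,
            all(missingness_rates >= 0), all(missingness_rates <= 1),
            random_intercept_sd >= 0, noise_sd >= 0)
  covariates <- c("hrv_mean_nn", "hrv_sdnn", "hrv_pnn20", "pa_steps")
  all_cols <- union(features, covariates)
  if (length(fixed_effects) &&
      !all(names(fixed_effects) %in% all_cols)) {
    stop("fixed_effects name a feature not in the generated columns")
  }
  if (length(interaction_effects)) {
    parts <- strsplit(names(interaction_effects), ":", fixed = TRUE)
    stopifnot(all(vapply(parts, length, 1L) == 2L))
    if (!all(unlist(parts) %in% all_cols)) {
      stop("interaction_effects name a column not in the generated set")
    }
  }
  structure(list(n_participants = n_participants, n_days = n_days,
                 features = features, covariates = covariates,
                 fixed_effects = fixed_effects,
                 interaction_effects = interaction_effects,
                 random_intercept_sd = random_intercept_sd,
                 confounder_effects = confounder_effects,
                 noise_sd = noise_sd,
                 missingness_rates = missingness_rates,
                 exacerbation_threshold = exacerbation_threshold,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# logistic-link parameters for the eight diary symptoms: majors are rarer at
# baseline but respond more steeply to severity, so score >= 6 days
# concentrate at high severity
symptom_links <- function() {
  data.frame(
    symptom = c("sputum_color", "breathlessness", "sputum_amount",
                "cold", "fever", "wheezing", "sore_throat", "cough"),
    major = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    intercept = c(-3, -3, -3, -1.8, -2.5, -1.8, -2.2, -1.5),
    slope = c(1.3, 1.3, 1.3, 0.8, 0.8, 0.8, 0.8, 0.8))
}

#' Generate a synthetic cohort analysis table with known ground truth
#'
#' Draws one row per participant-day: z-scale sensor features and
#' physiological covariates, demographic confounders (ages uniform on
#' 55-93, one third female, smoking history never/ex/active at
#' 11.1/66.7/22.2 percent), a latent severity from the planted effect
#' structure, an eight-symptom diary from per-symptom logistic links on
#' severity, the resulting daily symptom score, and per-day exacerbation
#' flags. Per-stream missingness is applied independently day by day.
#'
#' @param spec a [cohort_spec()].
#' @return a long-format data frame (one participant-day per row) with
#'   attribute `ground_truth` recording every planted parameter and the
#'   realized random intercepts.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    np <- spec$n_participants; nd <- spec$n_days
    n <- np * nd
    participant <- factor(rep(sprintf("P%02d", seq_len(np)), each = nd))
    day <- rep(seq_len(nd), times = np)

    age <- rep(sample(55:93, np, replace = TRUE), each = nd)
    sex <- rep(sample(c("female", "male"), np, replace = TRUE,
                      prob = c(1 / 3, 2 / 3)), each = nd)
    smoking <- rep(sample(c("never", "ex", "active"), np, replace = TRUE,
                          prob = c(0.111, 0.667, 0.222)), each = nd)

    cols <- union(spec$features, spec$covariates)
    X <- matrix(stats::rnorm(n * length(cols)), nrow = n,
                dimnames = list(NULL, cols))

    sev <- numeric(n)
    for (f in names(spec$fixed_effects)) {
      sev <- sev + spec$fixed_effects[[f]] * X[, f]
    }
    for (nm in names(spec$interaction_effects)) {
      p <- strsplit(nm, ":", fixed = TRUE)[[1]]
      sev <- sev + spec$interaction_effects[[nm]] * X[, p[1]] * X[, p[2]]
    }
    b <- stats::rnorm(np, sd = spec$random_intercept_sd)
    sev <- sev + rep(b, each = nd)
    ce <- spec$confounder_effects
    sev <- sev +
      ce[["age"]] * (age - 74) / 11 +
      ce[["sex_female"]] * (sex == "female") +
      ce[["smoking_ex"]] * (smoking == "ex") +
      ce[["smoking_active"]] * (smoking == "active")
    sev <- sev + stats::rnorm(n, sd = spec$noise_sd)

    links <- symptom_links()
    flags <- matrix(NA, nrow = n, ncol = nrow(links),
                    dimnames = list(NULL, links$symptom))
    for (j in seq_len(nrow(links))) {
      p <- stats::plogis(links$intercept[j] + links$slope[j] * sev)
      flags[, j] <- stats::runif(n) < p
    }
    score <- daily_score_matrix(flags, links$major)
    if (all(score == 0) || all(score == max_symptom_score())) {
      stop("degenerate symptom score distribution (all zero or all maximal)")
    }

    df <- data.frame(participant = participant, day = day,
                     age = age, sex = sex, smoking = smoking,
                     as.data.frame(X), as.data.frame(flags),
                     daily_score = score, check.names = FALSE)

    mr <- spec$missingness_rates
    miss <- function(rate) stats::runif(n) < rate
    if (!is.na(mr["speech"]) && length(spec$features)) {
      df[miss(mr[["speech"]]), spec$features] <- NA
    }
    if (!is.na(mr["hrv"])) {
      df[miss(mr[["hrv"]]), c("hrv_mean_nn", "hrv_sdnn", "hrv_pnn20")] <- NA
    }
    if (!is.na(mr["steps"])) df[miss(mr[["steps"]]), "pa_steps"] <- NA
    if (!is.na(mr["diary"])) {
      gone <- miss(mr[["diary"]])
      df[gone, links$symptom] <- NA
      df[gone, "daily_score"] <- NA
    }

    # per-day exacerbation state from the scored diary, per participant
    df$exacerbation_day <- FALSE
    for (p in levels(participant)) {
      i <- which(df$participant == p)
      ex <- detect_exacerbations(df$day[i], df$daily_score[i],
                                 threshold = spec$exacerbation_threshold)
      df$exacerbation_day[i] <- ex$exacerbation_day
      df$exacerbation_episode[i] <- ex$episode_id
    }

    attr(df, "ground_truth") <- list(
      spec = spec, random_intercepts = stats::setNames(b, levels(participant)),
      symptom_links = links)
    df
  })
}
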