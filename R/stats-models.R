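#' @name stats_models
#' @title Two-step mixed-effects association and moderation analysis
#'
#' @description
#' The analysis links daily sensor features to COPD outcomes in two steps.
#' First a univariate screen: for every feature, a mixed-effects model
#' `outcome ~ feature + age + sex + smoking + (1 | participant)` — linear
#' for the daily symptom score, logistic for the per-day exacerbation state
#' (estimates reported as odds ratios). Second, the significant features
#' enter a multivariate model together with four physiological covariates
#' (HRV mean NN, HRV SDNN, HRV pNN20, daily steps) as moderators: all
#' feature-by-covariate two-way interactions plus
#' feature-by-HRV-by-steps three-way interactions, after iterative
#' variance-inflation-factor pruning (cutoff 20). Where a covariate
#' moderates several features, a stratified moderation analysis refits the
#' univariate model within four moderator intervals
#' (below Mean-SD, \[Mean-SD, Mean), \[Mean, Mean+SD), above Mean+SD).
#' Linear-model p-values use the Satterthwaite approximation (lmerTest);
#' confidence intervals are Wald at 95%; no multiple-testing correction is
#' applied by default (a Benjamini-Hochberg option exists).
NULL

#' z-score columns over the cohort
#'
#' Centred and scaled with the cohort (pooled) mean and sample SD; missing
#' entries are left untouched. A zero-variance column is an error naming
#' the column.
#'
#' @param table data frame.
#' @param columns character vector of numeric columns to standardise.
#' @return the table with the named columns standardised.
#' @export
zscore <- function(table, columns) {
  for (cl in columns) {
    x <- table[[cl]]
    stopifnot(is.numeric(x))
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero-variance column: ", cl)
    }
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Significance tier for a p-value
#'
#' @param p numeric p-values.
#' @return `"***"` for p < .001, `"**"` for p < .01, `"*"` for p < .05,
#'   otherwise `""`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

# product columns for interaction terms named "a:b" or "a:b:c"; returns the
# table with backtick-safe column names added
add_product_columns <- function(table, terms) {
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1L && is.null(table[[tm]])) {
      table[[tm]] <- Reduce(`*`, as.list(table[parts]))
    }
  }
  table
}

result_row <- function(term, est, se, p, scale, converged = TRUE,
                       n_obs = NA_integer_, stratum = NA_character_) {
  z <- stats::qnorm(0.975)
  lo <- est - z * se; hi <- est + z * se
  if (scale == "or") {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(term = term, estimate = est, ci_low = lo, ci_high = hi,
             p_value = p, stars = significance_stars(p), scale = scale,
             converged = converged, n_obs = n_obs, stratum = stratum,
             stringsAsFactors = FALSE)
}

# shared fitting core: returns one result row per requested term
fit_mixed <- function(table, terms, outcome, confounders = TRUE) {
  outcome <- match.arg(outcome, c("score", "exacerbation"))
  yvar <- if (outcome == "score") "daily_score" else "exacerbation_day"
  table <- add_product_columns(table, terms)
  use <- stats::complete.cases(table[c(yvar, terms, if (confounders)
    c("age", "sex", "smoking"), "participant")])
  dat <- table[use, , drop = FALSE]
  rhs <- paste(vapply(terms, function(t) paste0("`", t, "`"), ""),
               collapse = " + ")
  if (confounders) {
    # drop any confounder that is constant in the analysed rows (possible in
    # tiny cohorts); it carries no adjustment information there
    keep <- vapply(c("age", "sex", "smoking"), function(cc) {
      length(unique(dat[[cc]])) > 1L
    }, logical(1))
    cvars <- c("age", "sex", "smoking")[keep]
    if (length(cvars)) rhs <- paste(rhs, "+", paste(cvars, collapse = " + "))
  }
  fml <- stats::as.formula(paste(yvar, "~", rhs, "+ (1 | participant)"))
  conv <- TRUE
  fail_rows <- function() {
    do.call(rbind, lapply(terms, function(tm) {
      result_row(tm, NA_real_, NA_real_, NA_real_,
                 if (outcome == "score") "beta" else "or",
                 converged = FALSE, n_obs = nrow(dat))
    }))
  }
  if (outcome == "exacerbation" &&
      length(unique(dat[[yvar]])) < 2L) {
    return(fail_rows())
  }
  if (outcome == "score") {
    fit <- withCallingHandlers(
      lmerTest::lmer(fml, data = dat),
      warning = function(w) {
        conv <<- FALSE; invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    pcol <- "Pr(>|t|)"
    scale <- "beta"
  } else {
    fit <- tryCatch(
      withCallingHandlers(
        lme4::glmer(fml, data = dat, family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE)),
        warning = function(w) {
          conv <<- FALSE; invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) return(fail_rows())
    co <- summary(fit)$coefficients
    pcol <- "Pr(>|z|)"
    scale <- "or"
  }
  rows <- lapply(terms, function(tm) {
    rn <- paste0("`", tm, "`")
    key <- if (rn %in% rownames(co)) rn else tm
    if (!key %in% rownames(co)) {
      stop("rank-deficient model: term aliased and dropped: ", tm)
    }
    result_row(tm, co[key, "Estimate"], co[key, "Std. Error"],
               co[key, pcol], scale, converged = conv, n_obs = nrow(dat))
  })
  do.call(rbind, rows)
}

#' Univariate mixed-effects screen for one feature
#'
#' Fits `outcome ~ feature + age + sex + smoking + (1 | participant)`.
#' Linear link for the daily symptom score; logistic link for the per-day
#' exacerbation state, with the estimate exponentiated to an odds ratio.
#' Non-convergence is flagged in the result, never silently dropped.
#'
#' @param table analysis table (one participant-day per row).
#' @param feature feature column name.
#' @param outcome `"score"` or `"exacerbation"`.
#' @return one-row data frame: `term`, `estimate`, `ci_low`, `ci_high`
#'   (95% Wald), `p_value`, `stars`, `scale`, `converged`, `n_obs`.
#' @export
fit_univariate <- function(table, feature, outcome = c("score",
                                                       "exacerbation")) {
  fit_mixed(table, feature, match.arg(outcome))
}

#' Variance inflation factors of a term set
#'
#' VIF of term j is 1/(1 - R^2) from the linear regression of its column on
#' all other terms' columns (interaction product columns included as plain
#' columns).
#'
#' @param table data frame carrying the term columns.
#' @param terms character vector of term names (product columns are created
#'   on the fly for `"a:b"` names).
#' @return named numeric vector of VIFs.
#' @export
vif_values <- function(table, terms) {
  table <- add_product_columns(table, terms)
  X <- stats::na.omit(as.matrix(table[terms]))
  vapply(seq_along(terms), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(terms)
}

#' Iterative VIF pruning of a candidate term set
#'
#' Starting from the full set, repeatedly removes the term with the highest
#' VIF (at or above `cutoff`) and recomputes, until every retained term has
#' VIF below `cutoff`. Ties are broken deterministically by removing the
#' lexicographically last of the tied terms. Every removal is logged with
#' the VIF that triggered it.
#'
#' @param table data frame with the term columns.
#' @param terms candidate term names (>= 2).
#' @param cutoff VIF threshold (default 20).
#' @return list with `retained` (character), `removed` (data frame `term`,
#'   `vif`, `step`).
#' @export
vif_prune <- function(table, terms, cutoff = 20) {
  stopifnot(length(terms) >= 2)
  removed <- data.frame(term = character(0), vif = numeric(0),
                        step = integer(0))
  step <- 0L
  while (length(terms) >= 2L) {
    v <- vif_values(table, terms)
    if (max(v) < cutoff) break
    worst <- names(v)[v == max(v)]
    worst <- sort(worst)[length(worst)]   # lexicographically last of ties
    step <- step + 1L
    removed <- rbind(removed, data.frame(term = worst, vif = max(v),
                                         step = step))
    terms <- setdiff(terms, worst)
  }
  list(retained = terms, removed = removed)
}

#' Interaction term structure for the multivariate model
#'
#' Main effects for the features and the four physiological covariates;
#' two-way interactions of every feature with every covariate; three-way
#' interactions feature x HRV-metric x steps. With
#' `include_covariate_interactions = TRUE` (default) the HRV-by-steps
#' covariate two-way terms are also included, matching the published model's
#' term structure. Term names use the colon convention (`"a:b:c"`).
#'
#' @param features significant feature names.
#' @param covariates physiological covariate names (default the package's
#'   canonical four).
#' @return character vector of term names.
#' @export
build_interaction_design <- function(features,
                                     covariates = c("hrv_mean_nn",
                                                    "hrv_sdnn", "hrv_pnn20",
                                                    "pa_steps"),
                                     include_covariate_interactions = TRUE) {
  hrv <- setdiff(covariates, "pa_steps")
  terms <- c(features, covariates)
  if (include_covariate_interactions && "pa_steps" %in% covariates) {
    terms <- c(terms, paste0(hrv, ":pa_steps"))
  }
  for (f in features) {
    terms <- c(terms, paste0(f, ":", covariates))
    if ("pa_steps" %in% covariates) {
      terms <- c(terms, paste0(f, ":", hrv, ":pa_steps"))
    }
  }
  unique(terms)
}

#' Fit the multivariate interaction model
#'
#' One mixed model (linear or logistic as in [fit_univariate()]) containing
#' every term of the pruned design; one result row per term. Rank
#' deficiency is an error naming the aliased term.
#'
#' @param table analysis table.
#' @param terms term names (main effects and colon-named interactions).
#' @param outcome `"score"` or `"exacerbation"`.
#' @return data frame of result rows, one per term.
#' @export
fit_multivariate <- function(table, terms,
                             outcome = c("score", "exacerbation")) {
  fit_mixed(table, terms, match.arg(outcome))
}

moderation_strata_labels <- function() {
  c("< Mean - SD", "[Mean - SD, Mean)", "[Mean, Mean + SD)", "> Mean + SD")
}

#' Moderation analysis by stratified refits
#'
#' Splits the data into four intervals of the moderator — below Mean-SD,
#' \[Mean-SD, Mean), \[Mean, Mean+SD), above Mean+SD, boundaries from the
#' observed mean and SD — and refits the univariate model for the feature
#' within each stratum. Strata with too few rows or participants are
#' reported as empty rows (that is data, not an error).
#'
#' @param table analysis table.
#' @param feature feature whose slope is examined.
#' @param moderator moderating covariate (numeric, positive variance).
#' @param outcome `"score"` or `"exacerbation"`.
#' @param min_rows,min_participants occupancy required to fit a stratum.
#' @return data frame of four result rows with `stratum` labels; empty
#'   strata carry `NA` estimates.
#' @export
moderation_stratify <- function(table, feature, moderator,
                                outcome = c("score", "exacerbation"),
                                min_rows = 10, min_participants = 2) {
  outcome <- match.arg(outcome)
  m <- table[[moderator]]
  stopifnot(is.numeric(m), stats::sd(m, na.rm = TRUE) > 0)
  mu <- mean(m, na.rm = TRUE); s <- stats::sd(m, na.rm = TRUE)
  cuts <- list(function(x) x < mu - s,
               function(x) x >= mu - s & x < mu,
               function(x) x >= mu & x < mu + s,
               function(x) x > mu + s)
  labels <- moderation_strata_labels()
  yvar <- if (outcome == "score") "daily_score" else "exacerbation_day"
  rows <- lapply(seq_along(cuts), function(k) {
    in_stratum <- !is.na(m) & cuts[[k]](m)
    sub <- table[in_stratum, , drop = FALSE]
    ok <- sum(stats::complete.cases(sub[c(feature, yvar)]))
    npart <- length(unique(sub$participant[!is.na(sub[[feature]])]))
    if (ok < min_rows || npart < min_participants) {
      r <- result_row(feature, NA_real_, NA_real_, NA_real_,
                      if (outcome == "score") "beta" else "or",
                      converged = NA, n_obs = nrow(sub))
    } else {
      r <- fit_univariate(sub, feature, outcome)
    }
    r$stratum <- labels[k]
    r
  })
  do.call(rbind, rows)
}

display_names <- function() {
  c(hnr = "HNR", jitter = "jitter", absolute_jitter = "absolute jitter",
    rap_jitter = "rap jitter", ppq5_jitter = "ppq5 jitter",
    ddp_jitter = "ddp jitter", shimmer = "shimmer",
    apq3_shimmer = "apq3 shimmer", apq5_shimmer = "apq5 shimmer",
    apq11_shimmer = "apq11 shimmer", dda_shimmer = "dda shimmer",
    mean_f0 = "mean F0", std_f0 = "std F0", mean_f1 = "mean F1",
    mean_f2 = "mean F2", mean_f3 = "mean F3", mean_f4 = "mean F4",
    mean_formant = "mean formant", delta_f = "delta_f", fdisp = "fdisp",
    fitch_vtl = "fitch_vtl", mff = "mff", pf = "pF",
    vtl_delta_f = "vtl_delta_f", pause_rate = "pause rate",
    phonation_time = "phonation time", speech_rate = "speech rate",
    abs_jitter = "absolute jitter",
    hrv_mean_nn = "HRV(mean NN)", hrv_sdnn = "HRV(SDNN)",
    hrv_pnn20 = "HRV(pNN20)", pa_steps = "PA(steps)")
}

format_term <- function(term) {
  dn <- display_names()
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  paste(vapply(parts, function(p) {
    if (p %in% names(dn)) dn[[p]] else p
  }, ""), collapse = ":")
}

#' Render model results as report tables
#'
#' Formats estimates as `estimate [ci_low, ci_high]` with significance
#' stars (`* p<.05, ** p<.01, *** p<.001`), interaction rows in the colon
#' naming convention, odds-ratio rows already on the exponentiated scale.
#' Optionally Benjamini-Hochberg adjusts the p-values (off by default,
#' matching raw-star reporting).
#'
#' @param results data frame of result rows.
#' @param path optional CSV output path.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param digits display digits (default 2).
#' @return data frame with `variable` (display name), `report` (formatted
#'   string) and the raw columns; written to `path` when given.
#' @export
render_reports <- function(results, path = NULL, adjust = c("none", "BH"),
                           digits = 2) {
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  out <- cbind(
    variable = vapply(results$term, format_term, ""),
    report = ifelse(
      is.na(results$estimate), "(empty)",
      paste0(fmt(results$estimate), " [", fmt(results$ci_low), ", ",
             fmt(results$ci_high), "]", significance_stars(p))),
    results)
  rownames(out) <- NULL
  if (!is.null(path)) write_table_csv(out, path)
  out
}
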