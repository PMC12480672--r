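#' @name outcomes
#' @title Daily symptom scoring and exacerbation detection
#'
#' @description
#' The daily symptom questionnaire (London COPD cohort instrument) asks for
#' eight worse-than-usual flags. Three major symptoms — sputum-colour change,
#' increased breathlessness, increased sputum amount — score 5 points each;
#' the five minor symptoms — cold, fever, increased wheezing, sore throat,
#' worsening cough — score 1 point each (daily score 0-20). An exacerbation
#' is two or more consecutive calendar days with a daily score of 6 or above
#' (at least one major plus one minor symptom).
NULL

major_symptoms <- function() c("sputum_color", "breathlessness", "sputum_amount")
minor_symptoms <- function() c("cold", "fever", "wheezing", "sore_throat", "cough")
max_symptom_score <- function() 5L * 3L + 1L * 5L

# score a flag matrix (columns in symptom_links() order); NA row -> NA score
daily_score_matrix <- function(flags, major) {
  w <- ifelse(major, 5L, 1L)
  as.integer(flags %*% w)
}

#' Score one diary day
#'
#' @param flags named logical vector with the eight symptom flags
#'   (`sputum_color`, `breathlessness`, `sputum_amount`, `cold`, `fever`,
#'   `wheezing`, `sore_throat`, `cough`). A day with any missing flag gets a
#'   missing score (no imputation).
#' @return integer daily score in 0-20, or `NA`.
#' @export
daily_score <- function(flags) {
  need <- c(major_symptoms(), minor_symptoms())
  if (!all(need %in% names(flags))) {
    stop("diary day must carry all eight symptom flags")
  }
  flags <- flags[need]
  if (anyNA(flags)) return(NA_integer_)
  as.integer(5L * sum(flags[major_symptoms()]) + sum(flags[minor_symptoms()]))
}

#' Score a diary table (one row per day)
#'
#' @param diary data frame with the eight symptom flag columns.
#' @return integer vector of daily scores.
#' @export
score_diary <- function(diary) {
  need <- c(major_symptoms(), minor_symptoms())
  stopifnot(all(need %in% names(diary)))
  apply(diary[need], 1L, function(r) daily_score(as.logical(r) |>
                                                   stats::setNames(need)))
}

#' Detect exacerbation episodes from a daily score series
#'
#' Maximal runs of at least two consecutive calendar days with score at or
#' above `threshold` become episodes; every day in a run is flagged. A
#' missing day (gap in the calendar or missing score) breaks consecutiveness
#' — no carry-forward.
#'
#' @param days integer/date vector (calendar positions; consecutive means
#'   `diff == 1`).
#' @param scores numeric daily scores aligned with `days`.
#' @param threshold score threshold (default 6).
#' @param strict if `TRUE`, require score strictly above `threshold`
#'   (the inclusive rule is the default).
#' @param min_run_days minimum run length (default 2).
#' @return data frame with `day`, `exacerbation_day` (logical) and
#'   `episode_id` (integer, `NA` outside episodes).
#' @export
detect_exacerbations <- function(days, scores, threshold = 6,
                                 strict = FALSE, min_run_days = 2L) {
  stopifnot(length(days) == length(scores))
  o <- order(days)
  days <- as.numeric(days)[o]; scores <- scores[o]
  hot <- if (strict) scores > threshold else scores >= threshold
  hot[is.na(hot)] <- FALSE
  flag <- logical(length(days)); epi <- rep(NA_integer_, length(days))
  if (any(hot)) {
    # break runs at calendar gaps and wherever the hot status changes
    run_id <- cumsum(c(TRUE, diff(days) != 1 |
                         hot[-1] != hot[-length(hot)]))
    eid <- 0L
    for (r in split(seq_along(days), run_id)) {
      if (all(hot[r]) && length(r) >= min_run_days) {
        eid <- eid + 1L
        flag[r] <- TRUE
        epi[r] <- eid
      }
    }
  }
  data.frame(day = days, exacerbation_day = flag, episode_id = epi)
}
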