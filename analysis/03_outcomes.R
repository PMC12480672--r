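#!/usr/bin/env Rscript
# Score the simulated symptom diaries and label exacerbation episodes.
suppressPackageStartupMessages(library(copdvoice))

cohort <- utils::read.csv("results/simulated/cohort.csv")
out <- "results/outcomes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scores <- score_diary(cohort)
stopifnot(identical(is.na(scores), is.na(cohort$daily_score)))

episodes <- do.call(rbind, lapply(split(cohort, cohort$participant),
                                  function(d) {
  ex <- detect_exacerbations(d$day, d$daily_score)
  ex$participant <- d$participant[1]
  ex
}))
rownames(episodes) <- NULL
copdvoice:::write_table_csv(episodes, file.path(out, "exacerbation_days.csv"))

n_epi <- tapply(episodes$episode_id, episodes$participant,
                function(e) length(unique(stats::na.omit(e))))
message(sprintf(
  "%d/%d participants had >= 1 exacerbation; %.1f%% of days in episodes",
  sum(n_epi > 0), length(n_epi), 100 * mean(episodes$exacerbation_day)))
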