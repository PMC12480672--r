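#!/usr/bin/env Rscript
# Generate the synthetic inputs for the whole analysis: a cohort table with
# planted effects (the statistical ground truth), a handful of daily voice
# recordings, and a wearable heart-rate stream. Everything downstream reads
# from results/.
suppressPackageStartupMessages(library(copdvoice))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

# Cohort: 20 participants x 100 days, planted negative jitter effect on the
# latent severity and a negative jitter-by-pNN20 moderation (jitter hurts
# more when parasympathetic tone, proxied by pNN20, is low).
spec <- cohort_spec(seed = seed)
cohort <- gen_cohort(spec)
write_table_csv <- copdvoice:::write_table_csv
write_table_csv(cohort, file.path(out, "cohort.csv"))
jsonlite::write_json(
  list(seed = seed, spec = unclass(spec)),
  file.path(out, "cohort_ground_truth.json"), auto_unbox = TRUE, digits = NA,
  force = TRUE)
message(sprintf("cohort: %d rows, %.1f%% exacerbation days, median score %d",
                nrow(cohort), 100 * mean(cohort$exacerbation_day),
                stats::median(cohort$daily_score, na.rm = TRUE)))

# Three voice recordings (sustained phonation with pauses) for the audio
# feature chain, written as WAV so the file-based path is exercised too.
for (k in 1:3) {
  # voiced runs must exceed the 2-s analysis window to survive windowing
  vs <- voice_spec(duration_s = 5.3, f0_hz = 140 + 10 * k,
                   jitter_pct = c(0.5, 1, 2)[k],
                   shimmer_pct = c(2, 5, 10)[k],
                   syllable_pattern = list(c(2.5, 0.5), c(2.3, 0)),
                   seed = seed + k)
  v <- gen_voice(vs)
  write_wav(v$samples, v$sample_rate_hz,
            file.path(out, sprintf("voice_day%02d.wav", k)))
}
message("voices: 3 WAV files written")

# One day of 1-Hz heart rate with gaps.
hr <- gen_hr_stream(n_days = 1, seed = seed)
write_table_csv(hr$samples, file.path(out, "hr_stream.csv"))
message(sprintf("heart rate: %d samples over %d runs", nrow(hr$samples),
                length(hr$ground_truth$runs_by_day[[1]])))
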