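#!/usr/bin/env Rscript
# Run the audio segmentation cascade and speech-feature extraction on the
# simulated recordings, and the HRV chain on the simulated heart-rate
# stream. Reports how well the extracted features recover the planted
# ground truth.
suppressPackageStartupMessages(library(copdvoice))

inp <- "results/simulated"
out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- run_config()
write_table_csv <- copdvoice:::write_table_csv

wavs <- list.files(inp, pattern = "^voice_day.*\\.wav$", full.names = TRUE)
rows <- list()
for (w in wavs) {
  rec <- read_wav(w)
  pr <- process_recording(rec$samples, rec$sample_rate_hz, config = cfg)
  segs <- pr$segments
  message(sprintf("%s: %.1f s usable speech in %d segments", basename(w),
                  pr$speech_minutes * 60, nrow(segs)))
  feats <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    s0 <- round(segs$start[i] * rec$sample_rate_hz) + 1L
    s1 <- round(segs$end[i] * rec$sample_rate_hz)
    extract_segment_features(rec$samples[s0:s1], rec$sample_rate_hz, cfg)
  }))
  rows[[w]] <- daily_aggregate(feats, participant = "P01",
                               date = basename(w))
}
daily <- do.call(rbind, rows)
rownames(daily) <- NULL
write_table_csv(daily, file.path(out, "daily_speech_features.csv"))
message("planted jitter 0.5/1/2 %, extracted: ",
        paste(round(daily$jitter, 2), collapse = "/"))
message("planted shimmer 2/5/10 %, extracted: ",
        paste(round(daily$shimmer, 2), collapse = "/"))

hr <- utils::read.csv(file.path(inp, "hr_stream.csv"))
hrv <- daily_hrv(hr$t_s, hr$hr_bpm, min_segment_s = cfg$min_segment_s,
                 rr_lo = cfg$rr_min_ms, rr_hi = cfg$rr_max_ms)
write_table_csv(hrv, file.path(out, "daily_hrv.csv"))
message(sprintf("HRV day: mean NN %.1f ms, SDNN %.1f ms, pNN20 %.1f%%",
                hrv$mean_nn_ms, hrv$sdnn_ms, hrv$pnn20_pct))
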