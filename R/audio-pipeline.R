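#' @name audio_pipeline
#' @title Daily audio segmentation cascade
#'
#' @description
#' Raw free-living audio is reduced to usable speech in four stages:
#' (1) silence removal — a sliding 50-ms frame discards audio below an
#' overall intensity of -20 dB (dB re full scale, amplitude 1.0);
#' (2) the non-silent signal is split into 2-s windows with a 1-s step
#' (50% overlap); (3) a frame-level voice activity detector scores 20-ms
#' frames with a speech probability, binarised at 0.7, and consecutive
#' speech frames merge into utterances, with utterances shorter than 250 ms
#' discarded; (4) a window counts as speech when its combined utterance
#' duration exceeds 1.5 s (75% of the window, strict inequality). Daily
#' usable speech duration is the union of retained-window time intervals
#' (overlaps counted once). Frames and windows use half-open \[start, end)
#' intervals; trailing partial frames are dropped.
NULL

#' Remove silent stretches from a waveform
#'
#' Slides a `frame_s` window (non-overlapping frames, trailing remainder
#' dropped) and keeps maximal merged runs of frames whose RMS intensity is
#' at or above `intensity_threshold_db` (dB re full scale).
#'
#' @param samples numeric waveform in \[-1, 1\].
#' @param sample_rate_hz sampling rate, Hz.
#' @param frame_s analysis frame length, seconds (default 0.050).
#' @param intensity_threshold_db threshold in dBFS (default -20).
#' @return data frame of non-silent intervals `start_s`, `end_s` in the
#'   original recording's coordinates (possibly zero rows).
#' @export
remove_silence <- function(samples, sample_rate_hz, frame_s = 0.050,
                           intensity_threshold_db = -20) {
  if (length(samples) == 0L) stop("empty waveform")
  stopifnot(frame_s > 0)
  flen <- floor(frame_s * sample_rate_hz)
  n_frames <- length(samples) %/% flen
  if (n_frames == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  loud <- vapply(seq_len(n_frames), function(i) {
    fr <- samples[((i - 1L) * flen + 1L):(i * flen)]
    rms_db(fr) >= intensity_threshold_db
  }, logical(1))
  runs <- contiguous_runs(which(loud))
  if (!length(runs)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  data.frame(
    start_s = vapply(runs, function(r) (r[1] - 1L) * flen / sample_rate_hz, 1),
    end_s = vapply(runs, function(r) r[length(r)] * flen / sample_rate_hz, 1))
}

#' Tile non-silent intervals with overlapping analysis windows
#'
#' @param intervals data frame `start_s`, `end_s`, sorted and non-overlapping.
#' @param window_s window length, seconds (default 2).
#' @param step_s hop between window starts, seconds (default 1, i.e. 50%
#'   overlap). A trailing remainder shorter than `window_s` is dropped.
#' @return data frame of windows `start_s`, `end_s`, `interval` (index of
#'   the source interval).
#' @export
window_signal <- function(intervals, window_s = 2.0, step_s = 1.0) {
  stopifnot(all(diff(intervals$start_s) >= 0))
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    len <- intervals$end_s[i] - intervals$start_s[i]
    if (len < window_s) return(NULL)
    starts <- intervals$start_s[i] +
      seq(0, by = step_s, length.out = floor((len - window_s) / step_s) + 1)
    data.frame(start_s = starts, end_s = starts + window_s, interval = i)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      interval = integer(0)))
  }
  do.call(rbind, out)
}

#' Bundled deterministic frame scorer: energy plus periodicity
#'
#' A stand-in frame-level voice activity detector used for tests and the
#' synthetic pipeline: combines a logistic intensity score with the
#' normalised autocorrelation peak in the 100-400 Hz pitch range (the lag
#' range that fits inside a 20-ms frame). Quiet frames score near 0, loud
#' aperiodic frames below 0.5, and voiced frames near 1. A pretrained neural
#' detector can be plugged in through the same contract: a function taking
#' `(frame_samples, sample_rate_hz)` and returning a probability in \[0, 1\].
#'
#' @param frame numeric samples of one 20-ms frame.
#' @param sample_rate_hz sampling rate, Hz.
#' @return speech probability in \[0, 1\].
#' @export
energy_periodicity_vad <- function(frame, sample_rate_hz) {
  e <- stats::plogis((rms_db(frame) + 30) / 3)
  lag_min <- max(2L, floor(sample_rate_hz / 400))
  lag_max <- min(length(frame) - 1L, ceiling(sample_rate_hz / 100))
  r <- 0
  if (lag_max > lag_min && stats::var(frame) > 0) {
    ac <- stats::acf(frame, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    lags <- lag_min:lag_max
    # unbiased normalisation for the finite frame
    r <- max(0, ac[lags + 1L] * length(frame) / (length(frame) - lags))
  }
  unname(e * (0.25 + 0.75 * clip(r, 0, 1)))
}

#' Frame-level speech probabilities for one analysis window
#'
#' Splits the window into 20-ms frames (half-open, trailing partial frame
#' dropped; a 2-s window yields exactly 100 frames) and scores each with the
#' pluggable detector.
#'
#' @param samples window samples.
#' @param sample_rate_hz sampling rate, Hz.
#' @param detector frame scorer conforming to the contract of
#'   [energy_periodicity_vad()] (the default).
#' @param frame_s frame length, seconds (default 0.020).
#' @return numeric vector of per-frame probabilities.
#' @export
vad_probabilities <- function(samples, sample_rate_hz,
                              detector = energy_periodicity_vad,
                              frame_s = 0.020) {
  flen <- floor(frame_s * sample_rate_hz)
  n_frames <- length(samples) %/% flen
  p <- vapply(seq_len(n_frames), function(i) {
    detector(samples[((i - 1L) * flen + 1L):(i * flen)], sample_rate_hz)
  }, numeric(1))
  if (any(p < 0 | p > 1)) stop("detector produced probabilities outside [0, 1]")
  p
}

#' Merge above-threshold frames into utterance spans
#'
#' Consecutive frames with probability at or above `threshold` merge into
#' spans; spans shorter than `min_utterance_s` are discarded.
#'
#' @param probabilities per-frame speech probabilities.
#' @param frame_s frame length, seconds.
#' @param threshold binarisation threshold (default 0.7).
#' @param min_utterance_s minimum utterance duration, seconds (default 0.250).
#' @return data frame of spans `start_s`, `end_s`, `duration_s` (window-local
#'   coordinates), non-overlapping and sorted.
#' @export
frames_to_utterances <- function(probabilities, frame_s = 0.020,
                                 threshold = 0.7, min_utterance_s = 0.250) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  runs <- contiguous_runs(which(probabilities >= threshold))
  if (!length(runs)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  }
  out <- data.frame(
    start_s = vapply(runs, function(r) (r[1] - 1L) * frame_s, 1),
    end_s = vapply(runs, function(r) r[length(r)] * frame_s, 1))
  out$duration_s <- out$end_s - out$start_s
  out[out$duration_s >= min_utterance_s, , drop = FALSE]
}

#' Classify a window as speech or non-speech
#'
#' A window is speech when the combined utterance duration is strictly
#' greater than `coverage_fraction * window_s` (1.5 s for the default 2-s
#' window; exactly 1.5 s is non-speech).
#'
#' @param utterances data frame with `duration_s` (spans within the window).
#' @param window_s window length, seconds.
#' @param coverage_fraction required coverage (default 0.75).
#' @return `"speech"` or `"non-speech"`.
#' @export
classify_window <- function(utterances, window_s = 2.0,
                            coverage_fraction = 0.75) {
  total <- if (nrow(utterances)) sum(utterances$duration_s) else 0
  if (total > coverage_fraction * window_s) "speech" else "non-speech"
}

#' Daily usable speech duration from retained windows
#'
#' Overlapping retained windows (the 50% overlap of the windowing stage) are
#' unioned on the recording timeline so overlapped time counts once.
#'
#' @param windows data frame of retained windows with absolute `start_s`,
#'   `end_s`.
#' @return duration in minutes.
#' @export
daily_speech_duration <- function(windows) {
  union_intervals(windows$start_s, windows$end_s)$total / 60
}

#' Run the full segmentation cascade on one recording
#'
#' Chains silence removal, windowing, the voice activity detector, utterance
#' filtering and window classification. Utterance spans from overlapping
#' retained windows are unioned on the recording timeline into merged speech
#' segments — the units on which speech features are computed.
#'
#' @param samples waveform.
#' @param sample_rate_hz sampling rate, Hz.
#' @param detector pluggable frame scorer.
#' @param config pipeline thresholds, see [run_config()].
#' @return list: `intervals` (non-silent), `windows` (with `total_utterance_s`
#'   and `retained`), `segments` (merged utterance intervals, absolute
#'   coordinates), `speech_minutes`.
#' @export
process_recording <- function(samples, sample_rate_hz,
                              detector = energy_periodicity_vad,
                              config = run_config()) {
  iv <- remove_silence(samples, sample_rate_hz,
                       frame_s = config$silence_frame_s,
                       intensity_threshold_db = config$silence_db)
  win <- window_signal(iv, window_s = config$window_s, step_s = config$step_s)
  if (!nrow(win)) {
    return(list(intervals = iv, windows = cbind(win, total_utterance_s =
                                                  numeric(0),
                                                retained = logical(0)),
                segments = data.frame(start = numeric(0), end = numeric(0)),
                speech_minutes = 0))
  }
  spans_abs <- list()
  win$total_utterance_s <- NA_real_
  win$retained <- FALSE
  for (i in seq_len(nrow(win))) {
    s0 <- round(win$start_s[i] * sample_rate_hz) + 1L
    s1 <- round(win$end_s[i] * sample_rate_hz)
    p <- vad_probabilities(samples[s0:s1], sample_rate_hz, detector,
                           frame_s = config$vad_frame_s)
    utt <- frames_to_utterances(p, frame_s = config$vad_frame_s,
                                threshold = config$vad_threshold,
                                min_utterance_s = config$min_utterance_s)
    win$total_utterance_s[i] <- if (nrow(utt)) sum(utt$duration_s) else 0
    win$retained[i] <- classify_window(utt, window_s = config$window_s,
                                       coverage_fraction =
                                         config$coverage_fraction) == "speech"
    if (win$retained[i] && nrow(utt)) {
      spans_abs[[length(spans_abs) + 1L]] <-
        data.frame(start = utt$start_s + win$start_s[i],
                   end = utt$end_s + win$start_s[i])
    }
  }
  spans <- if (length(spans_abs)) do.call(rbind, spans_abs) else
    data.frame(start = numeric(0), end = numeric(0))
  merged <- union_intervals(spans$start, spans$end)$intervals
  list(intervals = iv, windows = win, segments = merged,
       speech_minutes = daily_speech_duration(win[win$retained, , drop = FALSE]))
}
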