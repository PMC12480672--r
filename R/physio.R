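#' @name physio
#' @title Heart-rate variability and activity from wearable streams
#'
#' @description
#' Daily HRV is derived from 1-Hz wearable heart rate: the stream is split
#' into contiguous runs (a gap longer than one sample period ends a run),
#' runs shorter than 45 s are dropped (preserving the 0.04-0.15 Hz
#' low-frequency HRV component requires at least that much context), heart
#' rate is converted to RR intervals through HR x RR = 60,000, RR values
#' outside the physiological 350-1200 ms band are removed, and three
#' time-domain metrics — mean NN, SDNN, pNN20 — are computed per run and
#' averaged (unweighted) across the day. Physical activity is the aggregate
#' daily step count.
NULL

#' Split a 1-Hz heart-rate stream into contiguous runs
#'
#' A new run starts wherever the inter-sample gap exceeds one sample period
#' plus a 0.5 s tolerance (i.e. `dt > 1.5 s`). Runs spanning less than
#' `min_segment_s` are dropped; a run of k 1-Hz samples is taken to span k
#' seconds (each sample covers one second).
#'
#' @param t_s numeric timestamps in seconds (sorted).
#' @param hr_bpm heart-rate samples aligned with `t_s`.
#' @param min_segment_s minimum retained run span, seconds (default 45).
#' @param gap_tolerance_s slack added to the 1-s nominal period (default 0.5).
#' @return list of data frames (`t_s`, `hr_bpm`), one per retained run.
#' @export
segment_hr <- function(t_s, hr_bpm, min_segment_s = 45, gap_tolerance_s = 0.5) {
  stopifnot(length(t_s) == length(hr_bpm))
  if (length(t_s) == 0L) return(list())
  o <- order(t_s)
  t_s <- t_s[o]; hr_bpm <- hr_bpm[o]
  run_id <- cumsum(c(TRUE, diff(t_s) > 1 + gap_tolerance_s))
  runs <- split(data.frame(t_s = t_s, hr_bpm = hr_bpm), run_id)
  keep <- vapply(runs, function(r) {
    (max(r$t_s) - min(r$t_s) + 1) >= min_segment_s
  }, logical(1))
  unname(runs[keep])
}

#' Convert heart rate to RR interval
#'
#' Uses the hyperbolic relation HR x RR = 60,000 (bpm times ms).
#'
#' @param hr_bpm positive heart rate in beats per minute.
#' @return RR interval in ms.
#' @export
hr_to_rr <- function(hr_bpm) {
  if (any(!is.finite(hr_bpm)) || any(hr_bpm <= 0)) {
    stop("heart rate must be positive and finite")
  }
  60000 / hr_bpm
}

#' Range-filter an RR sequence
#'
#' Removes physiologically impossible values; the bounds are inclusive, so
#' 350 ms and 1200 ms themselves are retained. Removal positions are
#' recorded: by default a removed sample breaks the successive-difference
#' (NN-pair) chain so that pNN20 never compares across a removed beat.
#'
#' @param rr_ms numeric RR intervals, ms.
#' @param lo,hi retention bounds in ms (default 350 and 1200).
#' @param bridge_removals if `TRUE`, successive differences may span removed
#'   samples; default `FALSE`.
#' @return numeric vector of retained values with logical attribute
#'   `pair_break`: `pair_break[i]` is `TRUE` when the pair (i, i+1) must not
#'   be used for successive differences.
#' @export
filter_rr <- function(rr_ms, lo = 350, hi = 1200, bridge_removals = FALSE) {
  keep <- !is.na(rr_ms) & rr_ms >= lo & rr_ms <= hi
  kept <- rr_ms[keep]
  n <- length(kept)
  pb <- logical(max(n - 1L, 0L))
  if (!bridge_removals && n > 1L) {
    pos <- which(keep)
    pb <- diff(pos) > 1L
  }
  attr(kept, "pair_break") <- pb
  kept
}

#' Daily time-domain HRV metrics from segmented RR data
#'
#' Per retained segment: mean NN; SDNN as the sample standard deviation
#' (n - 1 denominator); pNN20 as the percentage of successive NN pairs
#' differing by more than 20 ms, pairs never spanning segment boundaries or
#' removed beats. Daily values are unweighted means over segments.
#'
#' @param segments list of RR vectors (ms), each optionally carrying the
#'   `pair_break` attribute produced by [filter_rr()].
#' @param pnn_threshold_ms successive-difference threshold, ms (default 20).
#' @return one-row data frame `mean_nn_ms`, `sdnn_ms`, `pnn20_pct`,
#'   `n_segments`, or `NULL` when no segment has at least two intervals.
#' @export
hrv_metrics <- function(segments, pnn_threshold_ms = 20) {
  per_seg <- lapply(segments, function(rr) {
    if (length(rr) < 2L) return(NULL)
    pb <- attr(rr, "pair_break")
    if (is.null(pb)) pb <- logical(length(rr) - 1L)
    d <- abs(diff(rr))[!pb]
    data.frame(mean_nn_ms = mean(rr),
               sdnn_ms = stats::sd(rr),
               pnn20_pct = if (length(d)) {
                 100 * mean(d > pnn_threshold_ms)
               } else NA_real_)
  })
  per_seg <- per_seg[!vapply(per_seg, is.null, logical(1))]
  if (!length(per_seg)) return(NULL)
  all <- do.call(rbind, per_seg)
  data.frame(mean_nn_ms = mean(all$mean_nn_ms),
             sdnn_ms = mean(all$sdnn_ms),
             pnn20_pct = mean(all$pnn20_pct, na.rm = TRUE),
             n_segments = nrow(all))
}

#' Daily HRV from a raw 1-Hz heart-rate stream
#'
#' Convenience wrapper chaining [segment_hr()], [hr_to_rr()], [filter_rr()]
#' and [hrv_metrics()] for one day of samples.
#'
#' @inheritParams segment_hr
#' @param rr_lo,rr_hi RR retention bounds, ms.
#' @return as [hrv_metrics()].
#' @export
daily_hrv <- function(t_s, hr_bpm, min_segment_s = 45,
                      rr_lo = 350, rr_hi = 1200) {
  runs <- segment_hr(t_s, hr_bpm, min_segment_s = min_segment_s)
  segs <- lapply(runs, function(r) filter_rr(hr_to_rr(r$hr_bpm),
                                             lo = rr_lo, hi = rr_hi))
  hrv_metrics(segs)
}

#' Aggregate daily step counts
#'
#' Passthrough of the device's daily totals; multiple records on one date
#' are summed. Negative counts are rejected.
#'
#' @param date vector of dates (or day indices).
#' @param count numeric step counts.
#' @return data frame `date`, `steps`, one row per observed date.
#' @export
daily_steps <- function(date, count) {
  stopifnot(length(date) == length(count))
  if (any(count < 0, na.rm = TRUE)) stop("negative step counts")
  agg <- tapply(count, date, sum, na.rm = FALSE)
  data.frame(date = names(agg), steps = as.numeric(agg),
             stringsAsFactors = FALSE)
}
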