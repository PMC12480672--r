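#' @name speech_features
#' @title Phonation, prosodic and syllabic-nuclei speech features
#'
#' @description
#' Twenty-seven features per participant-day: eleven phonation features
#' (HNR plus the jitter and shimmer families), thirteen prosodic features
#' (F0 statistics, formants F1-F4 and their derived vocal-tract measures)
#' and three syllabic-nuclei features (pause rate, phonation time, speech
#' rate). Perturbation features follow the standard voice-analysis
#' definitions on consecutive glottal cycle periods T_i and cycle peak
#' amplitudes A_i; the exact formulas are frozen in the function
#' documentation so the implementation has one canonical definition.
NULL

speech_feature_names <- function() {
  c("hnr", "jitter", "absolute_jitter", "rap_jitter", "ppq5_jitter",
    "ddp_jitter", "shimmer", "apq3_shimmer", "apq5_shimmer",
    "apq11_shimmer", "dda_shimmer",
    "mean_f0", "std_f0", "mean_f1", "mean_f2", "mean_f3", "mean_f4",
    "mean_formant", "delta_f", "fdisp", "fitch_vtl", "mff", "pf",
    "vtl_delta_f",
    "pause_rate", "phonation_time", "speech_rate")
}

# frame-level F0 by normalised autocorrelation with parabolic interpolation;
# returns NA for unvoiced frames (peak below voicing_threshold)
frame_f0 <- function(frame, sample_rate_hz, f0_min = 60, f0_max = 400,
                     voicing_threshold = 0.45) {
  frame <- frame - mean(frame)
  if (stats::var(frame) <= 0) return(NA_real_)
  lag_max <- min(length(frame) - 2L, ceiling(sample_rate_hz / f0_min))
  lag_min <- max(2L, floor(sample_rate_hz / f0_max))
  if (lag_max <= lag_min) return(NA_real_)
  ac <- stats::acf(frame, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  seg <- ac[(lag_min + 1L):(lag_max + 1L)]
  r_best <- max(seg)
  if (!is.finite(r_best) || r_best < voicing_threshold) return(NA_real_)
  # octave guard: take the shortest-lag local maximum within a small margin
  # of the global peak, so a subharmonic at twice the period cannot win on a
  # hair's difference
  is_peak <- c(FALSE, diff(sign(diff(seg))) < 0, FALSE)
  cand <- which(is_peak & seg >= r_best - 0.07 & seg >= voicing_threshold)
  j <- if (length(cand)) cand[1] else which.max(seg)
  r <- seg[j]
  lag <- lag_min + j - 1L
  # refine the peak position on the locally bias-corrected autocorrelation:
  # the finite frame loses lag/N of the overlap, tilting the peak towards
  # longer lags, so undo the ramp around the raw peak before interpolating
  if (lag > lag_min && lag < lag_max) {
    n <- length(frame)
    y <- ac[lag:(lag + 2L)] * n / (n - (lag - 1L):(lag + 1L))
    den <- y[1] - 2 * y[2] + y[3]
    d <- if (abs(den) > 1e-12) 0.5 * (y[1] - y[3]) / den else 0
    if (abs(d) < 1) lag <- lag + d
  }
  sample_rate_hz / lag
}

#' Frame-wise F0 contour of a segment
#'
#' @param samples waveform of one speech segment.
#' @param sample_rate_hz sampling rate, Hz.
#' @param frame_s analysis frame, seconds.
#' @param hop_s hop between frames, seconds.
#' @param f0_min,f0_max F0 search range, Hz (adult range 60-400 by default).
#' @param voicing_threshold minimum normalised autocorrelation peak for a
#'   frame to count as voiced (default 0.45).
#' @return data frame `t_s`, `f0_hz` (`NA` when unvoiced), `voiced`.
#' @export
f0_contour <- function(samples, sample_rate_hz, frame_s = 0.040,
                       hop_s = 0.010, f0_min = 60, f0_max = 400,
                       voicing_threshold = 0.45) {
  flen <- floor(frame_s * sample_rate_hz)
  hop <- floor(hop_s * sample_rate_hz)
  starts <- seq(1L, length(samples) - flen + 1L, by = hop)
  if (length(samples) < flen) {
    return(data.frame(t_s = numeric(0), f0_hz = numeric(0),
                      voiced = logical(0)))
  }
  f0 <- vapply(starts, function(s) {
    frame_f0(samples[s:(s + flen - 1L)], sample_rate_hz, f0_min, f0_max,
             voicing_threshold)
  }, numeric(1))
  data.frame(t_s = (starts - 1L) / sample_rate_hz + frame_s / 2,
             f0_hz = f0, voiced = !is.na(f0))
}

#' Track glottal cycle periods and peak amplitudes
#'
#' A frame-based autocorrelation F0 estimate seeds cycle-by-cycle peak
#' picking on the rectified waveform: each successive cycle peak is located
#' in a window of 0.6-1.4 periods after the previous one, with parabolic
#' sub-sample refinement of the peak position. Aperiodic input (no frame
#' reaching the voicing threshold) yields an empty track.
#'
#' @inheritParams f0_contour
#' @return object of class `period_track`: list with `periods_ms`
#'   (consecutive cycle durations) and `amplitudes` (cycle peak heights);
#'   both empty for unvoiced input.
#' @export
track_periods <- function(samples, sample_rate_hz, f0_min = 60, f0_max = 400,
                          voicing_threshold = 0.45) {
  empty <- structure(list(periods_ms = numeric(0), amplitudes = numeric(0)),
                     class = "period_track")
  ctr <- f0_contour(samples, sample_rate_hz, f0_min = f0_min, f0_max = f0_max,
                    voicing_threshold = voicing_threshold)
  if (!any(ctr$voiced)) return(empty)
  per0 <- sample_rate_hz / stats::median(ctr$f0_hz, na.rm = TRUE)  # samples
  ax <- abs(samples)
  i0 <- which.max(ax[seq_len(min(length(ax), round(2 * per0)))])
  peaks_t <- numeric(0); peaks_a <- numeric(0)
  t <- i0
  repeat {
    lo <- t + round(0.6 * per0); hi <- t + round(1.4 * per0)
    if (hi > length(ax)) break
    j <- lo + which.max(ax[lo:hi]) - 1L
    d <- 0
    if (j > 1L && j < length(ax)) {
      y1 <- ax[j - 1L]; y2 <- ax[j]; y3 <- ax[j + 1L]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) {
        d <- 0.5 * (y1 - y3) / den
        if (abs(d) >= 1) d <- 0
      }
    }
    peaks_t <- c(peaks_t, j + d); peaks_a <- c(peaks_a, ax[j])
    per0 <- j - t  # adapt to local period
    t <- j
  }
  if (length(peaks_t) < 2L) return(empty)
  structure(list(periods_ms = diff(peaks_t) / sample_rate_hz * 1000,
                 amplitudes = peaks_a[-1]),
            class = "period_track")
}

#' Jitter family: frequency perturbation measures
#'
#' On consecutive periods T_1..T_n:
#' local jitter = mean|T_i - T_(i-1)| / mean(T) (in %);
#' absolute jitter = mean|T_i - T_(i-1)| in ms;
#' rap = mean_i |T_i - (T_(i-1)+T_i+T_(i+1))/3| / mean(T) (%);
#' ppq5 = the five-point analogue (%);
#' ddp = mean|(T_(i+1)-T_i) - (T_i-T_(i-1))| / mean(T) (%), identically
#' 3 x rap.
#'
#' @param track a `period_track` (or list with `periods_ms`).
#' @return named list `jitter`, `absolute_jitter`, `rap_jitter`,
#'   `ppq5_jitter`, `ddp_jitter`; `NA` entries when the track is too short
#'   (n >= 3, ppq5 needs n >= 5).
#' @export
jitter_features <- function(track) {
  T <- track$periods_ms
  n <- length(T)
  out <- list(jitter = NA_real_, absolute_jitter = NA_real_,
              rap_jitter = NA_real_, ppq5_jitter = NA_real_,
              ddp_jitter = NA_real_)
  if (n < 3L) return(out)
  mT <- mean(T)
  out$absolute_jitter <- mean(abs(diff(T)))
  out$jitter <- 100 * out$absolute_jitter / mT
  i <- 2:(n - 1)
  mov3 <- (T[i - 1] + T[i] + T[i + 1]) / 3
  out$rap_jitter <- 100 * mean(abs(T[i] - mov3)) / mT
  out$ddp_jitter <- 100 * mean(abs(diff(diff(T)))) / mT
  if (n >= 5L) {
    i <- 3:(n - 2)
    mov5 <- (T[i - 2] + T[i - 1] + T[i] + T[i + 1] + T[i + 2]) / 5
    out$ppq5_jitter <- 100 * mean(abs(T[i] - mov5)) / mT
  }
  out
}

#' Shimmer family: amplitude perturbation measures
#'
#' Amplitude analogues of the jitter formulas on cycle peak amplitudes
#' A_1..A_n: local shimmer = mean|A_i - A_(i-1)| / mean(A) (%); apq3/apq5/
#' apq11 compare each amplitude to its 3/5/11-point local average; dda is
#' identically 3 x apq3.
#'
#' @param track a `period_track` (or list with `amplitudes`).
#' @return named list `shimmer`, `apq3_shimmer`, `apq5_shimmer`,
#'   `apq11_shimmer`, `dda_shimmer`; `NA` when too short (n >= 3; apq5
#'   needs n >= 5, apq11 needs n >= 11).
#' @export
shimmer_features <- function(track) {
  A <- track$amplitudes
  n <- length(A)
  out <- list(shimmer = NA_real_, apq3_shimmer = NA_real_,
              apq5_shimmer = NA_real_, apq11_shimmer = NA_real_,
              dda_shimmer = NA_real_)
  if (n < 3L) return(out)
  mA <- mean(A)
  out$shimmer <- 100 * mean(abs(diff(A))) / mA
  apq <- function(k) {
    h <- (k - 1L) %/% 2L
    i <- (1L + h):(n - h)
    mov <- vapply(i, function(j) mean(A[(j - h):(j + h)]), numeric(1))
    100 * mean(abs(A[i] - mov)) / mA
  }
  out$apq3_shimmer <- apq(3L)
  out$dda_shimmer <- 3 * out$apq3_shimmer
  if (n >= 5L) out$apq5_shimmer <- apq(5L)
  if (n >= 11L) out$apq11_shimmer <- apq(11L)
  out
}

#' Harmonics-to-noise ratio of a voiced segment
#'
#' HNR = 10 log10(r / (1 - r)) with r the normalised autocorrelation peak at
#' the detected pitch period, capped at `cap_db` for near-perfect
#' periodicity. Unvoiced input (peak below the voicing threshold) yields
#' `NA`.
#'
#' @inheritParams f0_contour
#' @param cap_db ceiling, dB (default 60).
#' @return HNR in dB, or `NA`.
#' @export
hnr <- function(samples, sample_rate_hz, f0_min = 60, f0_max = 400,
                voicing_threshold = 0.45, cap_db = 60,
                frame_s = 0.040, hop_s = 0.010) {
  flen <- floor(frame_s * sample_rate_hz)
  hop <- floor(hop_s * sample_rate_hz)
  if (length(samples) < flen) return(NA_real_)
  starts <- seq(1L, length(samples) - flen + 1L, by = hop)
  lag_max <- min(flen - 2L, ceiling(sample_rate_hz / f0_min))
  lag_min <- max(2L, floor(sample_rate_hz / f0_max))
  rs <- vapply(starts, function(s) {
    fr <- samples[s:(s + flen - 1L)]
    fr <- fr - mean(fr)
    if (stats::var(fr) <= 0) return(NA_real_)
    ac <- stats::acf(fr, lag.max = lag_max, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    # unbiased normalisation: the finite window loses lag/N of the overlap
    lags <- lag_min:lag_max
    r <- ac[lags + 1L] * flen / (flen - lags)
    max(r)
  }, numeric(1))
  rs <- rs[!is.na(rs) & rs >= voicing_threshold]
  if (!length(rs)) return(NA_real_)
  r <- clip(mean(rs), 0, 1 - 1e-12)
  min(10 * log10(r / (1 - r)), cap_db)
}

#' Daily F0 statistics
#'
#' Mean and standard deviation over all voiced-frame F0 estimates of a day.
#'
#' @param f0_values numeric F0 estimates pooled over the day's segments.
#' @return list `mean_f0`, `std_f0` (both `NA` when no voiced frames; SD is
#'   0 for a single voiced frame).
#' @export
f0_stats <- function(f0_values) {
  v <- f0_values[!is.na(f0_values)]
  if (!length(v)) return(list(mean_f0 = NA_real_, std_f0 = NA_real_))
  list(mean_f0 = mean(v), std_f0 = if (length(v) > 1) stats::sd(v) else 0)
}

#' Estimate the first four formant frequencies by linear prediction
#'
#' The segment is decimated to roughly an 11 kHz rate (anti-alias low-pass
#' then downsample), so the linear-prediction model spends its poles on the
#' formant band instead of the empty top octave of wide-band recordings.
#' LPC coefficients come from the Levinson-Durbin recursion on the whole
#' segment's autocovariance; complex roots of the prediction polynomial
#' with bandwidth below `bw_max_hz` are formant candidates and the four
#' lowest in-band frequencies are returned. Unvoiced input (no voiced
#' frame in the segment) yields missing values. The analysis configuration
#' is recorded as an attribute.
#'
#' @param samples voiced segment.
#' @param sample_rate_hz sampling rate, Hz.
#' @param order LPC order at the decimated rate (default 14: four
#'   resonances plus slack for the noise floor).
#' @param target_rate_hz analysis rate the signal is decimated towards.
#' @param bw_max_hz maximum admissible formant bandwidth, Hz.
#' @param f_min_hz minimum admissible formant frequency, Hz.
#' @param voicing_threshold voiced-frame gate (see [f0_contour()]).
#' @return named list `f1_hz`..`f4_hz` (all `NA` when fewer than four
#'   resolvable peaks), with attribute `config`.
#' @export
estimate_formants <- function(samples, sample_rate_hz, order = 14,
                              target_rate_hz = 11000, bw_max_hz = 700,
                              f_min_hz = 90, voicing_threshold = 0.45) {
  dec <- max(1L, floor(sample_rate_hz / target_rate_hz))
  sr2 <- sample_rate_hz / dec
  na_out <- structure(list(f1_hz = NA_real_, f2_hz = NA_real_,
                           f3_hz = NA_real_, f4_hz = NA_real_),
                      config = list(order = order, decimation = dec,
                                    analysis_rate_hz = sr2,
                                    bw_max_hz = bw_max_hz,
                                    pre_emphasis = 0))
  if (length(samples) < 0.05 * sample_rate_hz) return(na_out)
  ctr <- f0_contour(samples, sample_rate_hz,
                    voicing_threshold = voicing_threshold)
  if (!any(ctr$voiced)) return(na_out)
  x <- samples
  if (dec > 1L) {
    bf <- signal::butter(8, 0.85 / dec)
    x <- signal::filtfilt(bf, x)[seq(1L, length(x), by = dec)]
  }
  x <- x - mean(x)
  ac <- stats::acf(x, lag.max = order, plot = FALSE, demean = FALSE,
                   type = "covariance")$acf[, 1, 1]
  if (ac[1] <= 0) return(na_out)
  a <- as.numeric(signal::levinson(ac, order)$a)
  rts <- polyroot(rev(a))
  f <- Arg(rts) * sr2 / (2 * pi)
  bw <- -log(Mod(rts)) * sr2 / pi
  sel <- f > f_min_hz & f < sr2 / 2 - 200 & bw < bw_max_hz
  f <- sort(f[sel])
  if (length(f) < 4L || any(diff(f[1:4]) <= 0)) return(na_out)
  structure(list(f1_hz = f[1], f2_hz = f[2], f3_hz = f[3], f4_hz = f[4]),
            config = attr(na_out, "config"))
}

#' Vocal-tract measures derived from a formant set
#'
#' With formants F_1 < F_2 < F_3 < F_4 and speed of sound c:
#' mean formant = arithmetic mean; fdisp = (F4 - F1)/3 (average spacing);
#' delta_f = sum_i F_i (2i-1)/2 / sum_i ((2i-1)/2)^2, the least-squares
#' spacing of an ideal quarter-wave resonator (regression of F_i on the odd
#' half-multiples through the origin); mff = geometric mean;
#' fitch_vtl = mean_i (2i-1) c / (4 F_i) (weighted average of quarter
#' wavelengths); vtl_delta_f = c / (2 delta_f); pF = mean_i
#' (F_i - mu_i)/sigma_i against reference means and SDs (cohort-derived by
#' default, supplied through `pf_ref`).
#'
#' @param formants list/vector with `f1_hz`..`f4_hz`.
#' @param speed_of_sound_cm_s speed of sound, cm/s (default 35000; lengths
#'   come out in cm).
#' @param pf_ref optional list with numeric `mean` and `sd` of length 4; when
#'   `NULL`, `pf` is `NA` (to be filled once cohort reference values exist).
#' @return named list `mean_formant`, `delta_f`, `fdisp`, `fitch_vtl`,
#'   `mff`, `pf`, `vtl_delta_f`.
#' @export
formant_derived <- function(formants, speed_of_sound_cm_s = 35000,
                            pf_ref = NULL) {
  f <- as.numeric(c(formants$f1_hz, formants$f2_hz, formants$f3_hz,
                    formants$f4_hz))
  if (anyNA(f)) {
    return(list(mean_formant = NA_real_, delta_f = NA_real_,
                fdisp = NA_real_, fitch_vtl = NA_real_, mff = NA_real_,
                pf = NA_real_, vtl_delta_f = NA_real_))
  }
  stopifnot(all(f > 0), all(diff(f) > 0))
  i <- 1:4
  w <- (2 * i - 1) / 2
  delta_f <- sum(f * w) / sum(w^2)
  c_ <- speed_of_sound_cm_s
  list(mean_formant = mean(f),
       delta_f = delta_f,
       fdisp = (f[4] - f[1]) / 3,
       fitch_vtl = mean((2 * i - 1) * c_ / (4 * f)),
       mff = prod(f)^(1 / 4),
       pf = if (is.null(pf_ref)) NA_real_ else
         mean((f - pf_ref$mean) / pf_ref$sd),
       vtl_delta_f = c_ / (2 * delta_f))
}

#' Syllabic-nuclei features: pause rate, phonation time, speech rate
#'
#' Syllable nuclei are intensity peaks above a threshold (segment median
#' intensity by default), separated by dips of at least `dip_db`, and
#' coincident with voiced frames. Pauses are runs of unvoiced or
#' below-threshold frames lasting at least `min_pause_s`. Speech rate is
#' nuclei per second of segment; pause rate is pauses per second of segment;
#' phonation time is the voiced above-threshold fraction of the segment.
#'
#' @param samples segment waveform (non-empty).
#' @param sample_rate_hz sampling rate, Hz.
#' @param hop_s intensity/voicing frame hop, seconds.
#' @param dip_db required intensity dip between nuclei, dB (default 2).
#' @param min_pause_s minimum pause duration, seconds (default 0.3).
#' @param threshold_offset_db offset added to the median-intensity threshold.
#' @return list `pause_rate` (pauses/s), `phonation_time` (fraction),
#'   `speech_rate` (syllables/s); `phonation_time` is `NA` for an all-silent
#'   segment.
#' @export
syllable_nuclei_features <- function(samples, sample_rate_hz,
                                     hop_s = 0.010, dip_db = 2,
                                     min_pause_s = 0.3,
                                     threshold_offset_db = 0) {
  if (length(samples) == 0L) stop("empty segment")
  dur_s <- length(samples) / sample_rate_hz
  ctr <- f0_contour(samples, sample_rate_hz, hop_s = hop_s)
  flen <- floor(0.040 * sample_rate_hz)
  hop <- floor(hop_s * sample_rate_hz)
  starts <- seq(1L, max(1L, length(samples) - flen + 1L), by = hop)
  int_db <- vapply(starts, function(s) {
    rms_db(samples[s:min(s + flen - 1L, length(samples))])
  }, numeric(1))
  n <- min(length(int_db), nrow(ctr))
  int_db <- int_db[seq_len(n)]
  voiced <- ctr$voiced[seq_len(n)]
  thr <- stats::median(int_db) + threshold_offset_db
  active <- int_db >= thr & voiced
  if (!any(active)) {
    return(list(pause_rate = 0, phonation_time = NA_real_, speech_rate = 0))
  }
  # count nuclei: local intensity maxima within active regions, separated by
  # dips of at least dip_db
  nuclei <- 0L
  last_peak <- -Inf
  min_since <- Inf
  in_active <- FALSE
  for (k in seq_len(n)) {
    if (active[k]) {
      if (!in_active) {            # entering an active region
        in_active <- TRUE
        if (nuclei == 0L || min_since <= last_peak - dip_db) {
          nuclei <- nuclei + 1L
          last_peak <- int_db[k]
          min_since <- Inf
        }
      }
      last_peak <- max(last_peak, int_db[k])
    } else {
      in_active <- FALSE
      min_since <- min(min_since, int_db[k])
    }
  }
  inactive_runs <- contiguous_runs(which(!active))
  pause_lens <- vapply(inactive_runs, function(r) length(r) * hop_s, 1)
  n_pauses <- sum(pause_lens >= min_pause_s)
  list(pause_rate = n_pauses / dur_s,
       phonation_time = sum(active) * hop_s / dur_s,
       speech_rate = nuclei / dur_s)
}

#' All speech features for one merged speech segment
#'
#' @param samples segment waveform.
#' @param sample_rate_hz sampling rate, Hz.
#' @param config thresholds (see [run_config()]).
#' @return one-row data frame with the 27 features of
#'   `speech_feature_names()` (`pf` left `NA` until cohort reference values
#'   exist) plus `voiced_s`.
#' @export
extract_segment_features <- function(samples, sample_rate_hz,
                                     config = run_config()) {
  tr <- track_periods(samples, sample_rate_hz, f0_min = config$f0_min,
                      f0_max = config$f0_max,
                      voicing_threshold = config$voicing_threshold)
  jit <- jitter_features(tr)
  shi <- shimmer_features(tr)
  ctr <- f0_contour(samples, sample_rate_hz, f0_min = config$f0_min,
                    f0_max = config$f0_max,
                    voicing_threshold = config$voicing_threshold)
  f0s <- f0_stats(ctr$f0_hz)
  fm <- estimate_formants(samples, sample_rate_hz)
  fd <- formant_derived(fm, speed_of_sound_cm_s = config$speed_of_sound)
  syl <- syllable_nuclei_features(samples, sample_rate_hz)
  data.frame(
    hnr = hnr(samples, sample_rate_hz, f0_min = config$f0_min,
              f0_max = config$f0_max, cap_db = config$hnr_cap,
              voicing_threshold = config$voicing_threshold),
    jitter = jit$jitter, absolute_jitter = jit$absolute_jitter,
    rap_jitter = jit$rap_jitter, ppq5_jitter = jit$ppq5_jitter,
    ddp_jitter = jit$ddp_jitter,
    shimmer = shi$shimmer, apq3_shimmer = shi$apq3_shimmer,
    apq5_shimmer = shi$apq5_shimmer, apq11_shimmer = shi$apq11_shimmer,
    dda_shimmer = shi$dda_shimmer,
    mean_f0 = f0s$mean_f0, std_f0 = f0s$std_f0,
    mean_f1 = fm$f1_hz, mean_f2 = fm$f2_hz, mean_f3 = fm$f3_hz,
    mean_f4 = fm$f4_hz,
    mean_formant = fd$mean_formant, delta_f = fd$delta_f, fdisp = fd$fdisp,
    fitch_vtl = fd$fitch_vtl, mff = fd$mff, pf = fd$pf,
    vtl_delta_f = fd$vtl_delta_f,
    pause_rate = syl$pause_rate, phonation_time = syl$phonation_time,
    speech_rate = syl$speech_rate,
    voiced_s = sum(ctr$voiced) * 0.010)
}

#' Aggregate per-segment features to one participant-day
#'
#' Unweighted mean over segments per feature, missing segment values
#' excluded pairwise. A day with no segments is absent from the output.
#'
#' @param segment_features data frame of per-segment feature rows.
#' @param participant,date identifiers attached to the output row.
#' @return one-row data frame, or `NULL` when `segment_features` is empty.
#' @export
daily_aggregate <- function(segment_features, participant = NA, date = NA) {
  if (is.null(segment_features) || nrow(segment_features) == 0L) return(NULL)
  num <- vapply(segment_features, is.numeric, logical(1))
  means <- lapply(segment_features[num], function(x) {
    m <- mean(x, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  })
  cbind(data.frame(participant = participant, date = date),
        as.data.frame(means), n_segments = nrow(segment_features))
}
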