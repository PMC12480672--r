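#' Specification of a synthetic voiced utterance
#'
#' Describes a source-filter voice to synthesise: an impulse-train glottal
#' source with controlled cycle-to-cycle period perturbation (jitter) and
#' amplitude perturbation (shimmer), filtered through a cascade of four
#' second-order resonators at the target formant frequencies. The planted
#' parameters are the ground truth against which the feature extractors are
#' validated.
#'
#' @param duration_s total duration in seconds (> 0).
#' @param f0_hz fundamental frequency in Hz; must lie below the first formant.
#' @param jitter_pct planted cycle-to-cycle period perturbation, percent of
#'   the mean period; in \[0, 20).
#' @param shimmer_pct planted cycle-to-cycle amplitude perturbation, percent
#'   of the mean amplitude; in \[0, 20).
#' @param formants_hz four target formant frequencies, strictly increasing.
#' @param formant_bw_hz resonator bandwidths in Hz (one per formant). Wider
#'   bandwidths make each glottal cycle ring down before the next begins,
#'   which keeps per-cycle peak amplitudes separable.
#' @param noise_snr_db additive white-noise level relative to the voiced
#'   signal power, dB; `Inf` for noiseless.
#' @param syllable_pattern list of `c(voiced_s, pause_s)` pairs describing a
#'   burst/pause structure; `NULL` means one fully voiced stretch of
#'   `duration_s`. Pauses are near-silent (>= 40 dB below the voiced RMS).
#' @param sample_rate_hz sampling rate, Hz.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `voice_spec`.
#' @export
voice_spec <- function(duration_s = 3, f0_hz = 150,
                       jitter_pct = 1, shimmer_pct = 5,
                       formants_hz = c(500, 1500, 2500, 3500),
                       formant_bw_hz = c(150, 200, 250, 300),
                       noise_snr_db = 25,
                       syllable_pattern = NULL,
                       sample_rate_hz = 44100,
                       seed = 1L) {
  stopifnot(duration_s > 0,
            jitter_pct >= 0, jitter_pct < 20,
            shimmer_pct >= 0, shimmer_pct < 20,
            length(formants_hz) == 4,
            all(diff(formants_hz) > 0),
            f0_hz > 0, f0_hz < formants_hz[1],
            length(formant_bw_hz) == 4, all(formant_bw_hz > 0),
            sample_rate_hz > 2 * formants_hz[4])
  # perturbation noise is clipped at +/- 3 SD, so periods stay positive iff
  # 3 * jitter_pct / 100 < 1; same for amplitudes
  if (jitter_pct * 3 >= 100 || shimmer_pct * 3 >= 100) {
    stop("perturbation large enough to produce non-positive periods/amplitudes")
  }
  if (!is.null(syllable_pattern)) {
    stopifnot(is.list(syllable_pattern),
              all(vapply(syllable_pattern, length, 1L) == 2L))
  }
  structure(list(duration_s = duration_s, f0_hz = f0_hz,
                 jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
                 formants_hz = formants_hz, formant_bw_hz = formant_bw_hz,
                 noise_snr_db = noise_snr_db,
                 syllable_pattern = syllable_pattern,
                 sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "voice_spec")
}

# synthesise one voiced run; returns samples plus the realized period and
# amplitude sequences (the oracle for the perturbation features)
synth_voiced_run <- function(dur_s, spec) {
  sr <- spec$sample_rate_hz
  t0 <- 1 / spec$f0_hz
  n_cyc <- ceiling(dur_s / t0) + 2L
  z <- clip(stats::rnorm(n_cyc), -3, 3)
  w <- clip(stats::rnorm(n_cyc), -3, 3)
  periods <- t0 * (1 + spec$jitter_pct / 100 * z)
  amps <- 1 + spec$shimmer_pct / 100 * w
  onsets <- cumsum(c(0, periods[-n_cyc]))
  keep <- onsets < dur_s - t0 / 2
  onsets <- onsets[keep]; amps <- amps[keep]
  periods <- periods[seq_len(sum(keep))]
  n <- round(dur_s * sr)
  x <- numeric(n)
  idx <- pmin(round(onsets * sr) + 1L, n)
  x[idx] <- amps
  for (k in 1:4) {
    r <- exp(-pi * spec$formant_bw_hz[k] / sr)
    th <- 2 * pi * spec$formants_hz[k] / sr
    x <- as.numeric(stats::filter(x, filter = c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  if (is.finite(spec$noise_snr_db)) {
    x <- x + stats::rnorm(n, sd = sqrt(mean(x^2) / 10^(spec$noise_snr_db / 10)))
  }
  list(samples = x, periods_ms = periods * 1000, amplitudes = amps,
       onsets_s = onsets)
}

#' Synthesise a voiced waveform from a `voice_spec`
#'
#' Deterministic for a fixed spec (the seed lives in the spec). The returned
#' object carries the realized per-cycle period and amplitude sequences as
#' ground truth, so perturbation features extracted downstream can be checked
#' against a direct computation on the generator's own cycle list.
#'
#' @param spec a [voice_spec()].
#' @return object of class `voice_wave`: list with `samples` (peak-normalised
#'   to 0.9 full scale), `sample_rate_hz`, and `ground_truth` (per voiced run:
#'   onset, periods in ms, cycle amplitudes; plus the planted spec values).
#' @export
gen_voice <- function(spec) {
  stopifnot(inherits(spec, "voice_spec"))
  withr::with_seed(spec$seed, {
    pattern <- spec$syllable_pattern
    if (is.null(pattern)) pattern <- list(c(spec$duration_s, 0))
    sr <- spec$sample_rate_hz
    pieces <- list(); voiced <- logical(0); runs <- list(); t_cursor <- 0
    for (p in pattern) {
      run <- synth_voiced_run(p[1], spec)
      runs[[length(runs) + 1L]] <- list(
        start_s = t_cursor,
        duration_s = p[1],
        periods_ms = run$periods_ms,
        amplitudes = run$amplitudes,
        onsets_s = run$onsets_s + t_cursor)
      pieces[[length(pieces) + 1L]] <- run$samples
      voiced <- c(voiced, TRUE)
      t_cursor <- t_cursor + p[1]
      if (p[2] > 0) {
        pieces[[length(pieces) + 1L]] <- numeric(round(p[2] * sr))
        voiced <- c(voiced, FALSE)
        t_cursor <- t_cursor + p[2]
      }
    }
    voiced_rms <- sqrt(mean(unlist(pieces[voiced], use.names = FALSE)^2))
    # pause noise floor 60 dB below the voiced RMS (near-silent)
    pieces[!voiced] <- lapply(pieces[!voiced], function(z) {
      stats::rnorm(length(z), sd = voiced_rms * 10^(-60 / 20))
    })
    x <- unlist(pieces, use.names = FALSE)
    # normalise to 0.9 peak so voiced frames sit well above -20 dBFS
    g <- 0.9 / max(abs(x))
    x <- x * g
    structure(list(samples = x, sample_rate_hz = sr,
                   ground_truth = list(spec = spec, runs = runs, gain = g)),
              class = "voice_wave")
  })
}
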