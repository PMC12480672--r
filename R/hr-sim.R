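#' Generate a synthetic 1-Hz wearable heart-rate stream
#'
#' The underlying RR-interval process is stationary AR(1) Gaussian with mean
#' `mean_rr_ms` and standard deviation `sdnn_ms`. A fraction
#' `prob_large_delta` of successive steps is forced to exceed 20 ms in
#' magnitude, which controls the achievable pNN20 downstream. RR is converted
#' to heart rate through the hyperbolic relation HR x RR = 60,000 and emitted
#' as timestamped 1-Hz samples (full double precision, no device rounding).
#' A fraction `dropout_rate` of samples is removed in contiguous gaps.
#'
#' The object records, per retained contiguous run, its own RR values: this
#' ground-truth list is the oracle for the HRV pipeline.
#'
#' @param n_days number of days to simulate.
#' @param mean_rr_ms stationary mean RR interval, ms; must lie in (350, 1200).
#' @param sdnn_ms stationary SD of the RR process, ms.
#' @param prob_large_delta fraction of successive steps forced beyond 20 ms.
#' @param dropout_rate fraction of samples removed, in contiguous gaps.
#' @param seed integer seed.
#' @param seconds_per_day seconds of 1-Hz recording per day (daily wear time).
#' @param ar_coef AR(1) autocorrelation of the RR process.
#' @param mean_gap_s mean dropout gap length, seconds.
#' @return object of class `hr_stream`: data frame `samples` with columns
#'   `day`, `t_s` (seconds within day), `hr_bpm`; and `ground_truth` with the
#'   retained per-run RR lists.
#' @export
gen_hr_stream <- function(n_days = 1, mean_rr_ms = 800, sdnn_ms = 40,
                          prob_large_delta = 0.1, dropout_rate = 0.1,
                          seed = 1L, seconds_per_day = 3600,
                          ar_coef = 0.9, mean_gap_s = 30) {
  stopifnot(mean_rr_ms > 350, mean_rr_ms < 1200,
            sdnn_ms >= 0, prob_large_delta >= 0, prob_large_delta <= 1,
            dropout_rate >= 0, dropout_rate < 1, n_days >= 1)
  withr::with_seed(as.integer(seed), {
    days <- list()
    for (d in seq_len(n_days)) {
      n <- seconds_per_day
      rr <- numeric(n)
      rr[1] <- mean_rr_ms + stats::rnorm(1, sd = sdnn_ms)
      innov_sd <- sdnn_ms * sqrt(1 - ar_coef^2)
      forced <- stats::runif(n) < prob_large_delta
      for (t in 2:n) {
        if (forced[t] && sdnn_ms > 0) {
          delta <- sample(c(-1, 1), 1) * (20 + stats::rexp(1, rate = 1 / 10))
          rr[t] <- rr[t - 1] + delta
        } else {
          rr[t] <- mean_rr_ms + ar_coef * (rr[t - 1] - mean_rr_ms) +
            stats::rnorm(1, sd = innov_sd)
        }
      }
      rr <- clip(rr, 360, 1190)  # keep within the physiological filter band
      keep <- rep(TRUE, n)
      if (dropout_rate > 0) {
        n_drop <- round(dropout_rate * n)
        while (sum(!keep) < n_drop) {
          glen <- max(2L, stats::rpois(1, mean_gap_s))
          gstart <- sample.int(n - glen, 1)
          keep[gstart:(gstart + glen - 1L)] <- FALSE
        }
      }
      idx <- which(keep)
      runs <- contiguous_runs(idx)
      days[[d]] <- list(
        samples = data.frame(day = d, t_s = idx - 1L, hr_bpm = 60000 / rr[idx]),
        runs = lapply(runs, function(r) {
          list(start_s = r[1] - 1L, rr_ms = rr[r])
        }))
    }
    structure(list(
      samples = do.call(rbind, lapply(days, `[[`, "samples")),
      ground_truth = list(
        mean_rr_ms = mean_rr_ms, sdnn_ms = sdnn_ms,
        prob_large_delta = prob_large_delta, dropout_rate = dropout_rate,
        seed = as.integer(seed),
        runs_by_day = lapply(days, `[[`, "runs"))),
      class = "hr_stream")
  })
}
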