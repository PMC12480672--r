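# Independent direct-formula oracles, written as plain loops so they share
# no code path with the package's vectorised implementations.

oracle_jitter <- function(periods_ms) {
  n <- length(periods_ms)
  mT <- sum(periods_ms) / n
  s_abs <- 0
  for (i in 2:n) s_abs <- s_abs + abs(periods_ms[i] - periods_ms[i - 1])
  s_abs <- s_abs / (n - 1)
  s_rap <- 0
  for (i in 2:(n - 1)) {
    s_rap <- s_rap + abs(periods_ms[i] -
                           (periods_ms[i - 1] + periods_ms[i] +
                              periods_ms[i + 1]) / 3)
  }
  s_rap <- s_rap / (n - 2)
  s_ddp <- 0
  for (i in 2:(n - 1)) {
    s_ddp <- s_ddp + abs((periods_ms[i + 1] - periods_ms[i]) -
                           (periods_ms[i] - periods_ms[i - 1]))
  }
  s_ddp <- s_ddp / (n - 2)
  s_ppq5 <- NA_real_
  if (n >= 5) {
    s_ppq5 <- 0
    for (i in 3:(n - 2)) {
      s_ppq5 <- s_ppq5 + abs(periods_ms[i] - sum(periods_ms[(i - 2):(i + 2)]) / 5)
    }
    s_ppq5 <- s_ppq5 / (n - 4)
  }
  list(jitter = 100 * s_abs / mT, absolute_jitter = s_abs,
       rap_jitter = 100 * s_rap / mT, ppq5_jitter = 100 * s_ppq5 / mT,
       ddp_jitter = 100 * s_ddp / mT)
}

oracle_shimmer <- function(amps) {
  n <- length(amps)
  mA <- sum(amps) / n
  s_loc <- 0
  for (i in 2:n) s_loc <- s_loc + abs(amps[i] - amps[i - 1])
  s_loc <- s_loc / (n - 1)
  apq <- function(k) {
    h <- (k - 1) %/% 2
    if (n < k) return(NA_real_)
    s <- 0
    for (i in (1 + h):(n - h)) s <- s + abs(amps[i] - mean(amps[(i - h):(i + h)]))
    100 * (s / (n - 2 * h)) / mA
  }
  list(shimmer = 100 * s_loc / mA, apq3_shimmer = apq(3),
       apq5_shimmer = apq(5), apq11_shimmer = apq(11),
       dda_shimmer = 3 * apq(3))
}

oracle_hrv <- function(segments) {
  mnn <- c(); sdn <- c(); pnn <- c()
  for (rr in segments) {
    if (length(rr) < 2) next
    pb <- attr(rr, "pair_break")
    if (is.null(pb)) pb <- rep(FALSE, length(rr) - 1)
    mnn <- c(mnn, sum(rr) / length(rr))
    m <- sum(rr) / length(rr)
    sdn <- c(sdn, sqrt(sum((rr - m)^2) / (length(rr) - 1)))
    big <- 0; tot <- 0
    for (i in 2:length(rr)) {
      if (!pb[i - 1]) {
        tot <- tot + 1
        if (abs(rr[i] - rr[i - 1]) > 20) big <- big + 1
      }
    }
    pnn <- c(pnn, if (tot > 0) 100 * big / tot else NA_real_)
  }
  if (!length(mnn)) return(NULL)
  list(mean_nn_ms = mean(mnn), sdnn_ms = mean(sdn),
       pnn20_pct = mean(pnn, na.rm = TRUE), n_segments = length(mnn))
}

# greedy VIF pruning by exhaustive recomputation with plain lm(); removes
# the max-VIF term (lexicographically last among ties) until all < cutoff
oracle_vif_prune <- function(df, terms, cutoff = 20) {
  vif_one <- function(cols, j) {
    y <- df[[cols[j]]]
    others <- cols[-j]
    fml <- stats::as.formula(paste0("`", cols[j], "` ~ ",
                                    paste0("`", others, "`",
                                           collapse = " + ")))
    r2 <- summary(stats::lm(fml, data = df))$r.squared
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(terms) < 2) break
    v <- vapply(seq_along(terms), function(j) vif_one(terms, j), numeric(1))
    if (max(v) < cutoff) break
    tied <- terms[v == max(v)]
    terms <- setdiff(terms, sort(tied)[length(tied)])
  }
  terms
}

# random period/amplitude track for fuzzing
random_track <- function(n = NULL) {
  if (is.null(n)) n <- sample(11:60, 1)
  structure(list(periods_ms = stats::runif(n, 3, 12),
                 amplitudes = stats::runif(n, 0.2, 1.5)),
            class = "period_track")
}

symptom_flag_names <- c("sputum_color", "breathlessness", "sputum_amount",
                        "cold", "fever", "wheezing", "sore_throat", "cough")

diary_day <- function(on = character(0)) {
  stats::setNames(symptom_flag_names %in% on, symptom_flag_names)
}

# small cohort spec used where full study scale is not needed
smoke_cohort_spec <- function(seed, ...) {
  cohort_spec(n_participants = 6, n_days = 25, seed = seed, ...)
}
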