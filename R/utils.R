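#' @keywords internal
"_PACKAGE"

# clip to a symmetric band; used for perturbation noise (+/- 3 SD)
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# frame RMS -> dB re full scale (amplitude 1.0)
rms_db <- function(x) {
  r <- sqrt(mean(x^2))
  if (r <= 0) return(-Inf)
  20 * log10(r)
}

# split a numeric vector of sorted integer indices into contiguous runs
contiguous_runs <- function(idx) {
  if (length(idx) == 0L) return(list())
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  lapply(seq_len(length(brk) - 1L), function(k) idx[(brk[k] + 1L):brk[k + 1L]])
}

# union of [start, end) intervals; returns total length and merged intervals
union_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(list(intervals = data.frame(start = numeric(0), end = numeric(0)),
                total = 0))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  list(intervals = data.frame(start = outs, end = oute),
       total = sum(oute - outs))
}

# deterministic CSV writer (stable column order, no row names, full precision)
write_table_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
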