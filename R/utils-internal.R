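# Shared internal helpers: argument checks, filtering, resampling, smoothing.

.check_num <- function(x, name, finite = TRUE, positive = FALSE,
                       nonneg = FALSE, len = 1L) {
  if (!is.numeric(x) || (!is.null(len) && length(x) != len))
    stop(sprintf("`%s` must be numeric of length %d", name, len), call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && any(x < 0))
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

.check_frac <- function(x, name) {
  .check_num(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("`%s` must be in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Zero-phase Butterworth band-pass (3rd order, applied forward-backward).
.bandpass <- function(x, fs, lo, hi, order = 3L) {
  nyq <- fs / 2
  if (hi >= nyq) hi <- 0.99 * nyq
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

.lowpass <- function(x, fs, hi, order = 3L) {
  bf <- signal::butter(order, hi / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Integer-factor downsampling; assumes the caller already band-limited x.
.decimate <- function(x, fs, target_fs) {
  if (fs == target_fs) return(x)
  r <- fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("sampling rate must be an integer multiple of the target rate",
         call. = FALSE)
  x[seq(1L, length(x), by = as.integer(round(r)))]
}

# Centered boxcar moving average; window in samples.
.boxcar <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2L, circular = FALSE)) -> y
  # fill edges with shrinking windows so thresholds see no NA
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  if (half >= 1L) {
    for (i in seq_len(min(half, n))) {
      hi <- min(n, i + half)
      y[i] <- (cs[hi + 1L] - cs[1L]) / hi
      j <- n - i + 1L
      lo <- max(1L, j - half)
      y[j] <- (cs[n + 1L] - cs[lo]) / (n - lo + 1L)
    }
  }
  y
}

# Runs of TRUE as (start, stop) sample indices (inclusive).
.runs_true <- function(flag) {
  n <- length(flag)
  if (n == 0L || !any(flag)) {
    return(data.frame(start = integer(0), stop = integer(0)))
  }
  d <- diff(c(FALSE, flag, FALSE))
  data.frame(start = which(d == 1L), stop = which(d == -1L) - 1L)
}

# Merge intervals whose gap (in samples) is < max_gap.
.merge_runs <- function(runs, max_gap) {
  if (nrow(runs) < 2L) return(runs)
  keep_start <- runs$start[1L]
  out_s <- integer(0); out_e <- integer(0)
  cur_e <- runs$stop[1L]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - cur_e - 1L < max_gap) {
      cur_e <- max(cur_e, runs$stop[i])
    } else {
      out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_e)
      keep_start <- runs$start[i]; cur_e <- runs$stop[i]
    }
  }
  data.frame(start = c(out_s, keep_start), stop = c(out_e, cur_e))
}

# Empty typed event table shared by all detectors.
.empty_events <- function() {
  data.frame(kind = character(0), start_s = numeric(0), stop_s = numeric(0),
             peak_s = numeric(0), peak_amp = numeric(0),
             halfwidth_s = numeric(0), n_cycles = numeric(0),
             peak_freq_hz = numeric(0), stringsAsFactors = FALSE)
}

.as_events <- function(kind, start_s, stop_s, peak_s = NA_real_,
                       peak_amp = NA_real_, halfwidth_s = NA_real_,
                       n_cycles = NA_real_, peak_freq_hz = NA_real_) {
  n <- length(start_s)
  if (n == 0L) return(.empty_events())
  df <- data.frame(kind = rep_len(kind, n), start_s = start_s, stop_s = stop_s,
                   peak_s = rep_len(peak_s, n), peak_amp = rep_len(peak_amp, n),
                   halfwidth_s = rep_len(halfwidth_s, n),
                   n_cycles = rep_len(n_cycles, n),
                   peak_freq_hz = rep_len(peak_freq_hz, n),
                   stringsAsFactors = FALSE)
  df[order(df$start_s), , drop = FALSE]
}
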