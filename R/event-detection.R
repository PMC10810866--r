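# Time-domain detectors: active periods, sharp waves, dual-method ripples,
# consensus, SPW coupling, iHFO windows, movement rule.

# Local maxima of x above `height`, with prominence and half-height width.
# Returns indices plus per-peak width (samples) and half-height crossings.
.find_peaks <- function(x, height, min_prominence = -Inf,
                        max_width = Inf) {
  n <- length(x)
  if (n < 3L) return(data.frame(idx = integer(0)))
  core <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  core <- core[x[core] >= height]
  if (!length(core)) return(data.frame(idx = integer(0)))
  keep <- logical(length(core))
  prom <- wid <- left <- right <- numeric(length(core))
  for (j in seq_along(core)) {
    i <- core[j]; h <- x[i]
    # prominence: descend to the lowest point before re-reaching h each side
    li <- i; lo_l <- h
    while (li > 1L && x[li - 1L] < h) { li <- li - 1L; lo_l <- min(lo_l, x[li]) }
    if (li == 1L) lo_l <- min(x[1:i])
    ri <- i; lo_r <- h
    while (ri < n && x[ri + 1L] < h) { ri <- ri + 1L; lo_r <- min(lo_r, x[ri]) }
    if (ri == n) lo_r <- min(x[i:n])
    p <- h - max(lo_l, lo_r)
    # half-height width; a crossing requires two consecutive samples below
    # half height so single-sample noise dips do not truncate the width
    half <- h / 2
    below <- x <= half
    a <- i
    while (a > 2L && !(below[a] && below[a - 1L])) a <- a - 1L
    b <- i
    while (b < n - 1L && !(below[b] && below[b + 1L])) b <- b + 1L
    prom[j] <- p; wid[j] <- b - a
    left[j] <- a; right[j] <- b
    keep[j] <- p >= min_prominence && (b - a) <= max_width
  }
  data.frame(idx = core, prominence = prom, width = wid,
             left = left, right = right)[keep, , drop = FALSE]
}

#' Detect active LFP periods
#'
#' Flags epochs with oscillatory bursts in an otherwise discontinuous neonatal
#' LFP. The signal is band-pass filtered 4-12 Hz, downsampled to 250 Hz,
#' squared, convolved with a 500 ms boxcar and z-scored. Candidate periods
#' exceed 1 SD (or a 50 uV RMS envelope); gaps under 1 s are merged; a
#' period is kept only if its peak reaches both 2 SD and a 100 uV envelope
#' (a candidate falling short of either is discarded); periods shorter than
#' 300 ms are removed.
#'
#' @param x Single-channel LFP (uV), ideally the reversal channel.
#' @param fs Sampling rate, Hz (>= 24 Hz).
#' @return Event table with kind `"active"`; `peak_amp` is the peak RMS
#'   envelope in uV.
#' @export
detect_active_periods <- function(x, fs) {
  .check_num(fs, "fs", positive = TRUE)
  if (fs < 24) stop("`fs` must be at least 24 Hz", call. = FALSE)
  target <- if (fs >= 250 && (fs / 250) %% 1 == 0) 250 else fs
  y <- .bandpass(x, fs, 4, 12)
  y <- .decimate(y, fs, target)
  sq <- .boxcar(y^2, round(0.5 * target))
  rms <- sqrt(pmax(sq, 0))
  if (stats::sd(sq) == 0) return(.empty_events())
  z <- (sq - mean(sq)) / stats::sd(sq)
  flag <- z > 1 | rms > 50
  runs <- .runs_true(flag)
  if (!nrow(runs)) return(.empty_events())
  runs <- .merge_runs(runs, max_gap = round(1 * target))
  keep <- logical(nrow(runs))
  pk_i <- integer(nrow(runs)); pk_a <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs$start[i]:runs$stop[i]
    keep[i] <- max(z[seg]) >= 2 && max(rms[seg]) >= 100
    pk_i[i] <- seg[which.max(z[seg])]
    pk_a[i] <- max(rms[seg])
  }
  runs <- runs[keep, , drop = FALSE]; pk_i <- pk_i[keep]; pk_a <- pk_a[keep]
  dur <- (runs$stop - runs$start + 1L) / target
  long <- dur >= 0.3
  .as_events("active", (runs$start[long] - 1L) / target,
             runs$stop[long] / target, (pk_i[long] - 1L) / target,
             pk_a[long])
}

#' Radial LFP difference for sharp-wave detection
#'
#' Subtracts the channel below the pyramidal layer from the channel above it
#' (so the laminar polarity reversal of sharp waves adds constructively),
#' after 1-100 Hz band-pass filtering and downsampling to 250 Hz.
#'
#' @param lfp Samples x channels numeric matrix (uV).
#' @param fs Sampling rate of `lfp`, Hz.
#' @param above_idx,below_idx Column indices of the channels above and below
#'   the reversal channel.
#' @return List with `x` (difference signal, uV) and `fs` (250 Hz, or the
#'   input rate when it cannot be decimated by an integer factor).
#' @export
radial_difference <- function(lfp, fs, above_idx = 1, below_idx = 2) {
  if (!is.matrix(lfp)) stop("`lfp` must be a samples x channels matrix",
                            call. = FALSE)
  if (max(above_idx, below_idx) > ncol(lfp) || min(above_idx, below_idx) < 1)
    stop("channel index out of range", call. = FALSE)
  target <- if (fs >= 250 && (fs / 250) %% 1 == 0) 250 else fs
  a <- .decimate(.bandpass(lfp[, above_idx], fs, 1, 100), fs, target)
  b <- .decimate(.bandpass(lfp[, below_idx], fs, 1, 100), fs, target)
  list(x = a - b, fs = target)
}

#' Adaptive sharp-wave threshold multiplier
#'
#' Maps the standard deviation of the radial difference signal to a detection
#' multiplier between 3 and 5 SD, inversely proportional to the signal
#' variability: quiet (early-age) recordings get the permissive 5 SD bound,
#' high-variance (older) recordings the strict 3 SD bound, with linear
#' interpolation in between and clamping outside the calibration bounds.
#'
#' @param signal_sd Observed SD of the difference signal (uV).
#' @param sd_low,sd_high Calibration bounds (uV): at or below `sd_low` the
#'   multiplier is 5; at or above `sd_high` it is 3.
#' @return Multiplier in `[3, 5]`.
#' @export
adaptive_spw_multiplier <- function(signal_sd, sd_low = 10, sd_high = 100) {
  .check_num(signal_sd, "signal_sd", nonneg = TRUE)
  if (sd_low >= sd_high) stop("`sd_low` must be below `sd_high`",
                              call. = FALSE)
  frac <- (signal_sd - sd_low) / (sd_high - sd_low)
  5 - 2 * min(1, max(0, frac))
}

#' Detect sharp waves in the radial difference signal
#'
#' Labels local maxima exceeding `mean + multiplier * SD` of the signal as
#' sharp waves, requiring prominence of at least half the threshold and a
#' half-height width of at most 100 ms; the recorded halfwidth is the width
#' at half peak height.
#'
#' @param diff_signal Output of [radial_difference()] (list with `x`, `fs`) or
#'   a numeric vector (then supply `fs`).
#' @param multiplier Threshold multiplier, typically from
#'   [adaptive_spw_multiplier()].
#' @param fs Sampling rate when `diff_signal` is a bare vector.
#' @param max_width_ms Maximum half-height width, ms.
#' @return Event table with kind `"spw"`, peak amplitude (uV) and
#'   `halfwidth_s`.
#' @export
detect_spw <- function(diff_signal, multiplier = 4, fs = NULL,
                       max_width_ms = 100) {
  if (is.list(diff_signal)) { fs <- diff_signal$fs; x <- diff_signal$x }
  else x <- diff_signal
  if (is.null(fs)) stop("`fs` required for a bare numeric signal",
                        call. = FALSE)
  if (multiplier < 3 || multiplier > 5)
    warning("`multiplier` outside the 3-5 SD range")
  mu <- mean(x); sdv <- stats::sd(x)
  if (sdv == 0) return(.empty_events())
  thr <- mu + multiplier * sdv
  pk <- .find_peaks(x, height = thr, min_prominence = thr / 2,
                    max_width = round(max_width_ms / 1000 * fs))
  if (!nrow(pk)) return(.empty_events())
  # suppress satellite maxima: among peaks closer than the width bound,
  # keep the highest
  ord <- order(-x[pk$idx])
  keep <- logical(nrow(pk))
  taken <- numeric(0)
  min_sep <- max_width_ms / 1000 * fs
  for (j in ord) {
    if (!length(taken) || all(abs(pk$idx[j] - taken) > min_sep)) {
      keep[j] <- TRUE
      taken <- c(taken, pk$idx[j])
    }
  }
  pk <- pk[keep, , drop = FALSE]
  .as_events("spw",
             start_s = (pk$left - 1L) / fs, stop_s = (pk$right - 1L) / fs,
             peak_s = (pk$idx - 1L) / fs, peak_amp = x[pk$idx],
             halfwidth_s = pk$width / fs)
}

# Dominant frequency inside an event from zero crossings of the band signal.
.event_freq <- function(xf, fs, i0, i1) {
  seg <- xf[i0:i1]
  zc <- sum(diff(sign(seg)) != 0)
  (zc / 2) / ((i1 - i0 + 1L) / fs)
}

#' Power-threshold ripple detection
#'
#' The classic envelope method: band-limit to the ripple band, square, smooth
#' with a boxcar, then (i) label periods above 3 SD of the smoothed power,
#' (ii) merge labelled periods separated by less than 30 ms, (iii) discard
#' periods whose peak stays below 6 SD, and (iv) keep only periods longer than
#' 20 ms and shorter than `max_len_ms` (100 ms for spontaneous ripples,
#' 120 ms for induced high-frequency oscillations).
#'
#' @param x Single-channel LFP (uV), pyramidal-layer (reversal) channel.
#' @param fs Sampling rate, Hz (>= 1000 expected after the standard
#'   downsampling).
#' @param band Ripple band, Hz (default 80-200; alternatives such as 100-250
#'   are accepted for robustness checks).
#' @param max_len_ms Maximum event length, ms.
#' @param smooth_ms Boxcar smoothing window, ms (roughly 1.5 ripple cycles).
#' @param label_sd,peak_sd Labelling and peak thresholds in SDs of the
#'   smoothed power.
#' @param merge_ms Merge gap, ms.
#' @param min_len_ms Minimum event length, ms.
#' @return Event table with kind `"ripple"`, per-event peak frequency and
#'   cycle count.
#' @export
detect_ripples_power <- function(x, fs, band = c(80, 200), max_len_ms = 100,
                                 smooth_ms = 12, label_sd = 3, peak_sd = 6,
                                 merge_ms = 30, min_len_ms = 20) {
  .check_num(fs, "fs", positive = TRUE)
  xf <- .bandpass(x, fs, band[1], band[2])
  pow <- .boxcar(xf^2, round(smooth_ms / 1000 * fs))
  mu <- mean(pow); sdv <- stats::sd(pow)
  if (sdv == 0) return(.empty_events())
  runs <- .runs_true(pow > mu + label_sd * sdv)
  if (!nrow(runs)) return(.empty_events())
  runs <- .merge_runs(runs, max_gap = round(merge_ms / 1000 * fs))
  peak_ok <- vapply(seq_len(nrow(runs)), function(i)
    max(pow[runs$start[i]:runs$stop[i]]) >= mu + peak_sd * sdv, logical(1))
  runs <- runs[peak_ok, , drop = FALSE]
  if (!nrow(runs)) return(.empty_events())
  len_ms <- (runs$stop - runs$start + 1L) / fs * 1000
  runs <- runs[len_ms > min_len_ms & len_ms < max_len_ms, , drop = FALSE]
  if (!nrow(runs)) return(.empty_events())
  pk_i <- pk_a <- fr <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs$start[i]:runs$stop[i]
    pk_i[i] <- seg[which.max(pow[seg])]
    pk_a[i] <- max(abs(xf[seg]))
    fr[i] <- .event_freq(xf, fs, runs$start[i], runs$stop[i])
  }
  dur <- (runs$stop - runs$start + 1L) / fs
  .as_events("ripple", (runs$start - 1L) / fs, runs$stop / fs,
             (pk_i - 1L) / fs, pk_a, n_cycles = dur * fr, peak_freq_hz = fr)
}

#' Cycle-by-cycle ripple detection
#'
#' Time-domain burst detection: the signal is band-pass filtered (1-200 Hz,
#' with the ripple band used to localize cycle landmarks), segmented into
#' cycles delimited by rising zero-crossings, and per-cycle features are
#' computed (amplitude, period, rise-decay symmetry, peak-trough symmetry,
#' flank monotonicity). A cycle belongs to a burst when its amplitude and
#' period are consistent with its neighbours and its flanks are sufficiently
#' monotonic; events are maximal runs of at least `min_cycles` burst cycles.
#'
#' @param x Single-channel LFP (uV).
#' @param fs Sampling rate, Hz.
#' @param thresholds List with `amplitude_consistency`, `period_consistency`
#'   and `monotonicity`, each in `[0, 1]`.
#' @param band Frequency band used to localize cycles, Hz.
#' @param min_cycles Minimum consecutive burst cycles per event.
#' @return List with `events` (event table, kind `"ripple"`) and `cycles`
#'   (per-cycle feature data.frame).
#' @export
detect_ripples_bycycle <- function(x, fs,
                                   thresholds = list(
                                     amplitude_consistency = 0.6,
                                     period_consistency = 0.8,
                                     monotonicity = 0.85),
                                   band = c(80, 200), min_cycles = 3) {
  for (nm in c("amplitude_consistency", "period_consistency", "monotonicity")) {
    v <- thresholds[[nm]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("threshold `%s` must be in [0, 1]", nm), call. = FALSE)
  }
  broad <- .bandpass(x, fs, 1, min(200, 0.45 * fs))
  xf <- .bandpass(broad, fs, band[1], band[2])
  # rising zero-crossings of the band-limited signal delimit cycles
  rise <- which(xf[-length(xf)] < 0 & xf[-1L] >= 0)
  empty <- list(events = .empty_events(),
                cycles = data.frame(period_s = numeric(0),
                                    amplitude = numeric(0),
                                    rise_decay_symmetry = numeric(0),
                                    peak_trough_symmetry = numeric(0),
                                    monotonicity = numeric(0),
                                    is_burst = logical(0)))
  if (length(rise) < min_cycles + 2L) return(empty)
  nc <- length(rise) - 1L
  pk_i <- tr_i <- integer(nc)
  for (i in seq_len(nc)) {
    seg <- rise[i]:rise[i + 1L]
    pk_i[i] <- seg[which.max(xf[seg])]
    tr_i[i] <- seg[which.min(xf[seg])]
  }
  period <- diff(rise) / fs
  # cycle landmarks come from the band-limited signal; the features are
  # measured on the broadband signal so that non-oscillatory input does not
  # inherit the filter's smooth, sinusoid-like shape
  amp <- rise_t <- pt_sym <- mono <- ra <- da <- numeric(nc)
  for (i in seq_len(nc)) {
    prev_tr <- if (i > 1L) tr_i[i - 1L] else rise[1L]
    ra[i] <- broad[pk_i[i]] - broad[prev_tr]
    da[i] <- broad[pk_i[i]] - broad[tr_i[i]]
    amp[i] <- (ra[i] + da[i]) / 2
    rise_t[i] <- (pk_i[i] - prev_tr) / fs
    pt_sym[i] <- (tr_i[i] - pk_i[i]) / (rise[i + 1L] - rise[i])
    up <- diff(x[prev_tr:pk_i[i]]); dn <- diff(x[pk_i[i]:tr_i[i]])
    mono[i] <- mean(c(up > 0, dn < 0))
  }
  rd_sym <- pmin(1, pmax(0, rise_t / period))
  pt_sym <- pmin(1, pmax(0, pt_sym))
  rr <- function(a, b) ifelse(a <= 0 | b <= 0, 0,
                              pmin(a, b) / pmax(a, b))
  # amplitude consistency: ratio of the cycle's rise and decay flank
  # voltages (tapered bursts keep these close even while the envelope
  # changes across cycles; unstructured input does not)
  amp_c <- rr(ra, da)
  # period consistency with the better-matching neighbour, so that the
  # malformed edge cycle of a burst does not veto its first interior cycle
  per_c <- vapply(seq_len(nc), function(i) {
    nb <- c(if (i > 1L) period[i - 1L], if (i < nc) period[i + 1L])
    max(pmin(period[i], nb) / pmax(period[i], nb))
  }, numeric(1))
  in_band <- period > 0 & (1 / period) >= band[1] * 0.7 &
    (1 / period) <= band[2] * 1.3
  is_burst <- amp > 0 & amp_c >= thresholds$amplitude_consistency &
    per_c >= thresholds$period_consistency &
    mono >= thresholds$monotonicity & in_band
  is_burst[is.na(is_burst)] <- FALSE
  cyc <- data.frame(period_s = period, amplitude = amp,
                    rise_decay_symmetry = rd_sym,
                    peak_trough_symmetry = pt_sym, monotonicity = mono,
                    is_burst = is_burst)
  runs <- .runs_true(is_burst)
  if (!nrow(runs)) return(list(events = .empty_events(), cycles = cyc))
  runs <- runs[(runs$stop - runs$start + 1L) >= min_cycles, , drop = FALSE]
  if (!nrow(runs)) return(list(events = .empty_events(), cycles = cyc))
  ev <- .as_events("ripple",
                   start_s = (rise[runs$start] - 1L) / fs,
                   stop_s = (rise[runs$stop + 1L] - 1L) / fs,
                   peak_s = vapply(seq_len(nrow(runs)), function(i) {
                     cc <- runs$start[i]:runs$stop[i]
                     (pk_i[cc[which.max(amp[cc])]] - 1L) / fs
                   }, numeric(1)),
                   peak_amp = vapply(seq_len(nrow(runs)), function(i)
                     max(amp[runs$start[i]:runs$stop[i]]), numeric(1)),
                   n_cycles = runs$stop - runs$start + 1L,
                   peak_freq_hz = vapply(seq_len(nrow(runs)), function(i)
                     1 / stats::median(period[runs$start[i]:runs$stop[i]]),
                     numeric(1)))
  list(events = ev, cycles = cyc)
}

# Half-open interval overlap between two event tables.
.overlaps_any <- function(a_start, a_stop, b_start, b_stop) {
  vapply(seq_along(a_start), function(i)
    any(a_start[i] < b_stop & b_start < a_stop[i]), logical(1))
}

#' Consensus between the two ripple detectors
#'
#' Keeps each power-method event that overlaps (by any amount, half-open
#' convention) at least one cycle-by-cycle event; event boundaries are taken
#' from the power method. Only events found by both detectors count as
#' ripples.
#'
#' @param events_power Event table from [detect_ripples_power()].
#' @param events_bycycle Event table from [detect_ripples_bycycle()] (the
#'   `$events` element, or the full list).
#' @return Event table (subset of `events_power`).
#' @export
consensus_ripples <- function(events_power, events_bycycle) {
  if (is.list(events_bycycle) && !is.data.frame(events_bycycle))
    events_bycycle <- events_bycycle$events
  if (!nrow(events_power) || !nrow(events_bycycle))
    return(.empty_events())
  keep <- .overlaps_any(events_power$start_s, events_power$stop_s,
                        events_bycycle$start_s, events_bycycle$stop_s)
  out <- events_power[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition ripples into SPW-coupled and solo events
#'
#' A ripple co-occurs with a sharp wave when its interval overlaps (non-zero
#' overlap, half-open convention) the SPW window
#' `[peak - halfwidth/2, peak + halfwidth/2)`.
#'
#' @param ripples Ripple event table (e.g. from [consensus_ripples()]).
#' @param spws SPW event table from [detect_spw()] (needs `peak_s` and
#'   `halfwidth_s`).
#' @return List with `spwr` (coupled, kind set to `"spwr"`) and `solo`
#'   (kind `"solo_ripple"`); the two partitions are disjoint and exhaustive.
#' @export
couple_to_spw <- function(ripples, spws) {
  if (!nrow(ripples))
    return(list(spwr = .empty_events(), solo = .empty_events()))
  if (!nrow(spws)) {
    solo <- ripples; solo$kind <- "solo_ripple"
    return(list(spwr = .empty_events(), solo = solo))
  }
  ws <- spws$peak_s - spws$halfwidth_s / 2
  we <- spws$peak_s + spws$halfwidth_s / 2
  coupled <- .overlaps_any(ripples$start_s, ripples$stop_s, ws, we)
  spwr <- ripples[coupled, , drop = FALSE]
  solo <- ripples[!coupled, , drop = FALSE]
  if (nrow(spwr)) spwr$kind <- "spwr"
  if (nrow(solo)) solo$kind <- "solo_ripple"
  rownames(spwr) <- rownames(solo) <- NULL
  list(spwr = spwr, solo = solo)
}

#' Classify ripples as short or long
#'
#' A ripple counts as long when it spans at least `min_cycles` oscillatory
#' cycles (`duration * peak frequency`), the lower bound of the adult 3-9
#' cycle range; 30 ms at 100 Hz (3.0 cycles) is the boundary case and counts
#' as long.
#'
#' @param ripples Ripple event table with `peak_freq_hz` per event.
#' @param min_cycles Cycle cutoff for the long class.
#' @return The input table with added `class` (`"short"`/`"long"`) and
#'   recomputed `n_cycles`.
#' @export
classify_ripple_length <- function(ripples, min_cycles = 3) {
  if (!nrow(ripples)) {
    ripples$class <- character(0)
    return(ripples)
  }
  if (any(is.na(ripples$peak_freq_hz)))
    stop("`peak_freq_hz` required for every event", call. = FALSE)
  cyc <- (ripples$stop_s - ripples$start_s) * ripples$peak_freq_hz
  ripples$n_cycles <- cyc
  ripples$class <- ifelse(cyc >= min_cycles, "long", "short")
  ripples
}

#' Detect induced high-frequency oscillations in stimulation windows
#'
#' Runs both ripple detectors inside each stimulation window (with the
#' 120 ms induced-event length bound) and reports the consensus events plus
#' the fraction of windows containing at least one.
#'
#' @param x Pyramidal-layer LFP (uV).
#' @param fs Sampling rate, Hz.
#' @param stim_windows Two-column matrix or data.frame of window start/stop
#'   times (s).
#' @param ... Passed to [detect_ripples_power()] /
#'   [detect_ripples_bycycle()] (e.g. `band`).
#' @return List with `events` (kind `"ihfo"`) and `fraction_with_ihfo`.
#' @export
detect_ihfo <- function(x, fs, stim_windows, ...) {
  stim_windows <- as.matrix(stim_windows)
  if (!nrow(stim_windows)) stop("`stim_windows` must be non-empty",
                                call. = FALSE)
  # detect on the full trace (thresholds need the global noise statistics),
  # then restrict to windows
  pow <- detect_ripples_power(x, fs, max_len_ms = 120, ...)
  byc <- detect_ripples_bycycle(x, fs, ...)
  cons <- consensus_ripples(pow, byc)
  hit <- logical(nrow(stim_windows))
  keep <- logical(nrow(cons))
  for (i in seq_len(nrow(stim_windows))) {
    ov <- cons$start_s < stim_windows[i, 2] & stim_windows[i, 1] < cons$stop_s
    hit[i] <- any(ov)
    keep <- keep | ov
  }
  ev <- cons[keep, , drop = FALSE]
  if (nrow(ev)) ev$kind <- "ihfo"
  rownames(ev) <- NULL
  list(events = ev, fraction_with_ihfo = mean(hit))
}

#' Detect movement periods from tracked coordinates
#'
#' Flags a video frame as movement when any tracked reference point displaces
#' strictly more than `px_threshold` pixels from the previous frame;
#' consecutive flagged frames are merged into intervals.
#'
#' @param xy Either an n x 2 matrix (one tracked point) or a list of n x 2
#'   matrices (one per point), in pixels.
#' @param frame_rate Frames per second.
#' @param px_threshold Displacement threshold in pixels (strict inequality).
#' @return Event table with kind `"movement"`.
#' @export
detect_movement <- function(xy, frame_rate = 14.3, px_threshold = 25) {
  if (!is.list(xy)) xy <- list(xy)
  n <- nrow(xy[[1]])
  if (n < 2L) return(.empty_events())
  moved <- rep(FALSE, n - 1L)
  for (pt in xy) {
    d <- sqrt(rowSums(diff(as.matrix(pt))^2))
    moved <- moved | d > px_threshold
  }
  # frame i+1 is a movement frame when the step into it exceeds the threshold
  runs <- .runs_true(moved)
  if (!nrow(runs)) return(.empty_events())
  .as_events("movement", start_s = runs$start / frame_rate,
             stop_s = (runs$stop + 1L) / frame_rate)
}
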