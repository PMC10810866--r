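#' Specification for a synthetic neonatal CA1 recording
#'
#' Bundles every parameter of the ground-truthed recording generator
#' [make_recording()]. The defaults emulate a developing (first-postnatal-week)
#' CA1 recording: a discontinuous 1/f^chi background punctuated by sharp waves
#' (SPWs) that reverse polarity across the pyramidal layer, a fraction of which
#' carry a fast (80-200 Hz) ripple burst, and sparse unit firing whose
#' population rate is transiently raised around SPW peaks.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz; must be at least `4 * ripple_freq_hz`.
#' @param aperiodic_exponent Exponent chi of the 1/f^chi background spectrum.
#' @param aperiodic_offset log10 power of the background at 1 Hz (uV^2/Hz).
#' @param active_fraction Fraction of time carrying oscillatory background;
#'   the remainder is near-isoelectric, as in neonatal recordings.
#' @param spw_rate SPW rate, events per minute.
#' @param spw_amplitude_uV Mean absolute SPW peak deflection (uV) on the
#'   radial channel.
#' @param spw_halfwidth_ms SPW full width at half maximum, ms.
#' @param ripple_prob Probability that an SPW carries a ripple burst.
#' @param ripple_freq_hz Ripple carrier frequency, Hz.
#' @param ripple_cycles Number of carrier cycles per ripple burst.
#' @param ripple_amplitude_uV Peak ripple envelope amplitude, uV.
#' @param n_units Number of simulated single units.
#' @param baseline_rate_hz Mean per-unit baseline firing rate, Hz.
#' @param spw_modulation_z Target z-score of the population peri-event rate at
#'   the SPW peak (z-scored as in [peth_z()] with its default 10 ms bins).
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return An object of class `synth_spec` (a validated list).
#' @seealso [make_recording()]
#' @export
synth_spec <- function(duration_s = 600, fs = 1000,
                       aperiodic_exponent = 2, aperiodic_offset = 2.5,
                       active_fraction = 0.6,
                       spw_rate = 4, spw_amplitude_uV = 300,
                       spw_halfwidth_ms = 60,
                       ripple_prob = 0.5, ripple_freq_hz = 140,
                       ripple_cycles = 6, ripple_amplitude_uV = 60,
                       n_units = 40, baseline_rate_hz = 1,
                       spw_modulation_z = 3, seed = 1L) {
  .check_num(duration_s, "duration_s", positive = TRUE)
  .check_num(fs, "fs", positive = TRUE)
  .check_num(aperiodic_exponent, "aperiodic_exponent", nonneg = TRUE)
  .check_num(aperiodic_offset, "aperiodic_offset")
  .check_frac(active_fraction, "active_fraction")
  .check_num(spw_rate, "spw_rate", positive = TRUE)
  .check_num(spw_amplitude_uV, "spw_amplitude_uV", positive = TRUE)
  .check_num(spw_halfwidth_ms, "spw_halfwidth_ms", positive = TRUE)
  .check_frac(ripple_prob, "ripple_prob")
  .check_num(ripple_freq_hz, "ripple_freq_hz", positive = TRUE)
  .check_num(ripple_cycles, "ripple_cycles", positive = TRUE)
  .check_num(ripple_amplitude_uV, "ripple_amplitude_uV", positive = TRUE)
  .check_num(n_units, "n_units", positive = TRUE)
  .check_num(baseline_rate_hz, "baseline_rate_hz", positive = TRUE)
  .check_num(spw_modulation_z, "spw_modulation_z", positive = TRUE)
  if (fs < 4 * ripple_freq_hz)
    stop("`fs` must be at least 4 * ripple_freq_hz", call. = FALSE)
  spec <- list(duration_s = duration_s, fs = fs,
               aperiodic_exponent = aperiodic_exponent,
               aperiodic_offset = aperiodic_offset,
               active_fraction = active_fraction, spw_rate = spw_rate,
               spw_amplitude_uV = spw_amplitude_uV,
               spw_halfwidth_ms = spw_halfwidth_ms,
               ripple_prob = ripple_prob, ripple_freq_hz = ripple_freq_hz,
               ripple_cycles = ripple_cycles,
               ripple_amplitude_uV = ripple_amplitude_uV,
               n_units = as.integer(n_units),
               baseline_rate_hz = baseline_rate_hz,
               spw_modulation_z = spw_modulation_z, seed = as.integer(seed))
  class(spec) <- "synth_spec"
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic CA1 recording spec:", x$duration_s, "s at", x$fs, "Hz\n")
  cat("  background: 1/f^", x$aperiodic_exponent, ", offset ",
      x$aperiodic_offset, ", active fraction ", x$active_fraction, "\n",
      sep = "")
  cat("  SPWs:", x$spw_rate, "/min,", x$spw_amplitude_uV, "uV, FWHM",
      x$spw_halfwidth_ms, "ms; ripple prob", x$ripple_prob, "at",
      x$ripple_freq_hz, "Hz\n")
  cat("  units:", x$n_units, "at", x$baseline_rate_hz,
      "Hz baseline, SPW modulation z =", x$spw_modulation_z, "\n")
  invisible(x)
}

# Evaluate expr under a local RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate 1/f^chi aperiodic background noise
#'
#' Synthesizes Gaussian noise whose one-sided power spectral density follows
#' `10^offset / f^exponent`, by shaping the spectrum of white noise with a
#' `1/f^(exponent/2)` amplitude filter and inverse transforming. The log-log
#' slope of a Welch spectrum of the output equals `-exponent` up to finite
#' sample error.
#'
#' @param duration_s Length in seconds.
#' @param fs Sampling rate, Hz.
#' @param exponent Aperiodic exponent chi (>= 0); 0 gives white noise.
#' @param offset log10 power at 1 Hz.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return Numeric vector of `duration_s * fs` samples (uV).
#' @export
make_aperiodic_noise <- function(duration_s, fs, exponent, offset = 0,
                                 seed = 1L) {
  .check_num(duration_s, "duration_s", positive = TRUE)
  .check_num(fs, "fs", positive = TRUE)
  .check_num(exponent, "exponent", nonneg = TRUE)
  .check_num(offset, "offset")
  n <- as.integer(round(duration_s * fs))
  .with_seed(seed, {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
    # two-sided layout: mirror frequencies above Nyquist
    f <- pmin(f, fs - f)
    s <- numeric(n)
    pos <- f > 0
    s[pos] <- sqrt(10^offset / f[pos]^exponent * fs / 2)
    y <- Re(stats::fft(W * s, inverse = TRUE)) / n
    y
  })
}

#' Gaussian sharp-wave waveform
#'
#' A Gaussian-shaped LFP deflection whose extremum equals `amplitude_uV` and
#' whose full width at half maximum equals `halfwidth_ms`.
#'
#' @param amplitude_uV Peak deflection, uV (sign gives polarity; non-zero).
#' @param halfwidth_ms Full width at half maximum, ms.
#' @param fs Sampling rate, Hz; must resolve the FWHM with >= 8 samples.
#' @return Numeric waveform spanning +/- 3 SD of the Gaussian.
#' @export
make_spw_waveform <- function(amplitude_uV, halfwidth_ms, fs) {
  .check_num(amplitude_uV, "amplitude_uV")
  if (amplitude_uV == 0) stop("`amplitude_uV` must be non-zero", call. = FALSE)
  .check_num(halfwidth_ms, "halfwidth_ms", positive = TRUE)
  .check_num(fs, "fs", positive = TRUE)
  if (fs * halfwidth_ms / 1000 < 8)
    stop("`fs` too low: fewer than 8 samples across the FWHM", call. = FALSE)
  sd_s <- halfwidth_ms / 1000 / (2 * sqrt(2 * log(2)))
  half <- as.integer(ceiling(3 * sd_s * fs))
  t <- (-half:half) / fs
  amplitude_uV * exp(-t^2 / (2 * sd_s^2))
}

#' Hann-windowed ripple burst waveform
#'
#' A sinusoid at `freq_hz` under a Hann envelope lasting exactly
#' `n_cycles / freq_hz` seconds, e.g. 3 cycles at 100 Hz give a 30 ms burst.
#'
#' @param freq_hz Carrier frequency, Hz.
#' @param n_cycles Number of carrier cycles (>= 1).
#' @param amplitude_uV Envelope peak amplitude; all samples are bounded by it.
#' @param fs Sampling rate, Hz; must exceed `4 * freq_hz`.
#' @return Numeric waveform of `round(n_cycles / freq_hz * fs)` samples.
#' @export
make_ripple_waveform <- function(freq_hz, n_cycles, amplitude_uV, fs) {
  .check_num(freq_hz, "freq_hz", positive = TRUE)
  .check_num(n_cycles, "n_cycles", positive = TRUE)
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  .check_num(amplitude_uV, "amplitude_uV", positive = TRUE)
  .check_num(fs, "fs", positive = TRUE)
  if (fs < 4 * freq_hz)
    stop("`fs` below 4x the carrier frequency would alias the ripple",
         call. = FALSE)
  n <- as.integer(round(n_cycles / freq_hz * fs))
  t <- seq_len(n) / fs
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  amplitude_uV * hann * sin(2 * pi * freq_hz * t)
}

# Binary activity mask with alternating exponential on/off epochs tuned to
# active_fraction; 10 ms cosine ramps avoid step discontinuities.
.activity_mask <- function(n, fs, active_fraction) {
  if (active_fraction >= 1) return(rep(1, n))
  if (active_fraction <= 0) return(rep(0, n))
  mean_on <- 2 * fs                                  # 2 s mean active epoch
  mean_off <- mean_on * (1 - active_fraction) / active_fraction
  mask <- numeric(n)
  pos <- 1L
  on <- stats::runif(1) < active_fraction
  while (pos <= n) {
    len <- max(1L, as.integer(stats::rexp(1, 1 / if (on) mean_on else mean_off)))
    if (on) mask[pos:min(n, pos + len - 1L)] <- 1
    pos <- pos + len
    on <- !on
  }
  ramp <- as.integer(0.01 * fs)
  if (ramp > 1) mask <- .boxcar(mask, ramp)          # 10 ms edge ramps
  mask
}

#' Generate a ground-truthed synthetic CA1 recording
#'
#' Composes a two-channel (stratum pyramidale, stratum radiale) LFP, per-unit
#' spike trains, and an exact truth table of injected events. SPWs appear with
#' opposite polarity on the two channels (the laminar reversal); a fraction
#' `ripple_prob` of SPWs carry a ripple burst on the pyramidale channel; unit
#' firing is inhomogeneous Poisson with a Gaussian rate gain around SPW peaks
#' calibrated so the population peri-event z at the SPW peak is approximately
#' `spw_modulation_z`.
#'
#' @param spec A [synth_spec()] object.
#' @return A list with elements `lfp` (samples x 2 matrix, uV; columns
#'   `pyramidale`, `radiale`), `fs`, `depths_um`, `spikes` (list of per-unit
#'   spike-time vectors, s), `truth` (event table of kinds `spw` and `ripple`),
#'   and `unit_modulation` (per-unit injected gain).
#' @export
make_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  fs <- spec$fs
  exp_events <- spec$spw_rate * spec$duration_s / 60
  if (exp_events < 1 && spec$ripple_prob > 0)
    warning("fewer than one SPW expected over the recording; ",
            "ripple events may be absent")
  .with_seed(spec$seed, {
    pyr <- make_aperiodic_noise(spec$duration_s, fs, spec$aperiodic_exponent,
                                spec$aperiodic_offset,
                                seed = spec$seed + 1000L)
    rad <- make_aperiodic_noise(spec$duration_s, fs, spec$aperiodic_exponent,
                                spec$aperiodic_offset,
                                seed = spec$seed + 2000L)
    mask <- .activity_mask(n, fs, spec$active_fraction)
    pyr <- pyr * mask
    rad <- rad * mask

    # --- SPW placement: Poisson count, uniform times, >= 1 s separation
    pad <- 0.5 + 3 * spec$spw_halfwidth_ms / 1000
    n_spw <- stats::rpois(1, exp_events)
    t_spw <- numeric(0)
    tries <- 0L
    while (length(t_spw) < n_spw && tries < 200L) {
      cand <- stats::runif(n_spw - length(t_spw), pad, spec$duration_s - pad)
      t_spw <- sort(c(t_spw, cand))
      ok <- c(TRUE, diff(t_spw) > 1)
      t_spw <- t_spw[ok]
      tries <- tries + 1L
    }
    n_spw <- length(t_spw)

    hw_s <- spec$spw_halfwidth_ms / 1000
    amp <- spec$spw_amplitude_uV * pmax(0.5, stats::rnorm(n_spw, 1, 0.15))
    wshape <- make_spw_waveform(1, spec$spw_halfwidth_ms, fs)
    half_w <- (length(wshape) - 1L) %/% 2L
    for (i in seq_len(n_spw)) {
      c_idx <- as.integer(round(t_spw[i] * fs))
      idx <- (c_idx - half_w):(c_idx + half_w)
      keep <- idx >= 1L & idx <= n
      rad[idx[keep]] <- rad[idx[keep]] - amp[i] * wshape[keep]
      pyr[idx[keep]] <- pyr[idx[keep]] + 0.5 * amp[i] * wshape[keep]
    }

    # --- ripples on a random subset of SPWs, centered on the SPW peak
    has_rip <- if (n_spw > 0) stats::runif(n_spw) < spec$ripple_prob else logical(0)
    rip_w <- make_ripple_waveform(spec$ripple_freq_hz, spec$ripple_cycles,
                                  spec$ripple_amplitude_uV, fs)
    rip_len <- length(rip_w)
    rip_t <- t_spw[has_rip]
    for (tt in rip_t) {
      s_idx <- as.integer(round(tt * fs)) - rip_len %/% 2L
      idx <- s_idx:(s_idx + rip_len - 1L)
      keep <- idx >= 1L & idx <= n
      pyr[idx[keep]] <- pyr[idx[keep]] + rip_w[keep]
    }

    # --- spikes: baseline Poisson + per-event Gaussian-locked extra spikes
    sd_gain <- hw_s / (2 * sqrt(2 * log(2)))
    bin_s <- 0.01                     # matches peth_z default binning
    kappa <- (stats::pnorm(bin_s / 2, 0, sd_gain) -
              stats::pnorm(-bin_s / 2, 0, sd_gain)) / (bin_s) * sd_gain *
             sqrt(2 * pi)            # mean profile value over the peak bin
    r0 <- spec$baseline_rate_hz
    n_anch <- max(1L, n_spw)
    gain <- spec$spw_modulation_z /
      (kappa * sqrt(r0 * spec$n_units * bin_s * n_anch))
    unit_gain <- gain * stats::rgamma(spec$n_units, shape = 25, rate = 25)
    spikes <- vector("list", spec$n_units)
    for (u in seq_len(spec$n_units)) {
      n_base <- stats::rpois(1, r0 * spec$duration_s)
      st <- stats::runif(n_base, 0, spec$duration_s)
      if (n_spw > 0 && unit_gain[u] > 0) {
        lam_ev <- r0 * unit_gain[u] * sd_gain * sqrt(2 * pi)
        n_ev <- stats::rpois(n_spw, lam_ev)
        extra <- stats::rnorm(sum(n_ev), rep(t_spw, n_ev), sd_gain)
        st <- c(st, extra[extra > 0 & extra < spec$duration_s])
      }
      spikes[[u]] <- sort(st)
    }

    truth <- rbind(
      .as_events("spw", start_s = t_spw - hw_s, stop_s = t_spw + hw_s,
                 peak_s = t_spw, peak_amp = amp, halfwidth_s = hw_s),
      .as_events("ripple",
                 start_s = rip_t - rip_len / fs / 2,
                 stop_s = rip_t + rip_len / fs / 2,
                 peak_s = rip_t, peak_amp = spec$ripple_amplitude_uV,
                 n_cycles = spec$ripple_cycles,
                 peak_freq_hz = spec$ripple_freq_hz))
    truth <- truth[order(truth$start_s), , drop = FALSE]
    rownames(truth) <- NULL

    list(lfp = cbind(pyramidale = pyr, radiale = rad), fs = fs,
         depths_um = c(pyramidale = 0, radiale = -100),
         spikes = spikes, truth = truth, unit_modulation = unit_gain)
  })
}

#' Synthetic developmental trend table for breakpoint-fit validation
#'
#' Piecewise-linear mean over an age axis plus Gaussian noise, with the
#' generating parameters returned alongside the data, as a fixture for
#' [piecewise_linear_fit()].
#'
#' @param slopes Numeric vector of segment slopes (length `n_breakpoints + 1`).
#' @param breakpoints Strictly increasing breakpoints, interior to `x_range`.
#' @param noise_sd Gaussian noise SD added to the mean.
#' @param n_per_x Replicates per x value.
#' @param seed Integer seed.
#' @param x_range Range of the age axis (default postnatal days 4 to 12).
#' @param intercept Mean value at `x_range[1]`.
#' @return List with `data` (data.frame x, y) and `truth` (generating
#'   parameters).
#' @export
make_age_trend_table <- function(slopes, breakpoints = numeric(0),
                                 noise_sd = 0.2, n_per_x = 12, seed = 1L,
                                 x_range = c(4, 12), intercept = 0) {
  if (length(slopes) != length(breakpoints) + 1L)
    stop("`slopes` must have one more element than `breakpoints`",
         call. = FALSE)
  if (length(breakpoints) &&
      (is.unsorted(breakpoints, strictly = TRUE) ||
       any(breakpoints <= x_range[1]) || any(breakpoints >= x_range[2])))
    stop("`breakpoints` must be strictly increasing and inside `x_range`",
         call. = FALSE)
  .check_num(noise_sd, "noise_sd", nonneg = TRUE)
  xs <- rep(seq(x_range[1], x_range[2], by = 1), each = n_per_x)
  mu <- intercept + slopes[1] * (xs - x_range[1])
  if (length(breakpoints)) {
    for (k in seq_along(breakpoints)) {
      d <- slopes[k + 1] - slopes[k]
      mu <- mu + d * pmax(0, xs - breakpoints[k])
    }
  }
  y <- .with_seed(seed, mu + stats::rnorm(length(xs), 0, noise_sd))
  list(data = data.frame(x = xs, y = y),
       truth = list(slopes = slopes, breakpoints = breakpoints,
                    noise_sd = noise_sd, intercept = intercept))
}
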