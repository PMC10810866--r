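#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered overlapping segments (defaults:
#' 1 s windows overlapping by 250 ms), scaled as a one-sided density so that
#' the integral over frequency approximates the signal variance.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window_s Segment length, seconds.
#' @param overlap_s Overlap between consecutive segments, seconds.
#' @return A data.frame of class `psd` with columns `freq` (Hz, excluding DC)
#'   and `power` (linear units^2/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1.0, overlap_s = 0.25) {
  .check_num(fs, "fs", positive = TRUE)
  nw <- as.integer(round(window_s * fs))
  if (length(x) < nw)
    stop("signal shorter than one Welch window", call. = FALSE)
  step <- nw - as.integer(round(overlap_s * fs))
  if (step < 1L) stop("`overlap_s` must be smaller than `window_s`",
                      call. = FALSE)
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  u <- sum(w^2)
  nf <- nw %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf + 1L)]
    acc <- acc + (Mod(X)^2)
  }
  p <- acc / length(starts) / (fs * u)
  # one-sided: double all bins except DC and Nyquist
  if (nf >= 2L) p[2:nf] <- 2 * p[2:nf]
  freq <- seq(0, nf) * fs / nw
  out <- data.frame(freq = freq[-1L], power = p[-1L])
  class(out) <- c("psd", "data.frame")
  out
}

#' Notch out the line frequency and its harmonics
#'
#' Applies a battery of narrow second-order IIR notch filters (zero-phase,
#' forward-backward) at `base_hz`, `2*base_hz`, ... up to `n_harmonics`
#' multiples, attenuating each center by well over 20 dB while leaving the
#' signal 5 Hz away essentially untouched.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param base_hz Line frequency (default 50 Hz).
#' @param n_harmonics Number of harmonics to notch (including the base).
#' @param bw_hz Notch -3 dB bandwidth, Hz.
#' @return Filtered signal, same length as `x`.
#' @export
notch_line <- function(x, fs, base_hz = 50, n_harmonics = 3, bw_hz = 2) {
  .check_num(fs, "fs", positive = TRUE)
  .check_num(base_hz, "base_hz", positive = TRUE)
  if (base_hz >= fs / 2) stop("`base_hz` must be below Nyquist", call. = FALSE)
  y <- as.numeric(x)
  for (k in seq_len(n_harmonics)) {
    f0 <- k * base_hz
    if (f0 >= fs / 2) break
    # RBJ biquad notch
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) * sinh(log(2) / 2 * (bw_hz / f0) * w0 / sin(w0))
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    y <- as.numeric(signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]),
                                     y))
  }
  y
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Separates a PSD, in log10-log10 space, into an aperiodic `offset + exponent`
#' component (fixed mode, no knee) and at most one Gaussian oscillatory peak.
#' The aperiodic slope is fit robustly: bins lying far above the line
#' (putative peaks) are iteratively down-weighted so they cannot bias the
#' exponent. If `max_peaks = 1` and the largest positive residual exceeds
#' `peak_threshold` residual SDs, a Gaussian (center, height, width) is fit to
#' the residual under the width limits, and the aperiodic component is refit
#' on the peak-subtracted spectrum. Goodness of fit (`r2`) is computed between
#' model and data in log-power space.
#'
#' @param psd A `psd` data.frame from [welch_psd()] (or any data.frame with
#'   `freq` and `power`).
#' @param f_range Length-2 numeric fit range in Hz, e.g. `c(25, 45)` for
#'   aperiodic (E-I proxy) fits or `c(70, 200)` for fast-oscillation fits.
#' @param max_peaks 0 or 1 Gaussian peaks.
#' @param peak_threshold Minimum peak height in units of residual SD.
#' @param width_limits Allowed peak full bandwidth range, Hz.
#' @return Object of class `spectral_fit`: list with `offset`, `exponent`,
#'   `peaks` (data.frame center_freq_hz, peak_power, bandwidth_hz), `r2`,
#'   `f_range`, and fitted values.
#' @export
fit_spectrum <- function(psd, f_range, max_peaks = 1,
                         peak_threshold = 4.5, width_limits = c(2, 60)) {
  stopifnot(is.data.frame(psd), all(c("freq", "power") %in% names(psd)))
  if (!max_peaks %in% c(0, 1)) stop("`max_peaks` must be 0 or 1",
                                    call. = FALSE)
  sel <- psd$freq >= f_range[1] & psd$freq <= f_range[2]
  if (sum(sel) < 10L)
    stop("need at least 10 PSD bins inside `f_range`", call. = FALSE)
  f <- psd$freq[sel]; p <- psd$power[sel]
  if (any(p <= 0)) stop("non-positive power bins in fit range", call. = FALSE)
  lf <- log10(f); lp <- log10(p)

  ap_fit <- function(lf, lp) {
    w <- rep(1, length(lf))
    co <- NULL
    for (it in 1:10) {
      co <- stats::lm.wfit(cbind(1, lf), lp, w)$coefficients
      res <- lp - (co[1] + co[2] * lf)
      s <- stats::mad(res)               # robust scale: peaks are outliers
      if (s == 0) s <- stats::sd(res)
      if (s == 0) break
      w_new <- ifelse(res > 2.5 * s, 0, 1)   # drop bins far above the line
      if (all(w_new == w)) break
      w <- w_new
    }
    co
  }

  co <- ap_fit(lf, lp)
  model_peak <- rep(0, length(lf))
  peaks <- data.frame(center_freq_hz = numeric(0), peak_power = numeric(0),
                      bandwidth_hz = numeric(0))
  if (max_peaks == 1) {
    res <- lp - (co[1] + co[2] * lf)
    # robust residual scale: a genuine peak must not inflate its own
    # detection threshold
    s <- stats::mad(res)
    if (s == 0) s <- stats::sd(res)
    i_max <- which.max(res)
    if (s > 0 && res[i_max] >= peak_threshold * s) {
      sd_lim <- width_limits / (2 * sqrt(2 * log(2)))  # FWHM -> SD
      fit_gauss <- function(res) {
        i0 <- which.max(res)
        g <- function(par)
          sum((res - par[2] * exp(-(f - par[1])^2 / (2 * par[3]^2)))^2)
        stats::optim(c(f[i0], max(res[i0], 1e-3), mean(sd_lim)), g,
                     method = "L-BFGS-B",
                     lower = c(f_range[1], 0, sd_lim[1]),
                     upper = c(f_range[2], Inf, sd_lim[2]))
      }
      # alternate Gaussian fit and aperiodic refit so an imperfect first
      # slope cannot distort the peak (and vice versa)
      ok <- FALSE
      for (pass in 1:3) {
        opt <- fit_gauss(lp - (co[1] + co[2] * lf))
        if (opt$convergence != 0 || opt$par[2] <= 0) break
        ok <- TRUE
        mu <- opt$par[1]; h <- opt$par[2]; sdv <- opt$par[3]
        model_peak <- h * exp(-(f - mu)^2 / (2 * sdv^2))
        co <- ap_fit(lf, lp - model_peak)
      }
      if (ok) {
        peaks <- data.frame(center_freq_hz = mu, peak_power = h,
                            bandwidth_hz = 2 * sqrt(2 * log(2)) * sdv)
      } else {
        model_peak <- rep(0, length(lf))
      }
    }
  }
  model <- co[1] + co[2] * lf + model_peak
  ss_res <- sum((lp - model)^2)
  ss_tot <- sum((lp - mean(lp))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NaN
  out <- list(offset = unname(co[1]), exponent = unname(-co[2]),
              peaks = peaks, r2 = r2, f_range = f_range,
              freq = f, log_power = lp, fitted = model)
  class(out) <- "spectral_fit"
  out
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("Spectral parameterization over", x$f_range[1], "-", x$f_range[2],
      "Hz\n")
  cat(sprintf("  aperiodic: offset %.3f, exponent %.3f\n", x$offset,
              x$exponent))
  if (nrow(x$peaks)) {
    cat(sprintf("  peak: %.1f Hz, height %.3f log10-units, bandwidth %.1f Hz\n",
                x$peaks$center_freq_hz, x$peaks$peak_power,
                x$peaks$bandwidth_hz))
  } else cat("  no periodic peak\n")
  cat(sprintf("  R^2 = %.4f\n", x$r2))
  invisible(x)
}

#' @export
coef.spectral_fit <- function(object, ...) {
  c(offset = object$offset, exponent = object$exponent)
}

#' Predicted log10 power of a spectral parameterization
#' @param object A `spectral_fit`.
#' @param freq Frequencies (Hz) at which to evaluate; defaults to the fitted
#'   bins.
#' @param ... Unused.
#' @export
predict.spectral_fit <- function(object, freq = NULL, ...) {
  if (is.null(freq)) freq <- object$freq
  lp <- object$offset - object$exponent * log10(freq)
  if (nrow(object$peaks)) {
    sdv <- object$peaks$bandwidth_hz / (2 * sqrt(2 * log(2)))
    lp <- lp + object$peaks$peak_power *
      exp(-(freq - object$peaks$center_freq_hz)^2 / (2 * sdv^2))
  }
  lp
}

#' Fit-quality gate
#'
#' Accepts a spectral parameterization only if its R-squared reaches
#' `r2_min` (inclusive; the default reproduces the >= 0.95 criterion used for
#' developmental E-I estimation).
#'
#' @param fit A `spectral_fit` object.
#' @param r2_min Minimum acceptable R-squared.
#' @return Logical: `TRUE` if accepted.
#' @export
quality_gate <- function(fit, r2_min = 0.95) {
  stopifnot(inherits(fit, "spectral_fit"))
  isTRUE(!is.nan(fit$r2) && fit$r2 >= r2_min)
}
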