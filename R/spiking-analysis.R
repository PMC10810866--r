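# Event-locked spiking metrics and the piecewise-linear developmental fit.

# Pool spikes from a list of per-unit trains into one sorted vector.
.pool_spikes <- function(spikes) sort(unlist(spikes, use.names = FALSE))

# Population PETH: mean per-unit rate (Hz) per bin around anchors.
.peth_rate <- function(spikes, anchors, window_s, bin_s, n_units) {
  edges <- seq(-window_s, window_s, by = bin_s)
  centers <- edges[-1L] - bin_s / 2
  pooled <- .pool_spikes(spikes)
  counts <- numeric(length(centers))
  for (a in anchors) {
    rel <- pooled[pooled >= a - window_s & pooled < a + window_s] - a
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges,
                                               rightmost.closed = FALSE),
                                  nbins = length(centers))
  }
  rate <- counts / (length(anchors) * bin_s * n_units)
  list(centers = centers, rate = rate)
}

# Random baseline anchors outside all event windows.
.baseline_anchors <- function(n, duration, events, window_s, seed = NULL) {
  draw <- function() {
    out <- numeric(0)
    tries <- 0L
    while (length(out) < n && tries < 500L) {
      cand <- stats::runif(2L * n, window_s, duration - window_s)
      if (nrow(events)) {
        bad <- vapply(cand, function(tt)
          any(tt + window_s > events$start_s & events$stop_s > tt - window_s),
          logical(1))
        cand <- cand[!bad]
      }
      out <- c(out, cand)
      tries <- tries + 1L
    }
    out[seq_len(min(n, length(out)))]
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Peri-event time histogram with baseline z-scoring
#'
#' Population firing rate binned relative to event anchors, z-scored against
#' a baseline PETH computed at an equal number of random anchors drawn outside
#' all event windows: `z = (rate - baseline mean) / baseline SD`, with the
#' baseline moments taken over the bins of the baseline PETH.
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param anchors Event anchor times (s), e.g. SPW peaks.
#' @param duration_s Recording duration (s), used to draw baseline anchors.
#' @param window_s Half window around each anchor, s.
#' @param bin_s Bin width, s.
#' @param events Optional event table whose windows baseline anchors must
#'   avoid; defaults to `anchors +/- window_s`.
#' @param seed Seed for the baseline anchor draw.
#' @return Object of class `peth`: list with `centers`, `rate`, `z`,
#'   `n_events`, `baseline` (mean, sd), and a `degenerate` flag set when no
#'   spikes (or a zero-variance baseline) make the z-score undefined.
#' @export
peth_z <- function(spikes, anchors, duration_s, window_s = 0.2, bin_s = 0.01,
                   events = NULL, seed = 1L) {
  if (!length(anchors)) stop("at least one anchor is required", call. = FALSE)
  n_units <- length(spikes)
  ev <- if (is.null(events))
    data.frame(start_s = anchors - window_s, stop_s = anchors + window_s)
  else events
  ph <- .peth_rate(spikes, anchors, window_s, bin_s, n_units)
  base_anchors <- .baseline_anchors(length(anchors), duration_s, ev,
                                    window_s, seed = seed)
  bh <- .peth_rate(spikes, base_anchors, window_s, bin_s, n_units)
  mu <- mean(bh$rate); sdv <- stats::sd(bh$rate)
  degenerate <- !is.finite(sdv) || sdv == 0 ||
    sum(vapply(spikes, length, integer(1))) == 0L
  z <- if (degenerate) rep(NA_real_, length(ph$rate)) else (ph$rate - mu) / sdv
  out <- list(centers = ph$centers, rate = ph$rate, z = z,
              n_events = length(anchors),
              baseline = c(mean = mu, sd = sdv), degenerate = degenerate,
              window_s = window_s, bin_s = bin_s)
  class(out) <- "peth"
  out
}

#' @export
print.peth <- function(x, ...) {
  cat("PETH over", x$n_events, "events;", length(x$centers), "bins of",
      x$bin_s * 1000, "ms\n")
  if (x$degenerate) cat("  degenerate: z undefined\n")
  else cat(sprintf("  peak z = %.2f at %+.0f ms\n", max(x$z),
                   1000 * x$centers[which.max(x$z)]))
  invisible(x)
}

#' @export
plot.peth <- function(x, ...) {
  graphics::plot(x$centers * 1000, x$z, type = "l", xlab = "time (ms)",
                 ylab = "population rate (z)", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Fraction of events with modulated population spiking
#'
#' Computes, per event, the z-scored population rate in a window around the
#' event peak (baseline from random anchors) and reports the fraction of
#' events whose maximum z reaches `z_crit`.
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param events Event table with `peak_s` (e.g. SPWs).
#' @param duration_s Recording duration, s.
#' @param z_crit Modulation criterion on the per-event max z (default 2).
#' @param window_s Half window around the peak, s.
#' @param bin_s Bin width, s.
#' @param seed Seed for baseline anchors.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_modulated_events <- function(spikes, events, duration_s, z_crit = 2,
                                      window_s = 0.05, bin_s = 0.01,
                                      seed = 1L) {
  if (z_crit <= 0) stop("`z_crit` must be > 0", call. = FALSE)
  if (!nrow(events)) stop("no events supplied", call. = FALSE)
  n_units <- length(spikes)
  base_anchors <- .baseline_anchors(max(50L, nrow(events)), duration_s,
                                    events, window_s, seed = seed)
  # baseline distribution of single-anchor bin rates
  pooled <- .pool_spikes(spikes)
  bin_rate <- function(a) {
    edges <- seq(a - window_s, a + window_s, by = bin_s)
    rel <- pooled[pooled >= a - window_s & pooled < a + window_s]
    tabulate(findInterval(rel, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1L) / (bin_s * n_units)
  }
  base_rates <- unlist(lapply(base_anchors, bin_rate))
  mu <- mean(base_rates); sdv <- stats::sd(base_rates)
  if (!is.finite(sdv) || sdv == 0) return(NA_real_)
  max_z <- vapply(events$peak_s, function(a) max((bin_rate(a) - mu) / sdv),
                  numeric(1))
  mean(max_z >= z_crit)
}

#' First-spike offsets relative to the SPW peak
#'
#' For every (unit, event) pair, the time of the unit's first spike inside
#' the event window minus the SPW peak time; units silent in an event
#' contribute nothing for that event.
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param events Event table with `peak_s`, `start_s`, `stop_s`.
#' @return List with `offsets` (numeric, s) and `cdf` (the empirical CDF
#'   function).
#' @export
first_spike_offsets <- function(spikes, events) {
  offs <- numeric(0)
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    for (i in seq_len(nrow(events))) {
      inw <- st[st >= events$start_s[i] & st < events$stop_s[i]]
      if (length(inw)) offs <- c(offs, inw[1L] - events$peak_s[i])
    }
  }
  list(offsets = offs,
       cdf = if (length(offs)) stats::ecdf(offs) else NULL)
}

#' Spikes-per-event category percentages
#'
#' Pools the per-(unit, event) spike counts inside event windows and reports
#' the percentage of participating pairs (count >= 1) contributing exactly 1,
#' 2-3, or 4 or more spikes. The three percentages sum to 100.
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param events Event table with `start_s`, `stop_s`.
#' @return Named numeric vector `c("1", "2-3", ">=4")`, percentages.
#' @export
spikes_per_event_categories <- function(spikes, events) {
  counts <- integer(0)
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    for (i in seq_len(nrow(events))) {
      k <- sum(st >= events$start_s[i] & st < events$stop_s[i])
      if (k >= 1L) counts <- c(counts, k)
    }
  }
  if (!length(counts))
    return(c("1" = NA_real_, "2-3" = NA_real_, ">=4" = NA_real_))
  100 * c("1" = mean(counts == 1L), "2-3" = mean(counts %in% 2:3),
          ">=4" = mean(counts >= 4L))
}

#' Unit participation in events
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param events Event table with `start_s`, `stop_s`.
#' @return List with `unit_fraction` (per-unit fraction of events with at
#'   least one spike) and `units_per_event` (per-event count of participating
#'   units).
#' @export
participation_metrics <- function(spikes, events) {
  n_ev <- nrow(events)
  part <- matrix(FALSE, length(spikes), n_ev)
  for (u in seq_along(spikes)) {
    st <- spikes[[u]]
    for (i in seq_len(n_ev))
      part[u, i] <- any(st >= events$start_s[i] & st < events$stop_s[i])
  }
  list(unit_fraction = rowMeans(part), units_per_event = colSums(part))
}

#' Timing of the population rate peak relative to the event anchor
#'
#' @param peth A `peth` object from [peth_z()].
#' @return Offset in seconds (negative when the rate peaks before the
#'   anchor). Attribute `flagged` is `TRUE` on a plateau maximum (tie broken
#'   to the earliest bin) and the function errors on a flat or degenerate
#'   PETH.
#' @export
rate_peak_timing <- function(peth) {
  stopifnot(inherits(peth, "peth"))
  z <- if (peth$degenerate) peth$rate else peth$z
  if (all(!is.finite(z)) || diff(range(z)) == 0)
    stop("flat or degenerate PETH: rate peak undefined", call. = FALSE)
  i <- which.max(z)
  out <- peth$centers[i]
  attr(out, "flagged") <- sum(z == max(z)) > 1L
  out
}

#' Symmetric modulation index
#'
#' `MI = (post - pre) / (post + pre)`, bounded in `[-1, 1]`; used e.g. for
#' the change in SPW-R rate after a chemogenetic manipulation.
#'
#' @param rate_pre,rate_post Non-negative rates before and after the
#'   intervention.
#' @return MI, or `NaN` (with a warning) when both rates are zero.
#' @export
modulation_index <- function(rate_pre, rate_post) {
  .check_num(rate_pre, "rate_pre", nonneg = TRUE, len = NULL)
  .check_num(rate_post, "rate_post", nonneg = TRUE, len = NULL)
  s <- rate_pre + rate_post
  out <- ifelse(s == 0, NaN, (rate_post - rate_pre) / s)
  if (any(is.nan(out))) warning("modulation index undefined (both rates zero)")
  out
}

#' Cross-region spiking contrast between SPW-Rs and plain SPWs
#'
#' Locks the spiking of a second (target, e.g. prefrontal) region to
#' hippocampal SPWs without ripples versus SPW-R events and contrasts the mean
#' z-scored rate in the event window: `contrast = mean z (SPW-R) - mean z
#' (SPW)`.
#'
#' @param target_spikes List of per-unit spike trains from the target region.
#' @param spw_events SPW-without-ripple event table (needs `peak_s`).
#' @param spwr_events SPW-R event table (needs `peak_s`).
#' @param duration_s Recording duration, s.
#' @param window_s,bin_s PETH window and bin, s.
#' @param seed Seed for baseline anchors.
#' @return List with `peth_spw`, `peth_spwr` and `contrast`.
#' @export
coupled_region_contrast <- function(target_spikes, spw_events, spwr_events,
                                    duration_s, window_s = 0.1, bin_s = 0.01,
                                    seed = 1L) {
  if (!nrow(spw_events) || !nrow(spwr_events))
    stop("both event sets must be non-empty", call. = FALSE)
  all_ev <- rbind(spw_events[, c("start_s", "stop_s")],
                  spwr_events[, c("start_s", "stop_s")])
  # same baseline seed for both conditions so identical event sets give a
  # contrast of exactly zero
  p1 <- peth_z(target_spikes, spw_events$peak_s, duration_s, window_s, bin_s,
               events = all_ev, seed = seed)
  p2 <- peth_z(target_spikes, spwr_events$peak_s, duration_s, window_s, bin_s,
               events = all_ev, seed = seed)
  inwin <- abs(p1$centers) <= window_s / 2
  contrast <- mean(p2$z[inwin]) - mean(p1$z[inwin])
  list(peth_spw = p1, peth_spwr = p2, contrast = contrast)
}

# ---------------------------------------------------------------------------
# Piecewise-linear (segmented) regression

# Design matrix for continuous piecewise-linear mean with breaks `b`.
.pw_design <- function(x, b) {
  X <- cbind(1, x)
  for (bb in b) X <- cbind(X, pmax(0, x - bb))
  X
}

.pw_sse <- function(x, y, b) {
  fit <- stats::lm.fit(.pw_design(x, b), y)
  sum(fit$residuals^2)
}

.pw_grid <- function(x, resolution) {
  r <- range(x)
  margin <- 0.05 * diff(r)
  seq(r[1] + margin, r[2] - margin, by = resolution)
}

# Best breakpoints (0..2) by exhaustive grid search at `resolution`.
.pw_search <- function(x, y, k, resolution) {
  if (k == 0L) return(list(b = numeric(0), sse = .pw_sse(x, y, numeric(0))))
  grid <- .pw_grid(x, resolution)
  if (k == 1L) {
    sse <- vapply(grid, function(b) .pw_sse(x, y, b), numeric(1))
    i <- which.min(sse)
    return(list(b = grid[i], sse = sse[i]))
  }
  best <- list(b = NULL, sse = Inf)
  # coarse pass for pairs, then refine around the optimum
  coarse <- grid[seq(1L, length(grid), by = max(1L, length(grid) %/% 40L))]
  for (i in seq_along(coarse)) for (j in seq_along(coarse)) {
    if (coarse[j] <= coarse[i] + resolution) next
    s <- .pw_sse(x, y, c(coarse[i], coarse[j]))
    if (s < best$sse) best <- list(b = c(coarse[i], coarse[j]), sse = s)
  }
  for (pass in 1:2) {
    for (d in 1:2) {
      cand <- grid[abs(grid - best$b[d]) <= 5 * resolution * 4^(2 - pass)]
      for (bb in cand) {
        b_try <- best$b; b_try[d] <- bb
        if (is.unsorted(b_try, strictly = TRUE)) next
        s <- .pw_sse(x, y, b_try)
        if (s < best$sse) best <- list(b = b_try, sse = s)
      }
    }
  }
  best
}

#' Continuous piecewise-linear regression with breakpoint search
#'
#' Least-squares segmented fit of `y` on `x` with 0, 1 or 2 breakpoints.
#' Breakpoints are located by exhaustive grid search over the interior of the
#' x-range at the given resolution (default 0.05), minimizing the residual sum
#' of squares; when `n_breakpoints = NULL` the model order (0-2) is chosen by
#' BIC. Confidence intervals come from a case-resampling bootstrap.
#'
#' @param x,y Numeric vectors.
#' @param n_breakpoints 0, 1 or 2, or `NULL` for BIC selection.
#' @param n_boot Bootstrap replicates for breakpoint CIs (0 disables).
#' @param resolution Breakpoint grid resolution in x units.
#' @param seed Seed for the bootstrap.
#' @return Object of class `piecewise_fit` with `breakpoints`, `slopes`,
#'   `intercept`, `sse`, `bic`, `n_breakpoints`, and `boot_ci` (2.5/97.5
#'   percentiles per breakpoint).
#' @export
piecewise_linear_fit <- function(x, y, n_breakpoints = NULL, n_boot = 0,
                                 resolution = 0.05, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (diff(range(x)) == 0) stop("`x` is degenerate (all equal)",
                                call. = FALSE)
  if (!is.null(n_breakpoints) && !n_breakpoints %in% 0:2)
    stop("`n_breakpoints` must be 0, 1 or 2", call. = FALSE)
  ks <- if (is.null(n_breakpoints)) 0:2 else n_breakpoints
  n <- length(x)
  fits <- lapply(ks, function(k) {
    if (n < 4 + 2 * k) return(NULL)
    f <- .pw_search(x, y, k, resolution)
    f$k <- k
    f$bic <- n * log(f$sse / n) + (2 + 2 * k) * log(n)
    f
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("too few points for the requested model",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  co <- stats::lm.fit(.pw_design(x, best$b), y)$coefficients
  slopes <- cumsum(co[-1L])
  boot_ci <- NULL
  if (n_boot > 0 && best$k > 0) {
    bmat <- .with_seed(seed, {
      t(vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        .pw_search(x[idx], y[idx], best$k, resolution)$b
      }, numeric(best$k)))
    })
    boot_ci <- apply(bmat, 2, stats::quantile, probs = c(0.025, 0.975))
  }
  out <- list(breakpoints = unname(best$b), slopes = unname(slopes),
              intercept = unname(co[1L]), sse = best$sse, bic = best$bic,
              n_breakpoints = best$k, boot_ci = boot_ci, x = x, y = y)
  class(out) <- "piecewise_fit"
  out
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Piecewise-linear fit:", x$n_breakpoints, "breakpoint(s)\n")
  if (x$n_breakpoints) {
    cat("  breakpoints:", paste(sprintf("%.2f", x$breakpoints),
                                collapse = ", "), "\n")
    if (!is.null(x$boot_ci))
      cat("  bootstrap 95% CI:",
          paste(apply(x$boot_ci, 2, function(ci)
            sprintf("[%.2f, %.2f]", ci[1], ci[2])), collapse = ", "), "\n")
  }
  cat("  slopes:", paste(sprintf("%.3f", x$slopes), collapse = ", "), "\n")
  cat(sprintf("  intercept %.3f, SSE %.4f, BIC %.1f\n", x$intercept, x$sse,
              x$bic))
  invisible(x)
}

#' @export
coef.piecewise_fit <- function(object, ...) {
  c(intercept = object$intercept,
    stats::setNames(object$slopes,
                    paste0("slope", seq_along(object$slopes))),
    if (object$n_breakpoints)
      stats::setNames(object$breakpoints,
                      paste0("breakpoint", seq_len(object$n_breakpoints))))
}

#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  X <- .pw_design(x, object$breakpoints)
  # raw coefficients: intercept, first slope, then slope increments
  co <- c(object$intercept, object$slopes[1L])
  if (object$n_breakpoints) co <- c(co, diff(object$slopes))
  as.numeric(X %*% co)
}

#' @export
residuals.piecewise_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, col = "grey50", xlab = "x", ylab = "y",
                 ...)
  ord <- order(x$x)
  graphics::lines(x$x[ord], predict(x)[ord], lwd = 2)
  if (x$n_breakpoints) graphics::abline(v = x$breakpoints, lty = 2)
  invisible(x)
}
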