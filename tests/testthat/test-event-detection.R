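# Time-domain detectors and their exact threshold semantics.

test_that("active-period detection follows the four-step rule", {
  fs <- 1000
  bg <- quiet_background(60, fs, sd_uV = 3)[, 1]
  expect_equal(nrow(detect_active_periods(rep(0, 30 * fs), fs)), 0)
  # a 500 ms, 150 uV, 8 Hz burst on a quiet background -> one event
  t <- seq_len(0.5 * fs) / fs
  x <- bg
  x[20000 + seq_along(t)] <- x[20000 + seq_along(t)] +
    150 * sin(2 * pi * 8 * t)
  ev <- detect_active_periods(x, fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_s - 20.25), 0.6)
  # a 200 ms burst fails the >= 300 ms rule
  t2 <- seq_len(0.2 * fs) / fs
  y <- bg
  y[40000 + seq_along(t2)] <- y[40000 + seq_along(t2)] +
    150 * sin(2 * pi * 8 * t2)
  expect_equal(nrow(detect_active_periods(y, fs)), 0)
  expect_error(detect_active_periods(x, 20), "24 Hz")
})

test_that("radial difference adds the laminar reversal constructively", {
  fs <- 1000
  n <- 10 * fs
  a <- stats::rnorm(n)
  same <- radial_difference(cbind(a, a), fs)
  expect_lt(max(abs(same$x)), 1e-8)
  expect_equal(same$fs, 250)
  # synthetic reversal: +A above, -A below -> difference 2A
  w <- make_spw_waveform(100, 80, fs)
  sig <- matrix(0, n, 2)
  idx <- 5000 + seq_along(w)
  sig[idx, 1] <- w; sig[idx, 2] <- -w
  d <- radial_difference(sig, fs)
  expect_equal(max(d$x), 200, tolerance = 0.05 * 200)
  # the 1-100 Hz band-pass suppresses a 200 Hz tone
  tone <- sin(2 * pi * 200 * seq_len(n) / fs)
  dt <- radial_difference(cbind(tone, 0 * tone), fs)
  expect_lt(stats::sd(dt$x), 0.05 * stats::sd(tone))
  expect_error(radial_difference(sig, fs, 1, 5), "out of range")
})

test_that("the adaptive SPW multiplier interpolates between 5 and 3 SD", {
  expect_equal(adaptive_spw_multiplier(5, 10, 100), 5)
  expect_equal(adaptive_spw_multiplier(200, 10, 100), 3)
  expect_equal(adaptive_spw_multiplier(55, 10, 100), 4)
  expect_error(adaptive_spw_multiplier(-1), ">=")
  expect_error(adaptive_spw_multiplier(5, 100, 10), "below")
})

test_that("SPW detection honours height, prominence and width limits", {
  expect_equal(nrow(detect_spw(rep(0, 1000), 4, fs = 250)), 0)
  # slow (sub-SPW-frequency) background: the deflection is the sharpest
  # feature, so its localization is noise-free
  fs <- 250
  set.seed(2)
  slow <- stats::filter(stats::rnorm(60 * fs), rep(1 / 25, 25),
                        circular = TRUE)
  x <- as.numeric(slow)
  w <- make_spw_waveform(1, 60, fs)
  x[3000 + seq_along(w)] <- x[3000 + seq_along(w)] + 4.5 * stats::sd(x) * w
  ev <- detect_spw(x, 4, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_s - (3000 + (length(w) + 1) / 2) / fs), 0.004 + 1 / fs)
  expect_lt(abs(ev$halfwidth_s - 0.060), 0.015)
  # a 150 ms-wide deflection fails MaxPeakWidth
  wide <- make_spw_waveform(1, 150, fs)
  y <- as.numeric(slow)
  y[8000 + seq_along(wide)] <- y[8000 + seq_along(wide)] +
    5 * stats::sd(y) * wide
  ev2 <- detect_spw(y, 4, fs = fs)
  expect_equal(nrow(ev2), 0)
})

test_that("power-method ripple detection recovers injected bursts", {
  fs <- 1000
  # noise floor: about one false positive per minute or fewer, on average
  fp_rate <- mean(vapply(1:4, function(s) {
    set.seed(300 + s)
    nrow(detect_ripples_power(stats::rnorm(120 * fs, 0, 2), fs)) / 2
  }, numeric(1)))
  expect_lt(fp_rate, 1.25)
  set.seed(3)
  bg <- stats::rnorm(120 * fs, 0, 2)
  # injected 150 Hz, 50 ms burst at 8x the background SD
  w <- make_ripple_waveform(150, 7.5, 8 * 2, fs)
  x <- bg
  x[30000 + seq_along(w)] <- x[30000 + seq_along(w)] + w
  ev <- detect_ripples_power(x, fs)
  hit <- which(abs(ev$peak_s - 30.025) < 0.05)
  expect_equal(length(hit), 1)
  expect_lt(abs(ev$start_s[hit] - 30.0), 0.010)
  expect_lt(abs(ev$stop_s[hit] - 30.05), 0.010)
  expect_equal(ev$peak_freq_hz[hit], 150, tolerance = 15)
})

test_that("labelled periods separated by under 30 ms are pulled together", {
  fs <- 1000
  set.seed(4)
  bg <- stats::rnorm(60 * fs, 0, 2)
  w <- make_ripple_waveform(150, 4.5, 16, fs)   # 30 ms bursts
  x <- bg
  x[10000 + seq_along(w)] <- x[10000 + seq_along(w)] + w
  x[10050 + seq_along(w)] <- x[10050 + seq_along(w)] + w  # 20 ms gap
  ev <- detect_ripples_power(x, fs)
  near <- ev[ev$peak_s > 9.9 & ev$peak_s < 10.2, ]
  expect_equal(nrow(near), 1)
  expect_gt(near$stop_s - near$start_s, 0.06)
})

test_that("cycle-by-cycle detection flags sustained rhythms, not noise", {
  fs <- 1000
  set.seed(5)
  # stationary 120 Hz sinusoid: interior cycles are all burst, one event
  t <- seq_len(fs) / fs
  out <- detect_ripples_bycycle(sin(2 * pi * 120 * t), fs)
  expect_equal(nrow(out$events), 1)
  expect_gt(mean(out$cycles$is_burst), 0.8)
  expect_gt(out$events$n_cycles, 100)
  # white noise: low burst fraction
  nz <- detect_ripples_bycycle(stats::rnorm(30 * fs), fs)
  expect_lt(mean(nz$cycles$is_burst), 0.05)
  # alternating-period input fails period consistency (100/160 Hz cycles:
  # adjacent-period ratio 0.625 below the threshold)
  alt <- unlist(lapply(1:40, function(i) {
    f <- if (i %% 2 == 0) 100 else 160
    n <- round(fs / f)
    sin(2 * pi * seq_len(n) / n)
  }))
  ch <- detect_ripples_bycycle(alt, fs,
                               thresholds = list(amplitude_consistency = 0.6,
                                                 period_consistency = 0.8,
                                                 monotonicity = 0.6))
  expect_equal(nrow(ch$events), 0)
  expect_error(detect_ripples_bycycle(chirp, fs,
                                      thresholds = list(
                                        amplitude_consistency = 2,
                                        period_consistency = 0.6,
                                        monotonicity = 0.6)),
               "\\[0, 1\\]")
})

test_that("consensus keeps exactly the power events confirmed by-cycle", {
  a <- data.frame(kind = "ripple", start_s = c(1, 2, 3),
                  stop_s = c(1.05, 2.05, 3.05), peak_s = c(1.02, 2.02, 3.02),
                  peak_amp = 1, halfwidth_s = NA, n_cycles = 5,
                  peak_freq_hz = 140)
  expect_equal(consensus_ripples(a, a), a, ignore_attr = TRUE)
  b <- a; b$start_s <- b$start_s + 10; b$stop_s <- b$stop_s + 10
  expect_equal(nrow(consensus_ripples(a, b)), 0)
  c1 <- a[2, ]; c1$start_s <- 2.04; c1$stop_s <- 2.1
  kept <- consensus_ripples(a, c1)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start_s, 2)    # boundaries come from the power method
})

test_that("SPW coupling uses the half-open peak +/- halfwidth/2 window", {
  spws <- data.frame(kind = "spw", start_s = 10, stop_s = 10.2,
                     peak_s = 10.1, peak_amp = 100, halfwidth_s = 0.06,
                     n_cycles = NA, peak_freq_hz = NA)
  rip <- function(s, e) data.frame(kind = "ripple", start_s = s, stop_s = e,
                                   peak_s = (s + e) / 2, peak_amp = 10,
                                   halfwidth_s = NA, n_cycles = 5,
                                   peak_freq_hz = 140)
  # fully inside [10.07, 10.13)
  res <- couple_to_spw(rip(10.08, 10.12), spws)
  expect_equal(nrow(res$spwr), 1)
  expect_equal(nrow(res$solo), 0)
  expect_equal(res$spwr$kind, "spwr")
  # ends strictly before the window
  res2 <- couple_to_spw(rip(10.0, 10.06), spws)
  expect_equal(nrow(res2$spwr), 0)
  expect_equal(res2$solo$kind, "solo_ripple")
  # sharing exactly the boundary: ripple stops at window start -> no overlap
  res3 <- couple_to_spw(rip(10.02, 10.07), spws)
  expect_equal(nrow(res3$spwr), 0)
  # partition property
  both <- couple_to_spw(rbind(rip(10.08, 10.12), rip(11, 11.05)), spws)
  expect_equal(nrow(both$spwr) + nrow(both$solo), 2)
})

test_that("ripple length classes split at three cycles, inclusive", {
  rip <- data.frame(kind = "ripple",
                    start_s = c(0, 1, 2), stop_s = c(0.030, 1.020, 2.045),
                    peak_s = c(0.015, 1.01, 2.02), peak_amp = 1,
                    halfwidth_s = NA, n_cycles = NA,
                    peak_freq_hz = c(100, 100, 150))
  cls <- classify_ripple_length(rip)
  expect_equal(cls$class, c("long", "short", "long"))
  expect_equal(cls$n_cycles, c(3, 2, 6.75))
  rip$peak_freq_hz[1] <- NA
  expect_error(classify_ripple_length(rip), "peak_freq_hz")
})

test_that("iHFO fraction counts stimulation windows with consensus events", {
  fs <- 1000
  set.seed(6)
  x <- stats::rnorm(60 * fs, 0, 2)
  w <- make_ripple_waveform(150, 7.5, 20, fs)
  wins <- cbind(seq(1, 59, by = 2), seq(1, 59, by = 2) + 0.4)  # 30 windows
  with_rip <- seq(1, 30, by = 2)                               # 15 of 30
  for (k in with_rip) {
    i0 <- round((wins[k, 1] + 0.1) * fs)
    x[i0 + seq_along(w)] <- x[i0 + seq_along(w)] + w
  }
  out <- detect_ihfo(x, fs, wins)
  expect_equal(out$fraction_with_ihfo, 0.5, tolerance = 0.1)
  expect_true(all(out$events$kind == "ihfo"))
  expect_error(detect_ihfo(x, fs, wins[0, , drop = FALSE]), "non-empty")
  quiet <- detect_ihfo(stats::rnorm(60 * fs, 0, 2), fs, wins)
  expect_lte(quiet$fraction_with_ihfo, 0.1)
})

test_that("the movement rule uses a strict 25-pixel displacement", {
  xy <- matrix(100, nrow = 50, ncol = 2)
  expect_equal(nrow(detect_movement(xy)), 0)
  # one 30 px jump -> one single-frame interval
  xy2 <- xy; xy2[20:50, 1] <- 130
  ev <- detect_movement(xy2, frame_rate = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$stop_s - ev$start_s, 0.1)
  # exactly 25 px is not movement
  xy3 <- xy; xy3[20:50, 1] <- 125
  expect_equal(nrow(detect_movement(xy3, frame_rate = 10)), 0)
  # any of several tracked points can trigger
  ev2 <- detect_movement(list(xy, xy2), frame_rate = 10)
  expect_equal(nrow(ev2), 1)
  expect_equal(nrow(detect_movement(xy[1, , drop = FALSE])), 0)
})

test_that("raising detection thresholds never increases event counts", {
  rec <- make_recording(recovery_spec(seed = 21, duration_s = 60))
  x <- rec$lfp[, 1]
  n3 <- nrow(detect_ripples_power(x, rec$fs, label_sd = 3))
  n4 <- nrow(detect_ripples_power(x, rec$fs, label_sd = 4))
  expect_lte(n4, n3)
  d <- radial_difference(rec$lfp, rec$fs)
  expect_lte(nrow(detect_spw(d, 5)), nrow(detect_spw(d, 3)))
})

test_that("detection is deterministic for identical input", {
  rec <- make_recording(recovery_spec(seed = 22, duration_s = 30))
  a <- detect_ripples_power(rec$lfp[, 1], rec$fs)
  b <- detect_ripples_power(rec$lfp[, 1], rec$fs)
  expect_identical(a, b)
})
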