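# Event-locked spiking metrics and the segmented trend fit.

poisson_trains <- function(n_units, rate, duration, seed) {
  set.seed(seed)
  lapply(seq_len(n_units), function(u)
    sort(stats::runif(stats::rpois(1, rate * duration), 0, duration)))
}

test_that("PETH z is near zero under the Poisson null", {
  sp <- poisson_trains(30, 2, 300, 1)
  set.seed(2)
  anchors <- sort(stats::runif(40, 5, 295))
  ph <- peth_z(sp, anchors, 300, seed = 3)
  expect_false(ph$degenerate)
  expect_lt(abs(mean(ph$z)), 0.5)
  expect_lt(abs(ph$z[1]), 3.5)
  expect_error(peth_z(sp, numeric(0), 300), "anchor")
})

test_that("the generator's SPW modulation target is recovered by peth_z", {
  # the z value at the event anchor itself (mean of the two centre bins);
  # averaged over recordings because a z-scored PETH bin is self-normalized
  # and so carries order-1 sampling noise per recording
  zs <- vapply(1:8, function(s) {
    rec <- make_recording(synth_spec(duration_s = 400, spw_rate = 6,
                                     ripple_prob = 0, n_units = 100,
                                     baseline_rate_hz = 1,
                                     spw_modulation_z = 3, seed = 50 + s))
    spw <- rec$truth[rec$truth$kind == "spw", ]
    ph <- peth_z(rec$spikes, spw$peak_s, 400, seed = s)
    mean(ph$z[abs(ph$centers) <= 0.01])
  }, numeric(1))
  expect_lt(abs(mean(zs) - 3), 0.5)
})

test_that("empty spike sets yield a flagged, degenerate PETH", {
  ph <- peth_z(list(numeric(0), numeric(0)), c(1, 2), 10, seed = 1)
  expect_true(ph$degenerate)
  expect_true(all(is.na(ph$z)))
  expect_true(all(ph$rate == 0))
})

test_that("fraction of modulated events matches construction and the null", {
  # construct a raster in which every unit bursts at every event peak
  set.seed(76)
  peaks <- sort(stats::runif(50, 5, 595))
  spw <- data.frame(start_s = peaks - 0.05, stop_s = peaks + 0.05,
                    peak_s = peaks)
  sp <- lapply(1:30, function(u)
    sort(c(stats::runif(300, 0, 600),
           peaks + stats::rnorm(length(peaks), 0, 0.004))))
  frac <- fraction_modulated_events(sp, spw, 600, z_crit = 2, seed = 1)
  expect_gt(frac, 0.95)
  # Poisson null: fraction ~ tail probability of the max of ~10 bins
  sp <- poisson_trains(100, 1, 600, 4)
  set.seed(5)
  fake <- data.frame(start_s = 0, stop_s = 0,
                     peak_s = sort(stats::runif(60, 5, 595)))
  fake$start_s <- fake$peak_s - 0.05; fake$stop_s <- fake$peak_s + 0.05
  null_frac <- fraction_modulated_events(sp, fake, 600, z_crit = 2,
                                         seed = 6)
  expect_lt(null_frac, 0.5)
  expect_error(fraction_modulated_events(sp, fake[0, ], 600), "no events")
})

test_that("first-spike offsets implement the exclusion rule exactly", {
  ev <- data.frame(start_s = c(1, 2), stop_s = c(1.2, 2.2),
                   peak_s = c(1.1, 2.1))
  sp <- list(c(1.1, 2.1), c(1.05, 1.15), numeric(0))
  out <- first_spike_offsets(sp, ev)
  # unit 1: offsets 0, 0; unit 2: first spike in event 1 only; unit 3: none
  expect_equal(sort(out$offsets), sort(c(0, 0, -0.05)))
  expect_equal(out$cdf(0), 1)
  # normal offsets are recovered
  set.seed(8)
  peaks <- seq(10, 590, by = 5)
  evn <- data.frame(start_s = peaks - 0.3, stop_s = peaks + 0.3,
                    peak_s = peaks)
  spn <- lapply(1:20, function(u) sort(peaks + stats::rnorm(length(peaks),
                                                            0, 0.05)))
  on <- first_spike_offsets(spn, evn)
  expect_equal(stats::sd(on$offsets), 0.05, tolerance = 0.1)
})

test_that("spikes-per-event categories count and normalize correctly", {
  ev <- data.frame(start_s = 0, stop_s = 1)
  mk <- function(k) seq(0.1, 0.9, length.out = k)
  sp <- c(lapply(1:5, function(i) mk(1)), lapply(1:3, function(i) mk(2)),
          lapply(1:2, function(i) mk(5)))
  pct <- spikes_per_event_categories(sp, ev)
  expect_equal(unname(pct), c(50, 30, 20))
  expect_equal(sum(pct), 100)
  # every unit fires exactly once
  one <- spikes_per_event_categories(lapply(1:4, function(i) 0.5), ev)
  expect_equal(unname(one), c(100, 0, 0))
})

test_that("participation metrics equal the brute-force tally", {
  ev <- data.frame(start_s = c(0, 2, 4), stop_s = c(1, 3, 5))
  sp <- list(c(0.5, 2.5, 4.5), c(0.1), numeric(0))
  pm <- participation_metrics(sp, ev)
  expect_equal(pm$unit_fraction, c(1, 1 / 3, 0))
  expect_equal(pm$units_per_event, c(2, 1, 1))
})

test_that("rate-peak timing reports signed offsets and degeneracy", {
  mk_peth <- function(z, centers) {
    structure(list(centers = centers, rate = z, z = z, degenerate = FALSE,
                   n_events = 10, bin_s = diff(centers[1:2])),
              class = "peth")
  }
  centers <- seq(-0.2, 0.2, by = 0.01)
  sym <- mk_peth(stats::dnorm(centers, 0, 0.03), centers)
  expect_lt(abs(rate_peak_timing(sym)), 0.011)
  late <- mk_peth(stats::dnorm(centers, 0.02, 0.03), centers)
  expect_equal(as.numeric(rate_peak_timing(late)), 0.02, tolerance = 0.55)
  flat <- mk_peth(rep(1, length(centers)), centers)
  expect_error(rate_peak_timing(flat), "flat")
})

test_that("the modulation index is the bounded symmetric contrast", {
  expect_equal(modulation_index(3, 3), 0)
  expect_equal(modulation_index(2, 0), -1)
  expect_equal(modulation_index(2, 6), 0.5)
  expect_true(all(abs(modulation_index(stats::runif(50), stats::runif(50)))
                  <= 1))
  expect_warning(mi <- modulation_index(0, 0), "undefined")
  expect_true(is.nan(mi))
})

test_that("cross-region contrast is null for independent target spiking", {
  sp <- poisson_trains(25, 2, 600, 10)
  set.seed(11)
  p1 <- sort(stats::runif(40, 5, 595)); p2 <- sort(stats::runif(40, 5, 595))
  mk_ev <- function(p) data.frame(start_s = p - 0.05, stop_s = p + 0.05,
                                  peak_s = p)
  out <- coupled_region_contrast(sp, mk_ev(p1), mk_ev(p2), 600, seed = 2)
  expect_lt(abs(out$contrast), 1.2)
  same <- coupled_region_contrast(sp, mk_ev(p1), mk_ev(p1), 600, seed = 3)
  expect_lt(abs(same$contrast), 1e-9)
  expect_error(coupled_region_contrast(sp, mk_ev(p1)[0, ], mk_ev(p2), 600),
               "non-empty")
})

test_that("cross-region contrast recovers an injected SPW-R gain", {
  set.seed(12)
  p_spw <- seq(10, 590, by = 10) + stats::runif(59, -1, 1)
  p_spwr <- p_spw + 5
  base <- poisson_trains(30, 2, 600, 13)
  # add extra spikes locked to the SPW-R anchors only
  sp <- lapply(base, function(st)
    sort(c(st, p_spwr[stats::runif(length(p_spwr)) < 0.5] +
             stats::rnorm(sum(stats::runif(length(p_spwr)) < 0), 0, 0.02))))
  sp <- lapply(seq_along(base), function(u) {
    extra <- p_spwr[stats::runif(length(p_spwr)) < 0.4] +
      stats::rnorm(sum(stats::runif(1) < 2), 0, 0.02)
    sort(c(base[[u]], p_spwr + stats::rnorm(length(p_spwr), 0, 0.02)))
  })
  mk_ev <- function(p) data.frame(start_s = p - 0.05, stop_s = p + 0.05,
                                  peak_s = p)
  out <- coupled_region_contrast(sp, mk_ev(p_spw), mk_ev(p_spwr), 600,
                                 seed = 4)
  expect_gt(out$contrast, 1)
})

test_that("noiseless segmented data are recovered exactly", {
  tab <- make_age_trend_table(slopes = c(0, 0.8), breakpoints = 10,
                              noise_sd = 0, n_per_x = 3, seed = 1)
  fit <- piecewise_linear_fit(tab$data$x, tab$data$y, n_breakpoints = 1)
  expect_equal(fit$breakpoints, 10, tolerance = 0.051)
  expect_equal(fit$slopes, c(0, 0.8), tolerance = 0.02)
  expect_lt(fit$sse, 1e-10)
  expect_error(piecewise_linear_fit(rep(1, 10), stats::rnorm(10)),
               "degenerate")
})

test_that("the breakpoint at 9.75 is recovered from noisy trend tables", {
  bps <- vapply(1:30, function(s) {
    tab <- make_age_trend_table(slopes = c(0, 0.8), breakpoints = 9.75,
                                noise_sd = 0.2, n_per_x = 12, seed = s)
    piecewise_linear_fit(tab$data$x, tab$data$y,
                         n_breakpoints = 1)$breakpoints
  }, numeric(1))
  expect_lt(abs(mean(bps) - 9.75), 0.5)
  expect_lt(abs(mean(bps) - 9.75), 0.1 + 2 * stats::sd(bps) / sqrt(30))
  expect_lt(sqrt(mean((bps - 9.75)^2)), 0.5)
})

test_that("BIC prefers the single-slope model on unsegmented data", {
  wins <- vapply(1:12, function(s) {
    set.seed(400 + s)
    x <- rep(4:12, each = 8)
    y <- 0.5 * x + stats::rnorm(length(x), 0, 0.3)
    piecewise_linear_fit(x, y)$n_breakpoints == 0
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("bootstrap intervals cover the generating breakpoint", {
  tab <- make_age_trend_table(slopes = c(0, 0.8), breakpoints = 9.75,
                              noise_sd = 0.2, n_per_x = 12, seed = 3)
  fit <- piecewise_linear_fit(tab$data$x, tab$data$y, n_breakpoints = 1,
                              n_boot = 60, seed = 4)
  expect_lte(fit$boot_ci[1, 1], 9.75 + 0.2)
  expect_gte(fit$boot_ci[2, 1], 9.75 - 0.2)
  expect_equal(length(predict(fit)), length(tab$data$x))
  expect_lt(abs(mean(residuals(fit))), 0.1)
})

test_that("metrics are invariant to unit relabeling and global time shift", {
  sp <- poisson_trains(10, 3, 100, 20)
  ev <- data.frame(start_s = c(10, 40, 70), stop_s = c(10.2, 40.2, 70.2),
                   peak_s = c(10.1, 40.1, 70.1))
  a <- spikes_per_event_categories(sp, ev)
  b <- spikes_per_event_categories(rev(sp), ev)
  expect_equal(a, b)
  shift <- 5
  sp2 <- lapply(sp, function(s) s + shift)
  ev2 <- ev + shift
  expect_equal(spikes_per_event_categories(sp2, ev2), a)
  expect_equal(participation_metrics(sp2, ev2)$units_per_event,
               participation_metrics(sp, ev)$units_per_event)
})
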