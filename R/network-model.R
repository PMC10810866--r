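# Two-population CA1 LIF network: construction, integration, LFP proxy,
# inhibition sweeps and spectral readout.

#' Parameters of the CA1 two-population LIF network
#'
#' The default network represents the adult CA1 circuitry in a 0.4 mm slice
#' (4% of the hippocampus): 12,000 pyramidal cells (E) and 200
#' parvalbumin-positive basket cells (I), a 60:1 ratio, randomly connected
#' with probabilities `p_EE = 0.0164`, `p_IE = 0.1`, `p_EI = 0.1`,
#' `p_II = 0.2` (subscripts: target then source). Neurons are leaky
#' integrate-and-fire units with conductance-based biexponential synapses
#' (AMPA-type outgoing from E, GABA-type from I); the biexponential is
#' normalized so its maximum equals the stated peak conductance, which makes
#' the inhibitory multipliers `c_gei` (on the I-to-E peak conductance) and
#' `c_gii` (on I-to-I) well defined. Neuron and synapse constants are
#' behaviour-calibrated defaults in the lineage of published adult CA1 ripple
#' models (the network produces an in-band fast oscillation near 150 Hz at
#' multiplier 1); every constant is exposed here.
#'
#' @param N_E,N_I Population sizes.
#' @param p_EE,p_IE,p_EI,p_II Connection probabilities (target, source).
#' @param c_gei Multiplier on the I-to-E peak conductance (range 0.095-2;
#'   1 = adult).
#' @param c_gii Multiplier on the I-to-I peak conductance (range 0.05-2).
#' @param sigma_noise_mV Stationary membrane-voltage SD contributed by the
#'   white voltage noise (Ornstein-Uhlenbeck scaling).
#' @param dt_ms Integration step.
#' @param v_init_sd_mV SD of the Gaussian voltage initialization around rest.
#' @param neuron_e,neuron_i Per-population neuron constants: capacitance
#'   `C_pF`, leak `gL_nS`, resting `EL_mV`, threshold `Vth_mV`, reset
#'   `Vreset_mV`, refractory `ref_ms`.
#' @param syn_ee,syn_ie,syn_ei,syn_ii Per-class synapse constants: peak
#'   conductance `g_nS`, rise/decay time constants `tau_r_ms` < `tau_d_ms`,
#'   reversal `E_mV`, transmission delay `delay_ms`.
#' @return Object of class `network_params`.
#' @export
network_params <- function(N_E = 12000, N_I = 200,
                           p_EE = 0.0164, p_IE = 0.1, p_EI = 0.1, p_II = 0.2,
                           c_gei = 1, c_gii = 1,
                           sigma_noise_mV = 5, dt_ms = 0.1,
                           v_init_sd_mV = 0.1,
                           neuron_e = list(C_pF = 200, gL_nS = 10,
                                           EL_mV = -67, Vth_mV = -50,
                                           Vreset_mV = -60, ref_ms = 2),
                           neuron_i = list(C_pF = 80, gL_nS = 10,
                                           EL_mV = -65, Vth_mV = -52,
                                           Vreset_mV = -67, ref_ms = 1),
                           syn_ee = list(g_nS = 0.2, tau_r_ms = 0.5,
                                         tau_d_ms = 1.8, E_mV = 0,
                                         delay_ms = 1),
                           syn_ie = list(g_nS = 0.8, tau_r_ms = 0.5,
                                         tau_d_ms = 0.8, E_mV = 0,
                                         delay_ms = 0.6),
                           syn_ei = list(g_nS = 8.0, tau_r_ms = 0.45,
                                         tau_d_ms = 1.5, E_mV = -75,
                                         delay_ms = 0.6),
                           syn_ii = list(g_nS = 4.5, tau_r_ms = 0.45,
                                         tau_d_ms = 0.7, E_mV = -75,
                                         delay_ms = 0.6)) {
  for (p in c(p_EE, p_IE, p_EI, p_II)) .check_frac(p, "connection probability")
  .check_num(c_gei, "c_gei", positive = TRUE)
  .check_num(c_gii, "c_gii", positive = TRUE)
  .check_num(dt_ms, "dt_ms", positive = TRUE)
  .check_num(sigma_noise_mV, "sigma_noise_mV", nonneg = TRUE)
  for (s in list(syn_ee, syn_ie, syn_ei, syn_ii))
    if (s$tau_r_ms >= s$tau_d_ms)
      stop("synaptic rise time constant must be below the decay constant",
           call. = FALSE)
  out <- list(N_E = as.integer(N_E), N_I = as.integer(N_I),
              p_EE = p_EE, p_IE = p_IE, p_EI = p_EI, p_II = p_II,
              c_gei = c_gei, c_gii = c_gii,
              sigma_noise_mV = sigma_noise_mV, dt_ms = dt_ms,
              v_init_sd_mV = v_init_sd_mV,
              neuron_e = neuron_e, neuron_i = neuron_i,
              syn_ee = syn_ee, syn_ie = syn_ie, syn_ei = syn_ei,
              syn_ii = syn_ii)
  class(out) <- "network_params"
  out
}

#' @export
print.network_params <- function(x, ...) {
  cat("CA1 LIF network:", x$N_E, "E +", x$N_I, "I neurons\n")
  cat(sprintf("  p_EE %.4f, p_IE %.2f, p_EI %.2f, p_II %.2f\n",
              x$p_EE, x$p_IE, x$p_EI, x$p_II))
  cat(sprintf("  inhibition multipliers: c_gei %.3f, c_gii %.3f\n",
              x$c_gei, x$c_gii))
  cat(sprintf("  noise SD %.1f mV, dt %.2f ms\n", x$sigma_noise_mV, x$dt_ms))
  invisible(x)
}

# Per-source Bernoulli targets: binomial out-degree + uniform sampling
# without replacement, excluding the self-pair within a population.
.sample_class <- function(n_src, n_tgt, p, exclude_self) {
  if (p <= 0) return(list(idx = integer(0), ptr = rep(0L, n_src + 1L)))
  n_avail <- if (exclude_self) n_tgt - 1L else n_tgt
  deg <- stats::rbinom(n_src, n_avail, p)
  idx_list <- vector("list", n_src)
  for (s in seq_len(n_src)) {
    t0 <- sample.int(n_avail, deg[s])
    if (exclude_self) t0 <- ifelse(t0 >= s, t0 + 1L, t0)
    idx_list[[s]] <- t0 - 1L            # 0-based for the integrator
  }
  list(idx = as.integer(unlist(idx_list)),
       ptr = c(0L, cumsum(deg)))
}

#' Build the random connectivity of the network
#'
#' Each ordered (source, target) pair is connected independently with the
#' population-specific probability; self-connections and duplicate edges are
#' excluded. The realization is a deterministic function of the seed.
#'
#' @param params A [network_params()] object.
#' @param seed Integer seed.
#' @return Object of class `connectivity`: per class (`ee`, `ie`, `ei`,
#'   `ii`) a compressed adjacency (`idx` 0-based target indices, `ptr`
#'   per-source offsets). Class naming: `ie` = E source onto I target.
#' @export
build_connectivity <- function(params, seed = 1L) {
  stopifnot(inherits(params, "network_params"))
  .with_seed(seed, {
    out <- list(
      ee = .sample_class(params$N_E, params$N_E, params$p_EE, TRUE),
      ie = .sample_class(params$N_E, params$N_I, params$p_IE, FALSE),
      ei = .sample_class(params$N_I, params$N_E, params$p_EI, FALSE),
      ii = .sample_class(params$N_I, params$N_I, params$p_II, TRUE))
    out$N_E <- params$N_E; out$N_I <- params$N_I
    class(out) <- "connectivity"
    out
  })
}

#' Edge counts of a realized connectivity
#' @param conn A `connectivity` object.
#' @return Named integer vector of edges per class.
#' @export
edge_counts <- function(conn) {
  vapply(conn[c("ee", "ie", "ei", "ii")],
         function(cl) length(cl$idx), integer(1))
}

#' Edge list of one connection class
#' @param conn A `connectivity` object.
#' @param class One of `"ee"`, `"ie"`, `"ei"`, `"ii"`.
#' @return data.frame with 1-based `source` and `target` indices.
#' @export
edge_list <- function(conn, class = c("ee", "ie", "ei", "ii")) {
  class <- match.arg(class)
  cl <- conn[[class]]
  deg <- diff(cl$ptr)
  data.frame(source = rep(seq_along(deg), deg), target = cl$idx + 1L)
}

#' External CA3-like drive specification
#'
#' A random subpopulation of E cells receives a Gaussian current pulse; the
#' per-neuron pulse center is jittered around the common center. The default
#' amplitude is calibrated so the adult network's E-population rate rises
#' several-fold at the drive peak.
#'
#' @param target_fraction Fraction of E units receiving drive.
#' @param center_time_ms Common pulse center, ms.
#' @param profile_sd_ms Gaussian current SD (pulse width), ms.
#' @param jitter_sd_ms SD of the per-neuron center jitter, ms.
#' @param amplitude_pA Pulse peak amplitude, pA.
#' @return Object of class `drive_spec`.
#' @export
drive_spec <- function(target_fraction = 0.2, center_time_ms = 50,
                       profile_sd_ms = 10, jitter_sd_ms = 2,
                       amplitude_pA = 900) {
  .check_frac(target_fraction, "target_fraction")
  .check_num(profile_sd_ms, "profile_sd_ms", positive = TRUE)
  .check_num(jitter_sd_ms, "jitter_sd_ms", nonneg = TRUE)
  out <- list(target_fraction = target_fraction,
              center_time_ms = center_time_ms,
              profile_sd_ms = profile_sd_ms, jitter_sd_ms = jitter_sd_ms,
              amplitude_pA = amplitude_pA)
  class(out) <- "drive_spec"
  out
}

#' Realize the per-neuron external drive
#'
#' Draws the driven subpopulation (`ceiling(target_fraction * n_E)` units)
#' and each unit's jittered pulse center. Undriven units receive zero
#' current.
#'
#' @param spec A [drive_spec()] object.
#' @param n_E Number of E units.
#' @param seed Integer seed.
#' @return Object of class `network_drive`: per-unit amplitude and center.
#' @export
make_drive <- function(spec, n_E, seed = 1L) {
  stopifnot(inherits(spec, "drive_spec"))
  .with_seed(seed, {
    amp <- numeric(n_E)
    center <- rep(spec$center_time_ms, n_E)
    n_tgt <- ceiling(spec$target_fraction * n_E)
    if (n_tgt > 0) {
      tgt <- sample.int(n_E, n_tgt)
      amp[tgt] <- spec$amplitude_pA
      center[tgt] <- stats::rnorm(n_tgt, spec$center_time_ms,
                                  spec$jitter_sd_ms)
    }
    out <- list(amp_pA = amp, center_ms = center,
                profile_sd_ms = spec$profile_sd_ms, spec = spec)
    class(out) <- "network_drive"
    out
  })
}

#' Evaluate drive current traces
#' @param drive A `network_drive` object.
#' @param times_ms Times at which to evaluate (ms).
#' @param units Unit indices (default: all driven units).
#' @return Matrix `length(times_ms)` x `length(units)` of currents (pA).
#' @export
drive_traces <- function(drive, times_ms, units = NULL) {
  stopifnot(inherits(drive, "network_drive"))
  if (is.null(units)) units <- which(drive$amp_pA != 0)
  sapply(units, function(u)
    drive$amp_pA[u] *
      exp(-(times_ms - drive$center_ms[u])^2 / (2 * drive$profile_sd_ms^2)),
    simplify = TRUE) -> m
  matrix(m, nrow = length(times_ms))
}

#' Simulate the CA1 network
#'
#' Integrates the leaky integrate-and-fire dynamics with the Euler-Maruyama
#' scheme (dt 0.1 ms by default): voltages start from a Gaussian around rest
#' (SD 0.1 mV), additive white voltage noise is scaled so the stationary
#' membrane SD equals `sigma_noise_mV` (5 mV by default, enough for
#' spontaneous spiking without external input), spikes trigger reset and
#' refractoriness, and conductances follow normalized biexponentials. The
#' I-to-E peak conductance is scaled by `c_gei` and the I-to-I one by
#' `c_gii`. The LFP proxy (sum over E cells of absolute AMPA plus GABA
#' currents) is recorded at every step.
#'
#' @param params A [network_params()] object.
#' @param connectivity A [build_connectivity()] realization (built from
#'   `params` if omitted).
#' @param drive A `network_drive`, a [drive_spec()] (realized internally), or
#'   `NULL` for no external input.
#' @param duration_ms Simulated time, ms.
#' @param seed Integer seed controlling noise (and connectivity/drive when
#'   built internally).
#' @return Object of class `ca1_sim`: `spikes_e`/`spikes_i` (data.frames
#'   `unit`, `t_ms`), per-step spike counts, `lfp_ampa`/`lfp_gaba` (pA),
#'   `fs_hz`, `duration_ms`, `runaway` flag (E rate saturating near the
#'   refractory bound for over 20 ms) and the inputs used.
#' @export
simulate_network <- function(params, connectivity = NULL, drive = NULL,
                             duration_ms = 100, seed = 1L) {
  stopifnot(inherits(params, "network_params"))
  .check_num(duration_ms, "duration_ms", positive = TRUE)
  if (is.null(connectivity))
    connectivity <- build_connectivity(params, seed = seed + 7919L)
  if (inherits(drive, "drive_spec"))
    drive <- make_drive(drive, params$N_E, seed = seed + 104729L)
  n_steps <- as.integer(round(duration_ms / params$dt_ms))
  pe <- unlist(params$neuron_e[c("C_pF", "gL_nS", "EL_mV", "Vth_mV",
                                 "Vreset_mV", "ref_ms")])
  pi_ <- unlist(params$neuron_i[c("C_pF", "gL_nS", "EL_mV", "Vth_mV",
                                  "Vreset_mV", "ref_ms")])
  sv <- function(s, mult = 1) c(s$g_nS * mult, s$tau_r_ms, s$tau_d_ms,
                                s$E_mV, s$delay_ms)
  if (is.null(drive)) {
    amp <- numeric(0); cen <- numeric(0); dsd <- 1
  } else {
    amp <- drive$amp_pA; cen <- drive$center_ms; dsd <- drive$profile_sd_ms
  }
  res <- .with_seed(seed, {
    .lif_simulate_cpp(n_steps, params$dt_ms, pe, pi_,
                      sv(params$syn_ee), sv(params$syn_ie),
                      sv(params$syn_ei, params$c_gei),
                      sv(params$syn_ii, params$c_gii),
                      connectivity$ee$idx, connectivity$ee$ptr,
                      connectivity$ie$idx, connectivity$ie$ptr,
                      connectivity$ei$idx, connectivity$ei$ptr,
                      connectivity$ii$idx, connectivity$ii$ptr,
                      amp, cen, dsd,
                      params$sigma_noise_mV, params$v_init_sd_mV)
  })
  fs <- 1000 / params$dt_ms
  # runaway: E population rate pinned near the refractory ceiling for > 20 ms
  # (rate smoothed over ~2 refractory periods so synchronized population
  # spikes register as sustained saturation)
  rate_e <- res$count_e / (params$N_E * params$dt_ms / 1000)
  smooth_steps <- max(1L, as.integer(2 * params$neuron_e$ref_ms /
                                       params$dt_ms))
  rate_e <- .boxcar(rate_e, smooth_steps)
  ceiling_hz <- 1000 / params$neuron_e$ref_ms
  sat <- rate_e > 0.5 * ceiling_hz
  runaway <- FALSE
  if (any(sat)) {
    r <- .runs_true(sat)
    runaway <- any((r$stop - r$start + 1L) * params$dt_ms > 20)
  }
  out <- list(spikes_e = res$spikes_e, spikes_i = res$spikes_i,
              count_e = res$count_e, count_i = res$count_i,
              lfp_ampa = res$lfp_ampa, lfp_gaba = res$lfp_gaba,
              fs_hz = fs, duration_ms = duration_ms, runaway = runaway,
              params = params, drive = drive)
  class(out) <- "ca1_sim"
  out
}

#' @export
print.ca1_sim <- function(x, ...) {
  cat(sprintf("CA1 network simulation: %.0f ms at dt %.2f ms\n",
              x$duration_ms, x$params$dt_ms))
  cat(sprintf("  %d E spikes (%.2f Hz/unit), %d I spikes (%.1f Hz/unit)\n",
              nrow(x$spikes_e),
              nrow(x$spikes_e) / x$params$N_E / (x$duration_ms / 1000),
              nrow(x$spikes_i),
              nrow(x$spikes_i) / x$params$N_I / (x$duration_ms / 1000)))
  if (x$runaway) cat("  WARNING: runaway activity detected\n")
  invisible(x)
}

#' Reconstruct the LFP proxy from a simulation
#'
#' `lfp(t) = sum over E cells of |I_AMPA| + |I_GABA|`; nonnegative by
#' construction.
#'
#' @param sim A `ca1_sim` object.
#' @return Numeric LFP trace (pA) at `sim$fs_hz`.
#' @export
reconstruct_lfp <- function(sim) {
  stopifnot(inherits(sim, "ca1_sim"))
  as.numeric(sim$lfp_ampa + sim$lfp_gaba)
}

#' Population firing rate with Gaussian smoothing
#'
#' Instantaneous per-step rates averaged across units and convolved with a
#' Gaussian window (default SD 0.5 ms); the integral of the rate times the
#' unit count recovers the total spike count up to edge loss.
#'
#' @param spike_times Spike times, ms (e.g. `sim$spikes_e$t_ms`).
#' @param n_units Number of units in the population.
#' @param duration_ms Trace length, ms.
#' @param dt_ms Step, ms.
#' @param smoothing_sd_ms Gaussian smoothing SD, ms.
#' @return List with `t_ms` and `rate_hz`.
#' @export
population_rate <- function(spike_times, n_units, duration_ms, dt_ms = 0.1,
                            smoothing_sd_ms = 0.5) {
  .check_num(n_units, "n_units", positive = TRUE)
  n <- as.integer(round(duration_ms / dt_ms))
  counts <- tabulate(pmin(n, floor(spike_times / dt_ms) + 1L), nbins = n)
  rate <- counts / (n_units * dt_ms / 1000)
  half <- as.integer(ceiling(4 * smoothing_sd_ms / dt_ms))
  k <- stats::dnorm((-half:half) * dt_ms, 0, smoothing_sd_ms)
  k <- k / sum(k)
  sm <- stats::filter(c(rep(0, half), rate, rep(0, half)), k, sides = 2L)
  rate_sm <- as.numeric(sm[(half + 1L):(half + n)])
  rate_sm[is.na(rate_sm)] <- 0
  list(t_ms = (seq_len(n) - 0.5) * dt_ms, rate_hz = rate_sm)
}

#' Median-filtered power spectrum of the model LFP
#'
#' Squared FFT magnitude of the (demeaned, Hann-tapered) LFP, median-filtered
#' across frequency bins to suppress single-bin noise. The taper keeps the
#' large slow transient that the drive induces in the current-sum LFP from
#' leaking into the ripple band.
#'
#' @param lfp LFP trace (from [reconstruct_lfp()]).
#' @param fs Sampling rate, Hz.
#' @param median_k Median filter kernel width in bins (odd).
#' @param taper Apply the Hann taper before the FFT.
#' @param nfft FFT length; the default zero-pads to four times the trace
#'   length (next power of two) so that short transient oscillations are
#'   resolved on a fine frequency grid.
#' @return A `psd` data.frame (`freq`, `power`).
#' @export
psd_ripple <- function(lfp, fs, median_k = 5, taper = TRUE, nfft = NULL) {
  if (length(lfp) < 64) stop("LFP too short for a spectrum", call. = FALSE)
  x <- lfp - mean(lfp)
  n <- length(x)
  if (taper) x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  if (is.null(nfft)) nfft <- 2^ceiling(log2(4 * n))
  if (nfft > n) x <- c(x, numeric(nfft - n))
  X <- stats::fft(x)
  nf <- nfft %/% 2L
  p <- (Mod(X)[2:(nf + 1L)])^2
  if (median_k > 1) {
    k <- if (median_k %% 2 == 0) median_k + 1 else median_k
    p <- as.numeric(stats::runmed(p, k, endrule = "median"))
  }
  out <- data.frame(freq = (1:nf) * fs / nfft, power = p)
  class(out) <- c("psd", "data.frame")
  out
}

#' Extract the in-band spectral peak
#'
#' Whitens the spectrum against its local background (a running median over
#' the `+/- bg_halfwidth_hz` surround, with the central `+/- bg_notch_hz`
#' excluded) and takes the most prominent in-band bin. An
#' oscillation is declared present when the peak both (i) exceeds its local
#' background by at least the factor `prominence` and (ii) carries a
#' non-trivial share of the spectrum's absolute power
#' (`min_rel_power` of the spectral maximum) — a microscopic in-band
#' modulation riding on an otherwise quiet band does not count as ripple-like
#' activity.
#'
#' @param psd A `psd` data.frame.
#' @param band Analysis band, Hz (default 80-250, the reconstructed-LFP
#'   ripple range).
#' @param prominence Required ratio of peak power to the local median
#'   background.
#' @param bg_halfwidth_hz Half width of the background median window, Hz.
#' @param bg_notch_hz Half width of the central exclusion notch, Hz.
#' @param min_rel_power Required ratio of peak power to the whole-spectrum
#'   maximum.
#' @return List with `peak_freq_hz`, `peak_power`, `oscillation_present`.
#' @export
extract_peak <- function(psd, band = c(80, 250), prominence = 2.2,
                         bg_halfwidth_hz = 60, bg_notch_hz = 15,
                         min_rel_power = 0.01) {
  f_max <- max(psd$freq)
  if (band[1] >= f_max || band[2] > f_max + 1e-9)
    stop("`band` outside the spectrum's frequency support", call. = FALSE)
  # local background: running median over the +/- bg_halfwidth_hz surround,
  # excluding +/- bg_notch_hz so a genuine peak's own shoulder does not
  # inflate its background
  bg <- vapply(seq_along(psd$freq), function(i) {
    d <- abs(psd$freq - psd$freq[i])
    nb <- d > bg_notch_hz & d <= bg_halfwidth_hz
    if (!any(nb)) nb <- d <= bg_halfwidth_hz
    stats::median(psd$power[nb])
  }, numeric(1))
  ratio <- psd$power / pmax(bg, .Machine$double.xmin)
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  i <- sel[which.max(ratio[sel])]
  present <- ratio[i] >= prominence &&
    psd$power[i] >= min_rel_power * max(psd$power)
  list(peak_freq_hz = psd$freq[i], peak_power = psd$power[i],
       oscillation_present = isTRUE(present))
}

#' Sweep the strength of inhibition
#'
#' Repeats simulate / reconstruct / spectral-peak extraction over a grid of
#' inhibitory conductance multipliers on one axis (`"EI"`: I-to-E, range
#' 0.095-2; `"II"`: I-to-I, range 0.05-2) with independent random
#' realizations of connectivity and membrane noise per run; the non-swept
#' multiplier stays at 1.
#'
#' @param axis `"EI"` or `"II"`.
#' @param multipliers Multiplier grid.
#' @param n_realizations Independent realizations per level.
#' @param params Base [network_params()] (multipliers are overridden).
#' @param seed Integer seed; run seeds are derived per (level, realization).
#' @param duration_ms Simulated time per run.
#' @param drive A [drive_spec()] applied to every run.
#' @param band Peak-extraction band, Hz.
#' @return data.frame of class `sweep_result`: `axis`, `multiplier`,
#'   `realization`, `peak_freq_hz`, `peak_power`, `oscillation_present`,
#'   `runaway`.
#' @export
sweep_inhibition <- function(axis = c("EI", "II"), multipliers,
                             n_realizations = 5, params = network_params(),
                             seed = 1L, duration_ms = 100,
                             drive = drive_spec(), band = c(80, 250)) {
  axis <- match.arg(axis)
  rows <- list()
  for (li in seq_along(multipliers)) {
    m <- multipliers[li]
    p <- params
    if (axis == "EI") { p$c_gei <- m; p$c_gii <- 1 }
    else { p$c_gii <- m; p$c_gei <- 1 }
    for (r in seq_len(n_realizations)) {
      run_seed <- (seed * 1000L + li * 100L + r) %% .Machine$integer.max
      sim <- tryCatch(
        simulate_network(p, drive = drive, duration_ms = duration_ms,
                         seed = run_seed),
        error = function(e)
          stop(sprintf("sweep %s, multiplier %.3f, realization %d: %s",
                       axis, m, r, conditionMessage(e)), call. = FALSE))
      pk <- extract_peak(psd_ripple(reconstruct_lfp(sim), sim$fs_hz),
                         band = band)
      rows[[length(rows) + 1L]] <-
        data.frame(axis = axis, multiplier = m, realization = r,
                   peak_freq_hz = pk$peak_freq_hz,
                   peak_power = pk$peak_power,
                   oscillation_present = pk$oscillation_present,
                   runaway = sim$runaway)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Offset of the E-population rate peak relative to the drive center
#'
#' @param sim A `ca1_sim` simulated with external drive.
#' @param drive_center_ms Drive center; defaults to the one stored in `sim`.
#' @return Offset in ms (negative = rate peaks before the drive center).
#' @export
rate_peak_offset_vs_drive <- function(sim, drive_center_ms = NULL) {
  stopifnot(inherits(sim, "ca1_sim"))
  if (is.null(drive_center_ms)) {
    if (is.null(sim$drive)) stop("simulation was run without drive",
                                 call. = FALSE)
    drive_center_ms <- sim$drive$spec$center_time_ms
  }
  pr <- population_rate(sim$spikes_e$t_ms, sim$params$N_E, sim$duration_ms,
                        sim$params$dt_ms)
  if (diff(range(pr$rate_hz)) == 0)
    stop("constant population rate: peak undefined", call. = FALSE)
  pr$t_ms[which.max(pr$rate_hz)] - drive_center_ms
}
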