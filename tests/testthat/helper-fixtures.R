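# Shared fixtures: all built in code at test time.

# Welch-based log-log slope over a frequency range (independent of
# fit_spectrum; used as the oracle for exponent recovery).
slope_oracle <- function(x, fs, lo = 10, hi = 100) {
  p <- welch_psd(x, fs)
  sel <- p$freq >= lo & p$freq <= hi
  unname(stats::coef(stats::lm(log10(power) ~ log10(freq),
                               data = p[sel, ]))[2])
}

# A quiet two-channel background with known, low amplitude.
quiet_background <- function(duration_s = 60, fs = 1000, sd_uV = 3,
                             seed = 42) {
  set.seed(seed)
  cbind(pyramidale = stats::rnorm(duration_s * fs, 0, sd_uV),
        radiale = stats::rnorm(duration_s * fs, 0, sd_uV))
}

# Default high-SNR recording used by the detection recovery tests:
# clearly suprathreshold SPWs and >= 4-cycle ripples.
recovery_spec <- function(seed = 1L, duration_s = 120) {
  synth_spec(duration_s = duration_s, fs = 1000,
             aperiodic_exponent = 2, aperiodic_offset = 2.5,
             active_fraction = 0.7, spw_rate = 6, spw_amplitude_uV = 300,
             spw_halfwidth_ms = 60, ripple_prob = 0.6, ripple_freq_hz = 140,
             ripple_cycles = 6, ripple_amplitude_uV = 60, n_units = 40,
             baseline_rate_hz = 1, spw_modulation_z = 3, seed = seed)
}

# Match detected events to true events by peak-time proximity.
match_events <- function(detected, truth_peaks, tol_s = 0.05) {
  if (!nrow(detected)) {
    return(list(hits = 0L, false_pos = 0L))
  }
  hit <- vapply(truth_peaks, function(tp)
    any(abs(detected$peak_s - tp) <= tol_s |
          (detected$start_s - tol_s <= tp & detected$stop_s + tol_s >= tp)),
    logical(1))
  fp <- vapply(seq_len(nrow(detected)), function(i)
    !any(abs(truth_peaks - detected$peak_s[i]) <= tol_s |
           (detected$start_s[i] - tol_s <= truth_peaks &
              detected$stop_s[i] + tol_s >= truth_peaks)), logical(1))
  list(hits = sum(hit), false_pos = sum(fp))
}
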