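# I/O dialects: float32 binary + JSON sidecar for signals, CSV for events
# and spikes, and the end-to-end pipeline runner.

#' Write / read a multichannel signal
#'
#' Signals are stored as flat little-endian float32, channel-major (all of
#' channel 1, then channel 2, ...), next to a JSON sidecar
#' `{fs, n_channels, n_samples, depths_um, units}`. `read_signal()` is the
#' exact inverse up to float32 precision.
#'
#' @param x Samples x channels numeric matrix (uV).
#' @param path Path of the binary file; the sidecar is `paste0(path,
#'   ".json")`.
#' @param fs Sampling rate, Hz.
#' @param depths_um Optional per-channel depths.
#' @return `write_signal()` returns `path` invisibly; `read_signal()` a list
#'   with `lfp` (matrix), `fs`, `depths_um`.
#' @export
write_signal <- function(x, path, fs, depths_um = NULL) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (any(!is.finite(x))) stop("signal contains non-finite samples",
                               call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  meta <- list(fs = fs, n_channels = ncol(x), n_samples = nrow(x),
               depths_um = depths_um, units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar,
                                  call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (k in c("fs", "n_channels", "n_samples"))
    if (is.null(meta[[k]]))
      stop("sidecar is missing required field `", k, "`", call. = FALSE)
  n_expect <- meta$n_channels * meta$n_samples
  sz <- file.info(path)$size
  if (sz != 4L * n_expect)
    stop(sprintf("binary length mismatch: %d bytes found, %d expected",
                 sz, 4L * n_expect), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n_expect, size = 4L, endian = "little")
  if (any(!is.finite(v))) stop("signal contains non-finite samples",
                               call. = FALSE)
  list(lfp = matrix(v, ncol = meta$n_channels), fs = meta$fs,
       depths_um = meta$depths_um)
}

#' Write / read event tables (CSV dialect)
#'
#' Header `kind,start_s,stop_s,peak_s,peak_amp,halfwidth_s,n_cycles,
#' peak_freq_hz[,class]`; UTF-8, "." decimal. Reading validates that times
#' are ordered within rows and sorted by start, reporting offending line
#' numbers.
#'
#' @param events Event table.
#' @param path CSV path.
#' @param validate Set `FALSE` to skip row validation on read.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   table.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, validate = TRUE) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "start_s", "stop_s")
  if (!all(need %in% names(ev)))
    stop("event CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (validate && nrow(ev)) {
    bad <- which(ev$stop_s < ev$start_s)
    if (length(bad))
      stop("stop_s < start_s at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    if (is.unsorted(ev$start_s))
      stop("events are not sorted by start_s", call. = FALSE)
  }
  ev
}

#' Write / read spike trains (CSV dialect)
#'
#' Columns `unit_id,spike_s`. Reading returns the list-of-units
#' representation used across the package and validates per-unit time order.
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param path CSV path.
#' @param validate Set `FALSE` to skip sortedness validation on read.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()` a list
#'   of per-unit spike vectors.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    unit_id = rep(seq_along(spikes), vapply(spikes, length, integer(1))),
    spike_s = unlist(spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "spike_s") %in% names(df)))
    stop("spike CSV must have columns unit_id, spike_s", call. = FALSE)
  n_units <- if (nrow(df)) max(df$unit_id) else 0L
  out <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    st <- df$spike_s[df$unit_id == u]
    if (validate && is.unsorted(st))
      stop("unsorted spike times for unit ", u, call. = FALSE)
    out[[u]] <- st
  }
  out
}

#' Run the synthesize - detect - analyze pipeline
#'
#' Executes the stages configured in `config`: generate a synthetic
#' recording, detect active periods, SPWs and consensus ripples, couple them,
#' fit the spectrum, and compute event-locked spiking metrics. All outputs
#' are written under `out_dir` in the package's file dialects together with a
#' JSON run manifest. All randomness derives from the single `seed` in the
#' config.
#'
#' @param config List with elements `synth` (arguments for [synth_spec()]),
#'   optional `detect` (e.g. `band`), optional `fit` (e.g. `f_range`), and
#'   `seed`. A YAML file path is also accepted (parsed with the yaml
#'   package).
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ripplekit_run_")) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  known <- c("synth", "detect", "fit", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  spec <- do.call(synth_spec, c(config$synth, list(seed = seed)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  rec <- make_recording(spec)
  say("synth: %d SPWs, %d ripples injected",
      sum(rec$truth$kind == "spw"), sum(rec$truth$kind == "ripple"))
  write_signal(rec$lfp, file.path(out_dir, "signal.bin"), rec$fs,
               rec$depths_um)
  write_spikes(rec$spikes, file.path(out_dir, "spikes.csv"))
  write_events(rec$truth, file.path(out_dir, "truth.csv"))

  band <- if (!is.null(config$detect$band)) config$detect$band else c(80, 200)
  active <- detect_active_periods(rec$lfp[, 1], rec$fs)
  dif <- radial_difference(rec$lfp, rec$fs, 1, 2)
  mult <- adaptive_spw_multiplier(stats::sd(dif$x))
  say("detect: SPW multiplier %.2f SD", mult)
  spws <- detect_spw(dif, multiplier = mult)
  rip_p <- detect_ripples_power(rec$lfp[, 1], rec$fs, band = band)
  rip_b <- detect_ripples_bycycle(rec$lfp[, 1], rec$fs, band = band)
  cons <- consensus_ripples(rip_p, rip_b)
  parts <- couple_to_spw(cons, spws)
  cons_cls <- classify_ripple_length(cons)
  all_ev <- rbind(active, spws, cons_cls[names(active)])
  all_ev <- all_ev[order(all_ev$start_s), ]
  write_events(all_ev, file.path(out_dir, "events.csv"))
  say("detect: %d active periods, %d SPWs, %d consensus ripples (%d SPW-R)",
      nrow(active), nrow(spws), nrow(cons), nrow(parts$spwr))

  psd <- welch_psd(rec$lfp[, 1], rec$fs)
  f_range <- if (!is.null(config$fit$f_range)) config$fit$f_range else
    c(25, 45)
  fit <- fit_spectrum(psd, f_range,
                      max_peaks = if (is.null(config$fit$max_peaks)) 0 else
                        config$fit$max_peaks)
  say("fit: exponent %.2f, r2 %.3f, accepted %s", fit$exponent, fit$r2,
      quality_gate(fit))
  jsonlite::write_json(
    list(offset = fit$offset, exponent = fit$exponent,
         peaks = fit$peaks, r2 = fit$r2, accepted = quality_gate(fit)),
    file.path(out_dir, "spectral_fit.json"), auto_unbox = TRUE, digits = NA)

  metrics <- list()
  if (nrow(spws)) {
    ph <- peth_z(rec$spikes, spws$peak_s, spec$duration_s, seed = seed)
    metrics$peak_z <- if (ph$degenerate) NA else max(ph$z)
    metrics$fraction_modulated <-
      fraction_modulated_events(rec$spikes, spws, spec$duration_s,
                                seed = seed)
    metrics$spikes_per_event <-
      as.list(spikes_per_event_categories(rec$spikes, spws))
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ripplekit")),
    seed = seed, started = format(t0), finished = format(Sys.time()),
    config = config, spw_multiplier = mult,
    outputs = file.path(out_dir,
                        c("signal.bin", "spikes.csv", "truth.csv",
                          "events.csv", "spectral_fit.json", "metrics.json")),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
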