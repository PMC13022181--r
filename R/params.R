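#' Analysis parameters
#'
#' Bundle of every threshold and window used by the pipeline. Defaults encode
#' the standard MEA phenotyping constants: an electrode is inactive at <= 2
#' spikes/min; a single-channel burst is >= 5 spikes within a 30 ms window; a
#' network burst requires co-occurring bursts within 500 ms on the larger of
#' >= 5 electrodes or >= 30% of active electrodes; cross-correlation delays are
#' binned over 0-500 ms; recordings are compared over 5-minute pre/post
#' stimulation windows; temporal dynamics use 30 s bins.
#'
#' @param inactive_rate_max inactivity boundary, spikes per minute. An
#'   electrode is active only if its rate is strictly greater than this.
#' @param burst_min_spikes minimum spikes in a single-channel burst.
#' @param burst_window_s sliding window for the burst criterion, seconds.
#' @param nb_window_s span within which burst onsets must co-occur to form a
#'   network burst, seconds.
#' @param nb_min_electrodes fixed electrode floor of the hybrid network-burst
#'   rule.
#' @param nb_min_fraction fractional criterion of the hybrid rule (applied to
#'   the number of active electrodes, rounded up).
#' @param xcorr_max_lag_s maximum delay of the cross-correlogram, seconds.
#' @param xcorr_bin_s correlogram bin width, seconds (100 bins over 0-500 ms).
#' @param edge_threshold numeric edge threshold for connectivity graphs, or
#'   `NULL` to calibrate it per recording from jittered surrogates.
#' @param n_surrogates number of spike-time-jittered surrogates used when
#'   `edge_threshold` is `NULL`.
#' @param surrogate_jitter_s half-width of the uniform surrogate jitter,
#'   seconds.
#' @param surrogate_quantile quantile of the pooled surrogate pair strengths
#'   used as the calibrated edge threshold.
#' @param dynamics_bin_s bin width of the binned network dynamics, seconds.
#' @param dynamics_span_s span of the dynamics on each side of stimulation,
#'   seconds (60 s pre + 60 s post gives the plotted 120 s window).
#' @param window_s length of the pre- and post-stimulation analysis windows,
#'   seconds.
#' @param plasticity_bin_s sub-bin width used to test a pre/post rate change on
#'   one electrode, seconds (10 bins per 5-minute window).
#' @param alpha significance level for electrode-level and group tests.
#' @param n_permutations permutations for PERMANOVA.
#' @param rng_seed optional integer seed recorded with the parameters.
#' @return An object of class `mea_params` (a validated named list).
#' @examples
#' p <- mea_params()
#' p$burst_min_spikes
#' mea_params(nb_window_s = 0.25)$nb_window_s
#' @export
mea_params <- function(inactive_rate_max = 2,
                       burst_min_spikes = 5,
                       burst_window_s = 0.030,
                       nb_window_s = 0.500,
                       nb_min_electrodes = 5,
                       nb_min_fraction = 0.30,
                       xcorr_max_lag_s = 0.500,
                       xcorr_bin_s = 0.005,
                       edge_threshold = NULL,
                       n_surrogates = 20,
                       surrogate_jitter_s = 0.050,
                       surrogate_quantile = 0.95,
                       dynamics_bin_s = 30,
                       dynamics_span_s = 60,
                       window_s = 300,
                       plasticity_bin_s = 30,
                       alpha = 0.05,
                       n_permutations = 999,
                       rng_seed = NULL) {
  p <- list(
    inactive_rate_max = inactive_rate_max,
    burst_min_spikes = burst_min_spikes,
    burst_window_s = burst_window_s,
    nb_window_s = nb_window_s,
    nb_min_electrodes = nb_min_electrodes,
    nb_min_fraction = nb_min_fraction,
    xcorr_max_lag_s = xcorr_max_lag_s,
    xcorr_bin_s = xcorr_bin_s,
    edge_threshold = edge_threshold,
    n_surrogates = n_surrogates,
    surrogate_jitter_s = surrogate_jitter_s,
    surrogate_quantile = surrogate_quantile,
    dynamics_bin_s = dynamics_bin_s,
    dynamics_span_s = dynamics_span_s,
    window_s = window_s,
    plasticity_bin_s = plasticity_bin_s,
    alpha = alpha,
    n_permutations = n_permutations,
    rng_seed = rng_seed
  )
  validate_params(p)
  class(p) <- "mea_params"
  p
}

validate_params <- function(p) {
  num_fields <- setdiff(names(p), c("edge_threshold", "rng_seed"))
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  windows <- c("burst_window_s", "nb_window_s", "xcorr_max_lag_s",
               "xcorr_bin_s", "dynamics_bin_s", "dynamics_span_s", "window_s",
               "plasticity_bin_s", "surrogate_jitter_s")
  for (f in windows)
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0", call. = FALSE)
  if (p$nb_min_fraction <= 0 || p$nb_min_fraction >= 1)
    stop("nb_min_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (p$alpha <= 0 || p$alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (p$burst_min_spikes < 2)
    stop("burst_min_spikes must be >= 2", call. = FALSE)
  if (p$inactive_rate_max < 0)
    stop("inactive_rate_max must be >= 0", call. = FALSE)
  if (!is.null(p$edge_threshold) &&
      (!is.numeric(p$edge_threshold) || length(p$edge_threshold) != 1L))
    stop("edge_threshold must be NULL or a single number", call. = FALSE)
  invisible(p)
}

#' Stimulation protocol description
#'
#' Stores the electrical stimulation protocol applied between the pre- and
#' post-stimulation windows: repeated cycles of biphasic current pulses. The
#' defaults are three 20 s cycles of 20 biphasic pulses (100 uA, 66.7 us phase
#' width, 10 ms pulse duration) at 100 Hz. The numbers are stored as given;
#' only `n_cycles` and `cycle_duration_s` shape the recording timeline (the
#' stimulation gap between the analysis windows).
#'
#' @param n_cycles number of stimulation cycles.
#' @param cycle_duration_s duration of one cycle, seconds.
#' @param pulses_per_cycle biphasic pulses per cycle.
#' @param pulse_amplitude_uA pulse amplitude, microamperes.
#' @param phase_width_us phase width, microseconds.
#' @param pulse_duration_ms pulse duration, milliseconds.
#' @param frequency_hz intra-train pulse frequency, Hz.
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol()
#' @export
stim_protocol <- function(n_cycles = 3,
                          cycle_duration_s = 20,
                          pulses_per_cycle = 20,
                          pulse_amplitude_uA = 100,
                          phase_width_us = 66.7,
                          pulse_duration_ms = 10,
                          frequency_hz = 100) {
  p <- list(
    n_cycles = n_cycles,
    cycle_duration_s = cycle_duration_s,
    pulses_per_cycle = pulses_per_cycle,
    pulse_amplitude_uA = pulse_amplitude_uA,
    phase_width_us = phase_width_us,
    pulse_duration_ms = pulse_duration_ms,
    frequency_hz = frequency_hz
  )
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("protocol field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  class(p) <- "stim_protocol"
  p
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulation protocol: %d cycle(s) x %g s, %g pulses/cycle (%g uA, %g us phase, %g ms) at %g Hz\n",
    x$n_cycles, x$cycle_duration_s, x$pulses_per_cycle, x$pulse_amplitude_uA,
    x$phase_width_us, x$pulse_duration_ms, x$frequency_hz))
  invisible(x)
}

#' @export
print.mea_params <- function(x, ...) {
  cat("MEA analysis parameters:\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-20s %s\n", f,
                if (is.null(v)) "NULL (calibrated)" else format(v)))
  }
  invisible(x)
}

#' Load analysis parameters from a configuration file
#'
#' Reads a JSON object of parameter overrides. An absent or `NULL` path yields
#' the defaults of [mea_params()]; a partial configuration overrides only the
#' keys it names. Unknown keys are an error (the message suggests the nearest
#' valid key); non-numeric values for numeric fields are an error.
#'
#' @param path path to a JSON configuration file, or `NULL` for all defaults.
#' @return An `mea_params` object.
#' @seealso [write_config()] for the inverse.
#' @export
load_params <- function(path = NULL) {
  if (is.null(path) || !file.exists(path)) return(mea_params())
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- mea_params()
  check_config_keys(names(cfg), names(defaults))
  args <- unclass(defaults)
  for (k in names(cfg)) args[[k]] <- cfg[[k]]
  do.call(mea_params, args)
}

#' Load a stimulation protocol from a configuration file
#'
#' @param path path to a JSON configuration file, or `NULL` for defaults.
#' @return A `stim_protocol` object.
#' @export
load_protocol <- function(path = NULL) {
  if (is.null(path) || !file.exists(path)) return(stim_protocol())
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- stim_protocol()
  check_config_keys(names(cfg), names(defaults))
  args <- unclass(defaults)
  for (k in names(cfg)) args[[k]] <- cfg[[k]]
  do.call(stim_protocol, args)
}

check_config_keys <- function(keys, valid) {
  bad <- setdiff(keys, valid)
  if (length(bad)) {
    near <- vapply(bad, function(k) {
      d <- utils::adist(k, valid)
      valid[which.min(d)]
    }, character(1))
    stop("unknown configuration key(s): ",
         paste0("'", bad, "' (did you mean '", near, "'?)", collapse = ", "),
         "\nvalid keys: ", paste(valid, collapse = ", "), call. = FALSE)
  }
}

#' Write a parameter or protocol object to a configuration file
#'
#' Serializes an [mea_params()] or [stim_protocol()] object to JSON such that
#' [load_params()] / [load_protocol()] reproduce it exactly.
#'
#' @param x an `mea_params` or `stim_protocol` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, "mea_params") || inherits(x, "stim_protocol"))
  jsonlite::write_json(Filter(Negate(is.null), unclass(x)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
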