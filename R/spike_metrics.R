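#' Classify an electrode as active or inactive
#'
#' An electrode is inactive when it fires at or below `inactive_rate_max`
#' spikes per minute over the window (default 2/min); it is active only when
#' its window-average rate is strictly greater. The rule is applied to the
#' window-average rate, not to per-minute bins.
#'
#' @param train a [spike_train()].
#' @param window half-open window `c(start, end)` in seconds.
#' @param params an [mea_params()].
#' @return `TRUE` if active.
#' @examples
#' # 10 spikes over 5 min = 2/min: inactive; 11 spikes: active
#' classify_active(spike_train(1, seq(1, 300, length.out = 10)), c(0, 300))
#' classify_active(spike_train(1, seq(1, 300, length.out = 11)), c(0, 300))
#' @export
classify_active <- function(train, window, params = mea_params()) {
  len <- window[2] - window[1]
  if (!is.finite(len) || len <= 0)
    stop("window must have positive length", call. = FALSE)
  n <- length(spikes_in_window(train, window)$times)
  rate_per_min <- n / (len / 60)
  rate_per_min > params$inactive_rate_max
}

#' Active electrodes of a recording
#'
#' Applies [classify_active()] to every electrode over one window. The
#' convention throughout the pipeline is to determine the active set on the
#' pre-stimulation window and hold it fixed for that session's post-window
#' metrics, so the stimulation effect cannot change the denominator
#' population.
#'
#' @inheritParams classify_active
#' @param recording an [mea_recording()].
#' @return Integer vector of active electrode ids.
#' @export
active_electrodes <- function(recording, window, params = mea_params()) {
  act <- vapply(recording$trains, classify_active, logical(1),
                window = window, params = params)
  unname(vapply(recording$trains[act], `[[`, integer(1), "electrode_id"))
}

#' Per-electrode metrics over a window
#'
#' @inheritParams active_electrodes
#' @return Data frame with one row per electrode: `electrode_id`, `n_spikes`,
#'   `firing_rate_hz`, `mean_amplitude_uV`, `is_active`.
#' @export
electrode_metrics <- function(recording, window, params = mea_params()) {
  len <- window[2] - window[1]
  if (len <= 0) stop("window must have positive length", call. = FALSE)
  rows <- lapply(recording$trains, function(tr) {
    s <- spikes_in_window(tr, window)
    n <- length(s$times)
    data.frame(electrode_id = tr$electrode_id,
               n_spikes = n,
               firing_rate_hz = n / len,
               mean_amplitude_uV = if (is.null(s$amplitudes) || n == 0)
                 NA_real_ else mean(s$amplitudes),
               is_active = (n / (len / 60)) > params$inactive_rate_max)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(electrode_id = integer(), n_spikes = integer(),
                      firing_rate_hz = numeric(),
                      mean_amplitude_uV = numeric(), is_active = logical())
  out
}

#' Two-step mean firing rate
#'
#' The recording-level mean firing rate is computed in two steps: the firing
#' rate of each active electrode, then the unweighted mean of those rates over
#' the active set. Inactive electrodes are excluded entirely, so the value is
#' not driven by how many electrodes happen to be active. With zero active
#' electrodes the result is `NA` (a flagged missing value, never zero).
#'
#' @inheritParams active_electrodes
#' @param active optional integer vector of electrode ids to treat as the
#'   active set (e.g. the pre-window set reused for the post window); `NULL`
#'   determines it from `window`.
#' @return Mean firing rate in Hz, or `NA_real_` if no electrode is active.
#' @export
mean_firing_rate <- function(recording, window, params = mea_params(),
                             active = NULL) {
  m <- electrode_metrics(recording, window, params)
  keep <- if (is.null(active)) m$is_active else m$electrode_id %in% active
  if (!any(keep)) return(NA_real_)
  mean(m$firing_rate_hz[keep])
}

#' Amplitude statistics
#'
#' Spike amplitude is the minimum (most negative) voltage of the waveform
#' after baseline correction. The recording-level summary mirrors the two-step
#' mean firing rate: per-electrode mean amplitude, averaged over active
#' electrodes (a pooled mean over all spikes is also returned). The pooled
#' amplitude histogram is normalized to unit area.
#'
#' @inheritParams mean_firing_rate
#' @param breaks histogram breaks (passed to [graphics::hist()] semantics via
#'   [base::cut()]); default 30 equal bins over the pooled range.
#' @return List with `per_electrode` (data frame), `two_step_mean_uV`,
#'   `pooled_mean_uV`, and `histogram` (data frame of bin mids and unit-area
#'   densities), plus a `missing` flag when no amplitudes are present.
#' @export
amplitude_stats <- function(recording, window, params = mea_params(),
                            active = NULL, breaks = 30) {
  m <- electrode_metrics(recording, window, params)
  keep <- if (is.null(active)) m$is_active else m$electrode_id %in% active
  pooled <- unlist(lapply(recording$trains, function(tr) {
    s <- spikes_in_window(tr, window)
    s$amplitudes
  }), use.names = FALSE)
  no_amp <- is.null(pooled) || !length(pooled) || all(is.na(pooled))
  two_step <- if (any(keep) && !all(is.na(m$mean_amplitude_uV[keep])))
    mean(m$mean_amplitude_uV[keep], na.rm = TRUE) else NA_real_
  hist_df <- NULL
  if (!no_amp) {
    h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
    hist_df <- data.frame(mid_uV = h$mids, density = h$density)
  }
  list(per_electrode = m[, c("electrode_id", "mean_amplitude_uV")],
       two_step_mean_uV = two_step,
       pooled_mean_uV = if (no_amp) NA_real_ else mean(pooled, na.rm = TRUE),
       histogram = hist_df,
       missing = no_amp)
}

#' Threshold spike detection on a raw voltage trace
#'
#' Optional ingestion stage for uniformly sampled extracellular traces:
#' negative threshold crossings at `k` robust noise estimates (MAD) below the
#' median baseline, with refractory enforcement. The reported amplitude is the
#' minimum voltage within +/- 1 ms of the crossing after baseline subtraction.
#'
#' @param trace numeric voltage samples, microvolts.
#' @param fs_hz sampling rate, Hz (typically 30000).
#' @param electrode_id electrode label for the returned train.
#' @param k detection threshold in MADs (default 5).
#' @param refractory_s minimum separation between detections, seconds.
#' @return A [spike_train()].
#' @export
detect_spikes_raw <- function(trace, fs_hz = 30000, electrode_id = 1L,
                              k = 5, refractory_s = 0.001) {
  if (any(!is.finite(trace)))
    stop("trace contains non-finite samples", call. = FALSE)
  x <- trace - stats::median(trace)
  sigma <- stats::mad(x)
  if (sigma == 0) sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma == 0)
    return(spike_train(electrode_id, numeric(0), numeric(0)))
  thr <- -k * sigma
  below <- x < thr
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(onsets)) return(spike_train(electrode_id, numeric(0),
                                          numeric(0)))
  half <- round(0.001 * fs_hz)
  refr <- max(1L, round(refractory_s * fs_hz))
  keep <- onsets[c(TRUE, diff(onsets) > refr)]
  times <- numeric(0); amps <- numeric(0)
  last <- -Inf
  for (i in keep) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    j <- lo + which.min(x[lo:hi]) - 1L
    t <- (j - 1L) / fs_hz
    if (t - last <= refractory_s) next
    times <- c(times, t); amps <- c(amps, x[j]); last <- t
  }
  o <- order(times)
  dup <- duplicated(times[o])
  spike_train(electrode_id, times[o][!dup], amps[o][!dup])
}
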