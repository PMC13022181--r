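#' Spike train of one electrode
#'
#' @param electrode_id integer electrode label.
#' @param spike_times strictly increasing spike times, seconds from recording
#'   start.
#' @param amplitudes spike amplitudes in microvolts (negative-going trough of
#'   the waveform after baseline correction), one per spike, or `NULL` when
#'   amplitudes were not measured.
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(1, c(0.1, 0.2, 0.35), c(-60, -55, -72))
#' @export
spike_train <- function(electrode_id, spike_times, amplitudes = NULL) {
  electrode_id <- as.integer(electrode_id)
  spike_times <- as.numeric(spike_times)
  if (length(electrode_id) != 1L || is.na(electrode_id))
    stop("electrode_id must be a single integer", call. = FALSE)
  if (anyNA(spike_times)) stop("spike_times must not contain NA", call. = FALSE)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing (electrode ", electrode_id,
         ")", call. = FALSE)
  if (length(spike_times) && spike_times[1] < 0)
    stop("spike_times must be >= 0", call. = FALSE)
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != length(spike_times))
      stop("amplitudes must have one value per spike (electrode ",
           electrode_id, ")", call. = FALSE)
  }
  structure(list(electrode_id = electrode_id,
                 spike_times = spike_times,
                 amplitudes = amplitudes),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train, electrode %d: %d spikes%s\n", x$electrode_id,
              length(x$spike_times),
              if (length(x$spike_times))
                sprintf(" in [%.3f, %.3f] s", x$spike_times[1],
                        x$spike_times[length(x$spike_times)]) else ""))
  invisible(x)
}

#' MEA recording of one organoid session
#'
#' One recording session of one organoid on a multielectrode array: the spike
#' trains of all electrodes, the stimulation epochs, and the identifying
#' metadata (organoid, patient, experimental group, session). All downstream
#' analysis operates on this container.
#'
#' @param trains list of [spike_train()] objects with unique electrode ids.
#' @param duration_s total recording duration, seconds.
#' @param organoid_id,patient_id,group_label,session_index identifying
#'   metadata. `session_index` is typically 1 or 2 (two sessions per organoid,
#'   48 h apart).
#' @param stim_epochs numeric matrix (or 2-column data frame) of stimulation
#'   intervals, one row per epoch, columns start/end in seconds; `NULL` for a
#'   recording without stimulation. Epochs must be ordered and non-overlapping.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(trains, duration_s,
                          organoid_id = "organoid1",
                          patient_id = "patient1",
                          group_label = "Control",
                          session_index = 1L,
                          stim_epochs = NULL) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a single positive number", call. = FALSE)
  if (!is.list(trains) || (length(trains) &&
                           !all(vapply(trains, inherits, logical(1),
                                       "spike_train"))))
    stop("trains must be a list of spike_train objects", call. = FALSE)
  ids <- vapply(trains, `[[`, integer(1), "electrode_id")
  if (anyDuplicated(ids))
    stop("duplicate electrode id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (tr in trains) {
    n <- length(tr$spike_times)
    if (n && tr$spike_times[n] > duration_s)
      stop("electrode ", tr$electrode_id, " has spike times beyond duration_s",
           call. = FALSE)
  }
  if (!is.null(stim_epochs)) {
    stim_epochs <- as.matrix(stim_epochs)
    if (ncol(stim_epochs) != 2L)
      stop("stim_epochs must have two columns (start_s, end_s)", call. = FALSE)
    colnames(stim_epochs) <- c("start_s", "end_s")
    if (any(stim_epochs[, 2] <= stim_epochs[, 1]))
      stop("stim epochs must have end > start", call. = FALSE)
    if (nrow(stim_epochs) > 1L) {
      o <- order(stim_epochs[, 1])
      stim_epochs <- stim_epochs[o, , drop = FALSE]
      if (any(stim_epochs[-1, 1] < stim_epochs[-nrow(stim_epochs), 2]))
        stop("stim epochs must be non-overlapping", call. = FALSE)
    }
    if (any(stim_epochs < 0) || any(stim_epochs > duration_s))
      stop("stim epochs must lie within [0, duration_s]", call. = FALSE)
  }
  names(trains) <- as.character(ids)
  structure(list(organoid_id = as.character(organoid_id),
                 patient_id = as.character(patient_id),
                 group_label = as.character(group_label),
                 session_index = as.integer(session_index),
                 duration_s = duration_s,
                 trains = trains,
                 stim_epochs = stim_epochs),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  n_spk <- sum(vapply(x$trains, function(t) length(t$spike_times), integer(1)))
  cat(sprintf("MEA recording: organoid %s (patient %s, group %s, session %d)\n",
              x$organoid_id, x$patient_id, x$group_label, x$session_index))
  cat(sprintf("  %d electrode(s), %d spikes, %.0f s%s\n", length(x$trains),
              n_spk, x$duration_s,
              if (is.null(x$stim_epochs)) ", no stimulation"
              else sprintf(", %d stimulation epoch(s)", nrow(x$stim_epochs))))
  invisible(x)
}

#' Pre- and post-stimulation analysis windows
#'
#' The pre-stimulation window is the `window_s` span ending at the first
#' stimulation epoch; the post-stimulation window is the `window_s` span
#' starting at the end of the last epoch. Both are clipped to the recording and
#' returned as half-open intervals `[start, end)`. A recording without
#' stimulation has a pre window only.
#'
#' @param recording an [mea_recording()].
#' @param params an [mea_params()].
#' @return List with elements `pre` and `post`, each `c(start, end)` or `NULL`.
#' @export
analysis_windows <- function(recording, params = mea_params()) {
  w <- params$window_s
  if (is.null(recording$stim_epochs) || nrow(recording$stim_epochs) == 0L) {
    return(list(pre = c(0, min(w, recording$duration_s)), post = NULL))
  }
  first_stim <- recording$stim_epochs[1, 1]
  last_stim <- recording$stim_epochs[nrow(recording$stim_epochs), 2]
  pre <- c(max(0, first_stim - w), first_stim)
  post <- c(last_stim, min(recording$duration_s, last_stim + w))
  if (diff(pre) <= 0) pre <- NULL
  if (diff(post) <= 0) post <- NULL
  list(pre = pre, post = post)
}

# spikes of one train inside a half-open window [w[1], w[2])
spikes_in_window <- function(train, window) {
  t <- train$spike_times
  keep <- t >= window[1] & t < window[2]
  list(times = t[keep],
       amplitudes = if (is.null(train$amplitudes)) NULL
                    else train$amplitudes[keep])
}

#' Read a spike-event file and its metadata sidecar
#'
#' The native on-disk format is a plain CSV with header
#' `electrode,time_s,amplitude_uV` plus a JSON metadata sidecar holding
#' `organoid_id`, `patient_id`, `group_label`, `session_index`, `duration_s`
#' and optional `stim_epochs` (list of `[start, end]` pairs). Rows with spike
#' times outside `[0, duration_s]` raise an error naming the offending row;
#' duplicated (electrode, time) pairs are dropped with a warning.
#'
#' @param path path to the spike-event CSV.
#' @param metadata_path path to the metadata JSON; defaults to `path` with the
#'   extension replaced by `.meta.json`.
#' @return An [mea_recording()].
#' @seealso [write_spike_events()]
#' @export
read_spike_events <- function(path,
                              metadata_path = default_meta_path(path)) {
  if (!file.exists(path)) stop("spike-event file not found: ", path,
                               call. = FALSE)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  required <- c("organoid_id", "patient_id", "group_label", "session_index",
                "duration_s")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("metadata missing required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ev <- tryCatch(
    utils::read.csv(path, colClasses = c("integer", "numeric", "numeric")),
    warning = function(w) stop("malformed spike-event file: ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("malformed spike-event file: ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(names(ev), c("electrode", "time_s", "amplitude_uV")))
    stop("spike-event header must be 'electrode,time_s,amplitude_uV'",
         call. = FALSE)
  bad <- which(!is.finite(ev$time_s) | is.na(ev$electrode))
  if (length(bad))
    stop("malformed spike-event row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  out_of_range <- which(ev$time_s < 0 | ev$time_s > meta$duration_s)
  if (length(out_of_range))
    stop("spike time outside [0, duration_s] at data row(s) ",
         paste(utils::head(out_of_range, 5L), collapse = ", "),
         " (e.g. time ", ev$time_s[out_of_range[1]], " s vs duration ",
         meta$duration_s, " s)", call. = FALSE)
  dup <- duplicated(ev[, c("electrode", "time_s")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (electrode, time) pair(s) removed",
            call. = FALSE)
    ev <- ev[!dup, , drop = FALSE]
  }
  trains <- lapply(split(ev, ev$electrode), function(d) {
    o <- order(d$time_s)
    spike_train(d$electrode[1], d$time_s[o], d$amplitude_uV[o])
  })
  trains <- trains[order(vapply(trains, `[[`, integer(1), "electrode_id"))]
  stim <- meta$stim_epochs
  if (!is.null(stim) && length(stim)) {
    stim <- matrix(unlist(stim), ncol = 2, byrow = !is.matrix(stim))
    if (is.matrix(meta$stim_epochs)) stim <- meta$stim_epochs
  } else stim <- NULL
  mea_recording(unname(trains), meta$duration_s,
                organoid_id = meta$organoid_id,
                patient_id = meta$patient_id,
                group_label = meta$group_label,
                session_index = meta$session_index,
                stim_epochs = stim)
}

default_meta_path <- function(path) sub("\\.[^.]*$", "", path) |>
  paste0(".meta.json")

#' Write a recording to the native spike-event format
#'
#' Writes the spike-event CSV (times with 6 decimal places) and the metadata
#' sidecar so that [read_spike_events()] reproduces the recording exactly up to
#' microsecond time formatting.
#'
#' @param recording an [mea_recording()].
#' @param path output CSV path.
#' @param metadata_path output metadata path; defaults as in
#'   [read_spike_events()].
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(recording, path,
                               metadata_path = default_meta_path(path)) {
  stopifnot(inherits(recording, "mea_recording"))
  rows <- lapply(recording$trains, function(tr) {
    n <- length(tr$spike_times)
    if (!n) return(NULL)
    data.frame(electrode = rep(tr$electrode_id, n),
               time_s = sprintf("%.6f", tr$spike_times),
               amplitude_uV = if (is.null(tr$amplitudes)) rep(NA_real_, n)
                              else tr$amplitudes)
  })
  ev <- rbind_rows(rows)
  if (is.null(ev))
    ev <- data.frame(electrode = integer(), time_s = character(),
                     amplitude_uV = numeric())
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(ev, con, row.names = FALSE, quote = FALSE)
  meta <- list(organoid_id = recording$organoid_id,
               patient_id = recording$patient_id,
               group_label = recording$group_label,
               session_index = recording$session_index,
               duration_s = recording$duration_s)
  if (!is.null(recording$stim_epochs))
    meta$stim_epochs <- unname(apply(recording$stim_epochs, 1, c,
                                     simplify = FALSE))
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
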