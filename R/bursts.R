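#' Detect single-channel bursts
#'
#' A burst is triggered whenever at least `burst_min_spikes` spikes (default 5)
#' fall within a sliding `burst_window_s` window (default 30 ms): a run of
#' `m` consecutive spikes qualifies iff its span is at most the window.
#' Overlapping qualified windows are merged into one maximal event whose
#' boundaries are the first and last spike of the merged run, so events are
#' disjoint.
#'
#' @param train a [spike_train()] (times sorted, as enforced by the
#'   constructor).
#' @param params an [mea_params()].
#' @param window optional half-open window restricting the spikes considered.
#' @return Data frame with columns `electrode_id`, `start_s`, `end_s`,
#'   `n_spikes`, one row per burst (zero rows for no bursts).
#' @examples
#' # five spikes spanning 20 ms: exactly one burst
#' detect_scb(spike_train(1, c(0, 5, 10, 15, 20) / 1000))
#' # four spikes: no burst
#' detect_scb(spike_train(1, c(0, 10, 20, 30) / 1000))
#' @export
detect_scb <- function(train, params = mea_params(), window = NULL) {
  t <- train$spike_times
  if (!is.null(window)) t <- t[t >= window[1] & t < window[2]]
  m <- params$burst_min_spikes
  w <- params$burst_window_s
  empty <- data.frame(electrode_id = integer(), start_s = numeric(),
                      end_s = numeric(), n_spikes = integer())
  n <- length(t)
  if (n < m) return(empty)
  i <- seq_len(n - m + 1L)
  ok <- which(t[i + m - 1L] - t[i] <= w)
  if (!length(ok)) return(empty)
  # qualified windows cover spike indices [s, s + m - 1]; merge overlapping
  starts <- ok
  ends <- ok + m - 1L
  brk <- which(starts[-1] > ends[-length(ends)] + 0L)  # next start beyond end
  grp_start <- c(1L, brk + 1L)
  grp_end <- c(brk, length(starts))
  data.frame(electrode_id = train$electrode_id,
             start_s = t[starts[grp_start]],
             end_s = t[ends[grp_end]],
             n_spikes = ends[grp_end] - starts[grp_start] + 1L)
}

#' Detect network bursts
#'
#' A network burst is a cluster of single-channel burst onsets spanning at most
#' `nb_window_s` (default 500 ms) on at least
#' `T = max(nb_min_electrodes, ceiling(nb_min_fraction * n_active))` distinct
#' active electrodes — the hybrid rule combining a fixed floor of 5 electrodes
#' with 30% of the active set. Clustering is greedy left-to-right over sorted
#' onsets (earliest onset opens a candidate window); clusters are disjoint in
#' membership.
#'
#' @param scbs data frame of single-channel bursts as returned by
#'   [detect_scb()] (rows from several electrodes combined), or a list of such
#'   data frames.
#' @param active_set integer vector of active electrode ids; only their bursts
#'   participate, and the 30% criterion is taken over this set.
#' @param params an [mea_params()].
#' @return Data frame with columns `start_s`, `end_s`, `n_members`,
#'   `members` (list column of electrode ids).
#' @export
detect_nb <- function(scbs, active_set, params = mea_params()) {
  if (is.list(scbs) && !is.data.frame(scbs))
    scbs <- do.call(rbind, scbs)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_members = integer())
  empty$members <- list()
  if (length(active_set) == 0L || is.null(scbs) || nrow(scbs) == 0L)
    return(empty)
  scbs <- scbs[scbs$electrode_id %in% active_set, , drop = FALSE]
  if (nrow(scbs) == 0L) return(empty)
  T_req <- nb_threshold(length(active_set), params)
  o <- order(scbs$start_s)
  onset <- scbs$start_s[o]
  elec <- scbs$electrode_id[o]
  bend <- scbs$end_s[o]
  n <- length(onset)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && onset[j + 1L] - onset[i] <= params$nb_window_s)
      j <- j + 1L
    members <- unique(elec[i:j])
    if (length(members) >= T_req) {
      out[[length(out) + 1L]] <-
        data.frame(start_s = onset[i], end_s = max(bend[i:j]),
                   n_members = length(members),
                   members = I(list(sort(members))))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Network-burst electrode threshold
#'
#' The hybrid criterion: the larger of the fixed floor (>= 5 electrodes) and
#' 30% of the active electrodes, rounded up.
#'
#' @param n_active number of active electrodes.
#' @param params an [mea_params()].
#' @return Integer threshold.
#' @examples
#' nb_threshold(10)  # max(5, ceiling(3)) = 5
#' nb_threshold(20)  # max(5, ceiling(6)) = 6
#' @export
nb_threshold <- function(n_active, params = mea_params()) {
  max(params$nb_min_electrodes, ceiling(params$nb_min_fraction * n_active))
}

#' Burst rates over a window
#'
#' Per-electrode single-channel burst counts per minute (with the recording
#' level value as the two-step mean over active electrodes), burst shape
#' summaries, and the network-burst count and rate.
#'
#' @param recording an [mea_recording()].
#' @param window half-open analysis window, seconds.
#' @param params an [mea_params()].
#' @param active active electrode ids; `NULL` determines them from `window`.
#' @return List with `per_electrode` (electrode_id, n_bursts, scb_per_min),
#'   `scb_per_min` (two-step mean, `NA` with zero active electrodes),
#'   `mean_burst_duration_s`, `mean_spikes_per_burst`, `n_nb`, `nb_per_min`,
#'   `mean_nb_size`, and the detected `scbs` / `nbs` tables.
#' @export
burst_rates <- function(recording, window, params = mea_params(),
                        active = NULL) {
  if (is.null(active)) active <- active_electrodes(recording, window, params)
  minutes <- (window[2] - window[1]) / 60
  scb_list <- lapply(recording$trains, detect_scb, params = params,
                     window = window)
  scbs <- rbind_rows(scb_list)
  per_el <- data.frame(
    electrode_id = vapply(recording$trains, `[[`, integer(1), "electrode_id"),
    n_bursts = vapply(scb_list, nrow, integer(1)))
  per_el$scb_per_min <- per_el$n_bursts / minutes
  act <- per_el$electrode_id %in% active
  nbs <- detect_nb(scbs, active, params)
  act_scb <- if (is.null(scbs)) scbs else
    scbs[scbs$electrode_id %in% active, , drop = FALSE]
  list(per_electrode = per_el,
       scb_per_min = if (any(act)) mean(per_el$scb_per_min[act]) else NA_real_,
       mean_burst_duration_s = if (!is.null(act_scb) && nrow(act_scb))
         mean(act_scb$end_s - act_scb$start_s) else NA_real_,
       mean_spikes_per_burst = if (!is.null(act_scb) && nrow(act_scb))
         mean(act_scb$n_spikes) else NA_real_,
       n_nb = nrow(nbs),
       nb_per_min = nrow(nbs) / minutes,
       mean_nb_size = if (nrow(nbs)) mean(nbs$n_members) else NA_real_,
       scbs = scbs, nbs = nbs)
}
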