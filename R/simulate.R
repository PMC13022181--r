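#' Group activity profile for the synthetic MEA generator
#'
#' Describes the statistical structure of one experimental group's recordings:
#' per-electrode baseline Poisson rates (with between-electrode dispersion),
#' spike amplitudes, injected single-channel bursts, synchronized network
#' bursts over electrode subsets, pairwise spike-time coupling, and the
#' stimulation-effect mixture (probabilities of short-term depression,
#' potentiation, or no change, with multiplicative post/pre rate effects).
#'
#' @param name group label.
#' @param n_electrodes number of electrodes on the array.
#' @param base_rate_hz mean baseline firing rate per electrode, Hz.
#' @param rate_dispersion log-normal sd (on the log scale) of per-electrode
#'   baseline rates around `base_rate_hz`; 0 gives identical rates.
#' @param amplitude_mean_uV mean spike amplitude magnitude, microvolts
#'   (amplitudes are emitted negative).
#' @param amplitude_cv coefficient of variation of spike amplitudes.
#' @param burst_rate_per_min expected injected single-channel bursts per
#'   electrode per minute.
#' @param burst_spikes_mean mean spikes per injected burst (minimum 5; spikes
#'   are laid down at a fixed 4 ms inter-spike interval so every injected burst
#'   satisfies the 5-spikes-in-30-ms criterion by construction).
#' @param nb_rate_per_min expected injected network bursts per minute.
#' @param nb_electrode_fraction fraction of electrodes recruited into each
#'   network burst.
#' @param coupling_strength probability that a spike on the source electrode of
#'   a coupled pair is copied onto its partner (with uniform 0-20 ms jitter).
#' @param coupling_pairs integer matrix of electrode index pairs (columns
#'   source, target), or `NULL` to couple disjoint random pairs covering half
#'   the array.
#' @param p_std,p_stp,p_none stimulation-effect mixture; must sum to 1.
#' @param std_effect,stp_effect multiplicative post/pre rate effects applied to
#'   electrodes drawn as depressed / potentiated.
#' @param post_coupling_factor multiplier on `coupling_strength` in the
#'   post-stimulation window (< 1 emulates stimulation-induced network
#'   decoupling; 1 leaves coupling unchanged).
#' @return An object of class `group_profile`.
#' @examples
#' group_profile("Control", n_electrodes = 12, base_rate_hz = 2)
#' @export
group_profile <- function(name = "Control",
                          n_electrodes = 60,
                          base_rate_hz = 2,
                          rate_dispersion = 0.3,
                          amplitude_mean_uV = 60,
                          amplitude_cv = 0.25,
                          burst_rate_per_min = 2,
                          burst_spikes_mean = 8,
                          nb_rate_per_min = 1,
                          nb_electrode_fraction = 0.5,
                          coupling_strength = 0.2,
                          coupling_pairs = NULL,
                          p_std = 0.6, p_stp = 0.1, p_none = 0.3,
                          std_effect = 0.5, stp_effect = 1.6,
                          post_coupling_factor = 1) {
  if (abs(p_std + p_stp + p_none - 1) > 1e-8)
    stop("p_std + p_stp + p_none must equal 1", call. = FALSE)
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]", call. = FALSE)
  if (base_rate_hz < 0 || burst_rate_per_min < 0 || nb_rate_per_min < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (n_electrodes < 1) stop("n_electrodes must be >= 1", call. = FALSE)
  if (!is.null(coupling_pairs)) {
    coupling_pairs <- as.matrix(coupling_pairs)
    if (ncol(coupling_pairs) != 2L || any(coupling_pairs < 1) ||
        any(coupling_pairs > n_electrodes))
      stop("coupling_pairs must be a 2-column matrix of electrode indices",
           call. = FALSE)
  }
  structure(list(name = name, n_electrodes = as.integer(n_electrodes),
                 base_rate_hz = base_rate_hz,
                 rate_dispersion = rate_dispersion,
                 amplitude_mean_uV = amplitude_mean_uV,
                 amplitude_cv = amplitude_cv,
                 burst_rate_per_min = burst_rate_per_min,
                 burst_spikes_mean = burst_spikes_mean,
                 nb_rate_per_min = nb_rate_per_min,
                 nb_electrode_fraction = nb_electrode_fraction,
                 coupling_strength = coupling_strength,
                 coupling_pairs = coupling_pairs,
                 p_std = p_std, p_stp = p_stp, p_none = p_none,
                 std_effect = std_effect, stp_effect = stp_effect,
                 post_coupling_factor = post_coupling_factor),
            class = "group_profile")
}

# run code with a temporary RNG state seeded from `seed`
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# homogeneous Poisson spike times on [t0, t1) at rate r (Hz)
rpoisson_train <- function(r, t0, t1) {
  if (r <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, r * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# one injected burst: >= 5 spikes at 4 ms ISI from `onset`
burst_spike_block <- function(onset, n_spikes, isi = 0.004) {
  onset + (seq_len(n_spikes) - 1) * isi
}

draw_burst_sizes <- function(n, mean_spikes, min_spikes = 5L) {
  extra <- max(0, mean_spikes - min_spikes)
  min_spikes + stats::rpois(n, extra)
}

#' Simulate one MEA recording with ground truth
#'
#' Generates a recording whose statistical structure matches the assumptions of
#' the downstream analysis: electrodes fire as Poisson processes around drawn
#' baseline rates; single-channel bursts are injected as fixed-ISI spike blocks
#' (guaranteed to satisfy the burst criterion); network bursts inject
#' near-simultaneous bursts on a sampled electrode subset; coupled electrode
#' pairs share jittered spike copies; each electrode draws a stimulation-effect
#' label (depression / potentiation / none) whose multiplicative rate effect
#' applies throughout the post-stimulation window. Amplitudes are negative with
#' log-normal magnitude. The timeline is `pre_s` seconds of baseline, the
#' stimulation epochs of `protocol`, then `post_s` seconds.
#'
#' @param profile a [group_profile()].
#' @param protocol a [stim_protocol()], or `NULL` for an unstimulated
#'   recording.
#' @param pre_s,post_s lengths of the pre- and post-stimulation segments,
#'   seconds (5 minutes each by default).
#' @param seed integer seed; identical `(profile, seed)` give identical output.
#' @param organoid_id,patient_id,session_index metadata passed through to the
#'   recording.
#' @return A list with elements `recording` (an [mea_recording()]) and `truth`
#'   (ground truth: per-electrode baseline rates, stimulation labels and effect
#'   sizes, injected burst and network-burst intervals, coupled pairs).
#' @examples
#' sim <- simulate_recording(group_profile(n_electrodes = 4), seed = 1,
#'                           pre_s = 60, post_s = 60)
#' sim$recording
#' @export
simulate_recording <- function(profile,
                               protocol = stim_protocol(),
                               pre_s = 300, post_s = 300,
                               seed = NULL,
                               organoid_id = "organoid1",
                               patient_id = "patient1",
                               session_index = 1L) {
  stopifnot(inherits(profile, "group_profile"))
  if (pre_s <= 0 || post_s < 0)
    stop("window durations must be positive", call. = FALSE)
  local_seed(seed, {
    n_el <- profile$n_electrodes
    stim <- NULL
    post_start <- pre_s
    if (!is.null(protocol)) {
      starts <- pre_s + (seq_len(protocol$n_cycles) - 1) *
        protocol$cycle_duration_s
      stim <- cbind(start_s = starts,
                    end_s = starts + protocol$cycle_duration_s)
      post_start <- max(stim[, 2])
    }
    duration <- post_start + post_s

    base_rates <- if (profile$rate_dispersion > 0)
      stats::rlnorm(n_el, log(profile$base_rate_hz) -
                      profile$rate_dispersion^2 / 2, profile$rate_dispersion)
    else rep(profile$base_rate_hz, n_el)

    labels <- sample(c("STD", "STP", "none"), n_el, replace = TRUE,
                     prob = c(profile$p_std, profile$p_stp, profile$p_none))
    effects <- ifelse(labels == "STD", profile$std_effect,
                      ifelse(labels == "STP", profile$stp_effect, 1))

    pre_min <- pre_s / 60
    post_min <- post_s / 60

    spike_list <- vector("list", n_el)
    burst_truth <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      r <- base_rates[e]
      base <- c(rpoisson_train(r, 0, post_start),
                rpoisson_train(r * effects[e], post_start, duration))
      nb_pre <- stats::rpois(1, profile$burst_rate_per_min * pre_min)
      nb_post <- stats::rpois(1, profile$burst_rate_per_min * effects[e] *
                                post_min)
      onsets <- c(if (nb_pre) stats::runif(nb_pre, 0, pre_s - 0.2),
                  if (nb_post) stats::runif(nb_post, post_start,
                                            duration - 0.2))
      sizes <- draw_burst_sizes(length(onsets), profile$burst_spikes_mean)
      bspk <- unlist(mapply(burst_spike_block, onsets, sizes,
                            SIMPLIFY = FALSE))
      spike_list[[e]] <- c(base, bspk)
      if (length(onsets))
        burst_truth[[e]] <- data.frame(electrode = e, start_s = onsets,
                                       end_s = onsets + (sizes - 1) * 0.004,
                                       n_spikes = sizes)
    }

    # network bursts: simultaneous burst blocks on a sampled subset
    nb_members <- max(2L, ceiling(profile$nb_electrode_fraction * n_el))
    n_nb <- stats::rpois(1, profile$nb_rate_per_min * (pre_min + post_min))
    nb_truth <- NULL
    if (n_nb > 0 && profile$nb_rate_per_min > 0) {
      nb_onsets <- sort(stats::runif(n_nb, 0, pre_s + post_s - 0.5))
      nb_onsets <- ifelse(nb_onsets < pre_s - 0.5, nb_onsets,
                          nb_onsets - (pre_s - 0.5) + post_start)
      nb_onsets <- pmin(nb_onsets, duration - 0.5)
      nb_list <- vector("list", n_nb)
      for (k in seq_len(n_nb)) {
        members <- sort(sample(n_el, nb_members))
        jit <- stats::runif(nb_members, 0, 0.1)
        sizes <- draw_burst_sizes(nb_members, profile$burst_spikes_mean)
        for (m in seq_along(members)) {
          e <- members[m]
          onset <- nb_onsets[k] + jit[m]
          spike_list[[e]] <- c(spike_list[[e]],
                               burst_spike_block(onset, sizes[m]))
          burst_truth[[e]] <- rbind(
            burst_truth[[e]],
            data.frame(electrode = e, start_s = onset,
                       end_s = onset + (sizes[m] - 1) * 0.004,
                       n_spikes = sizes[m]))
        }
        nb_list[[k]] <- data.frame(nb = k, onset_s = nb_onsets[k],
                                   n_members = nb_members,
                                   members = I(list(members)))
      }
      nb_truth <- do.call(rbind, nb_list)
    }

    # pairwise coupling: jittered spike copies source -> target
    pairs <- profile$coupling_pairs
    if (is.null(pairs) && profile$coupling_strength > 0 && n_el >= 2) {
      perm <- sample(n_el)
      n_pairs <- floor(n_el / 2)
      pairs <- cbind(perm[seq_len(n_pairs)],
                     perm[n_pairs + seq_len(n_pairs)])
    }
    if (!is.null(pairs) && profile$coupling_strength > 0) {
      for (k in seq_len(nrow(pairs))) {
        src <- spike_list[[pairs[k, 1]]]
        if (!length(src)) next
        c_pre <- profile$coupling_strength
        c_post <- c_pre * profile$post_coupling_factor
        prob <- ifelse(src >= post_start, c_post, c_pre)
        keep <- stats::runif(length(src)) < prob
        if (any(keep)) {
          copies <- src[keep] + stats::runif(sum(keep), 0, 0.020)
          spike_list[[pairs[k, 2]]] <- c(spike_list[[pairs[k, 2]]], copies)
        }
      }
    }

    trains <- vector("list", n_el)
    amp_sdlog <- sqrt(log(1 + profile$amplitude_cv^2))
    for (e in seq_len(n_el)) {
      t <- sort(spike_list[[e]])
      t <- t[t >= 0 & t < duration]
      t <- t[!duplicated(t)]
      amp <- -stats::rlnorm(length(t),
                            log(profile$amplitude_mean_uV) - amp_sdlog^2 / 2,
                            amp_sdlog)
      trains[[e]] <- spike_train(e, t, amp)
    }

    rec <- mea_recording(trains, duration,
                         organoid_id = organoid_id, patient_id = patient_id,
                         group_label = profile$name,
                         session_index = session_index, stim_epochs = stim)
    truth <- list(base_rate_hz = base_rates,
                  stim_label = labels,
                  stim_effect = effects,
                  bursts = do.call(rbind, burst_truth),
                  network_bursts = nb_truth,
                  coupling_pairs = pairs,
                  pre_window = c(0, pre_s),
                  post_window = c(post_start, duration))
    list(recording = rec, truth = truth)
  })
}

#' Default group profiles for cohort studies
#'
#' Three shipped activity profiles spanning the qualitative phenotype space
#' the pipeline is designed to resolve:
#' \describe{
#'   \item{Control}{moderate baseline rate (2 Hz), moderate coupling, mixed
#'     depression-biased stimulation response with a mild post-stimulation
#'     decoupling.}
#'   \item{Hypoactive}{fourfold reduced baseline rate, smaller amplitudes,
#'     sparse bursting and weak coupling — the hypoactive pattern of
#'     idiopathic-like lines.}
#'   \item{Hyperactive}{elevated baseline rate and bursting, strong coupling
#'     with a pronounced post-stimulation decoupling, and a strongly
#'     depression-dominant stimulation response — the hyperactive,
#'     STD-biased pattern of several syndromic lines.}
#' }
#' Effect sizes are fixed design choices of the generator; only the array
#' size is exposed so studies can trade electrode count against runtime.
#'
#' @param n_electrodes electrodes per simulated array.
#' @return Named list of three [group_profile()] objects.
#' @export
default_profiles <- function(n_electrodes = 12) {
  list(
    Control = group_profile("Control", n_electrodes = n_electrodes,
                            base_rate_hz = 2, coupling_strength = 0.25,
                            post_coupling_factor = 0.6,
                            p_std = 0.5, p_stp = 0.1, p_none = 0.4),
    Hypoactive = group_profile("Hypoactive", n_electrodes = n_electrodes,
                               base_rate_hz = 0.5, amplitude_mean_uV = 35,
                               burst_rate_per_min = 0.5,
                               nb_rate_per_min = 0.3,
                               coupling_strength = 0.1,
                               p_std = 0.5, p_stp = 0.1, p_none = 0.4),
    Hyperactive = group_profile("Hyperactive", n_electrodes = n_electrodes,
                                base_rate_hz = 5, burst_rate_per_min = 4,
                                nb_rate_per_min = 2, coupling_strength = 0.3,
                                post_coupling_factor = 0.15,
                                p_std = 0.85, p_stp = 0.05, p_none = 0.10,
                                std_effect = 0.4))
}

#' Simulate a hierarchical cohort of recordings
#'
#' Samples a full study: groups -> patients -> organoids -> sessions, with
#' log-normal patient- and organoid-level random effects on baseline firing
#' rates. Each recording is generated by [simulate_recording()] from a
#' sub-seed drawn deterministically from `seed`, so the whole cohort is
#' reproducible.
#'
#' @param profiles list of [group_profile()] objects with distinct names.
#' @param patients_per_group,organoids_per_patient,sessions cohort dimensions
#'   (two sessions per organoid by default).
#' @param protocol a [stim_protocol()] shared by all recordings.
#' @param pre_s,post_s window lengths passed to [simulate_recording()].
#' @param patient_sd,organoid_sd log-scale standard deviations of the patient
#'   and organoid rate effects.
#' @param seed integer seed for the whole cohort.
#' @return An object of class `mea_cohort`: a list of entries, each with
#'   `recording` and `truth`.
#' @export
simulate_cohort <- function(profiles,
                            patients_per_group = 2,
                            organoids_per_patient = 3,
                            sessions = 2,
                            protocol = stim_protocol(),
                            pre_s = 300, post_s = 300,
                            patient_sd = 0.15,
                            organoid_sd = 0.10,
                            seed = NULL) {
  if (inherits(profiles, "group_profile")) profiles <- list(profiles)
  nms <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate group name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  if (patients_per_group < 1 || organoids_per_patient < 1 || sessions < 1)
    stop("cohort counts must be >= 1", call. = FALSE)
  local_seed(seed, {
    entries <- list()
    for (g in seq_along(profiles)) {
      prof <- profiles[[g]]
      for (p in seq_len(patients_per_group)) {
        pid <- sprintf("%s_P%d", prof$name, p)
        p_eff <- stats::rlnorm(1, -patient_sd^2 / 2, patient_sd)
        for (o in seq_len(organoids_per_patient)) {
          oid <- sprintf("%s_O%d", pid, o)
          o_eff <- stats::rlnorm(1, -organoid_sd^2 / 2, organoid_sd)
          prof_o <- prof
          prof_o$base_rate_hz <- prof$base_rate_hz * p_eff * o_eff
          for (s in seq_len(sessions)) {
            sub_seed <- sample.int(.Machine$integer.max, 1)
            entries[[length(entries) + 1L]] <-
              simulate_recording(prof_o, protocol, pre_s, post_s,
                                 seed = sub_seed, organoid_id = oid,
                                 patient_id = pid, session_index = s)
          }
        }
      }
    }
    structure(entries, class = "mea_cohort")
  })
}

#' @export
print.mea_cohort <- function(x, ...) {
  groups <- vapply(x, function(e) e$recording$group_label, character(1))
  cat(sprintf("MEA cohort: %d recording(s) across %d group(s)\n",
              length(x), length(unique(groups))))
  print(table(group = groups))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one spike-event CSV + metadata sidecar per recording (via
#' [write_spike_events()]) and one ground-truth JSON per recording.
#'
#' @param cohort an `mea_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mea_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in cohort) {
    rec <- e$recording
    stem <- sprintf("%s_S%d", rec$organoid_id, rec$session_index)
    write_spike_events(rec, file.path(dir, paste0(stem, ".csv")))
    truth <- e$truth
    truth$coupling_pairs <- if (is.null(truth$coupling_pairs)) NULL
      else apply(truth$coupling_pairs, 1, c, simplify = FALSE)
    if (!is.null(truth$network_bursts))
      truth$network_bursts <- lapply(seq_len(nrow(truth$network_bursts)),
        function(i) list(onset_s = truth$network_bursts$onset_s[i],
                         members = truth$network_bursts$members[[i]]))
    jsonlite::write_json(truth, file.path(dir, paste0(stem, ".truth.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}
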