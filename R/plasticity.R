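#' Classify one electrode's stimulation response
#'
#' Compares an electrode's mean spike rate in the pre-stimulation window with
#' the post-stimulation window. Both windows are split into equal sub-bins
#' (default 30 s, i.e. 10 bins per 5-minute window) and the per-bin spike
#' counts are compared with a two-sided Mann-Whitney U test at `alpha`. A
#' significant decrease is short-term depression (STD), a significant increase
#' short-term potentiation (STP), and no significant difference "none".
#' Amplitude plays no role in the classification.
#'
#' @param train a [spike_train()].
#' @param pre_window,post_window half-open windows of equal length, seconds.
#' @param params an [mea_params()].
#' @param allow_unequal permit windows of unequal length (rates and bins are
#'   still computed per window).
#' @return A one-row data frame: `electrode_id`, `label` (`"STD"`, `"STP"` or
#'   `"none"`), `pre_rate_hz`, `post_rate_hz`, `delta_relative`
#'   (`(post - pre)/pre`), `p_value`.
#' @export
classify_electrode <- function(train, pre_window, post_window,
                               params = mea_params(),
                               allow_unequal = FALSE) {
  len_pre <- pre_window[2] - pre_window[1]
  len_post <- post_window[2] - post_window[1]
  if (len_pre <= 0 || len_post <= 0)
    stop("windows must have positive length", call. = FALSE)
  if (!allow_unequal && abs(len_pre - len_post) > 1e-9)
    stop("pre and post windows must have equal length ",
         "(set allow_unequal = TRUE to override)", call. = FALSE)
  bin <- params$plasticity_bin_s
  pre_counts <- bin_counts(train$spike_times, pre_window, bin)
  post_counts <- bin_counts(train$spike_times, post_window, bin)
  pre_rate <- sum(pre_counts) / len_pre
  post_rate <- sum(post_counts) / len_post
  p <- if (all(c(pre_counts, post_counts) ==
               c(pre_counts, post_counts)[1])) 1
  else suppressWarnings(
    stats::wilcox.test(post_counts, pre_counts, exact = FALSE)$p.value)
  if (is.na(p)) p <- 1
  label <- "none"
  if (p < params$alpha && post_rate < pre_rate) label <- "STD"
  if (p < params$alpha && post_rate > pre_rate) label <- "STP"
  data.frame(electrode_id = train$electrode_id, label = label,
             pre_rate_hz = pre_rate, post_rate_hz = post_rate,
             delta_relative = if (pre_rate > 0)
               (post_rate - pre_rate) / pre_rate else NA_real_,
             p_value = p)
}

# spike counts in consecutive `bin`-second bins over a half-open window
bin_counts <- function(times, window, bin) {
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2] - 1e-9)
    edges <- c(edges, window[2])
  t <- times[times >= window[1] & times < window[2]]
  if (!length(t)) return(integer(length(edges) - 1L))
  idx <- findInterval(t, edges, rightmost.closed = FALSE, left.open = FALSE)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Classify every active electrode of a recording
#'
#' Runs [classify_electrode()] over the active set (determined on the
#' pre-stimulation window and held fixed).
#'
#' @param recording an [mea_recording()] with stimulation epochs.
#' @param params an [mea_params()].
#' @param active optional active electrode ids; `NULL` uses the pre window.
#' @return Data frame of per-electrode results.
#' @export
classify_plasticity <- function(recording, params = mea_params(),
                                active = NULL) {
  w <- analysis_windows(recording, params)
  if (is.null(w$post))
    stop("recording has no post-stimulation window", call. = FALSE)
  if (is.null(active)) active <- active_electrodes(recording, w$pre, params)
  rows <- lapply(recording$trains, function(tr) {
    if (!(tr$electrode_id %in% active)) return(NULL)
    classify_electrode(tr, w$pre, w$post, params,
                       allow_unequal = abs(diff(w$pre) - diff(w$post)) > 1e-9)
  })
  rbind_rows(rows)
}

#' Summarize plasticity over a recording's electrodes
#'
#' Fractions of STD / STP / unchanged electrodes, the mean absolute relative
#' rate change within each class, and the signed STP/STD ratio built from the
#' summed magnitudes `S_STP` and `S_STD` of the relative changes: positive
#' `+S_STP/S_STD` when potentiation dominates (`S_STP >= S_STD`), negative
#' `-S_STD/S_STP` when depression dominates. An empty denominator caps the
#' ratio at +/- `cap` (flagged); with both classes empty the ratio is the
#' boundary value +1.
#'
#' @param results data frame from [classify_plasticity()] /
#'   [classify_electrode()].
#' @param cap magnitude cap for an empty-denominator ratio.
#' @return List: `f_std`, `f_stp`, `f_none`, `n`, `std_magnitude`,
#'   `stp_magnitude`, `signed_ratio`, `ratio_capped`.
#' @examples
#' res <- data.frame(electrode_id = 1:10,
#'                   label = rep(c("STD", "STP", "none"), c(6, 2, 2)),
#'                   delta_relative = c(rep(-0.4, 6), 0.3, 0.5, 0, 0))
#' summarize_plasticity(res)$f_std
#' @export
summarize_plasticity <- function(results, cap = 10) {
  if (is.null(results) || nrow(results) == 0L)
    return(list(f_std = NA_real_, f_stp = NA_real_, f_none = NA_real_,
                n = 0L, std_magnitude = NA_real_, stp_magnitude = NA_real_,
                signed_ratio = NA_real_, ratio_capped = NA))
  n <- nrow(results)
  is_std <- results$label == "STD"
  is_stp <- results$label == "STP"
  mag <- abs(results$delta_relative)
  s_std <- sum(mag[is_std], na.rm = TRUE)
  s_stp <- sum(mag[is_stp], na.rm = TRUE)
  capped <- FALSE
  if (s_std == 0 && s_stp == 0) {
    ratio <- 1
  } else if (s_std == 0) {
    ratio <- cap; capped <- TRUE
  } else if (s_stp == 0) {
    ratio <- -cap; capped <- TRUE
  } else if (s_stp >= s_std) {
    ratio <- s_stp / s_std
  } else {
    ratio <- -s_std / s_stp
  }
  list(f_std = mean(is_std), f_stp = mean(is_stp),
       f_none = mean(!is_std & !is_stp), n = n,
       std_magnitude = if (any(is_std)) mean(mag[is_std], na.rm = TRUE)
                       else NA_real_,
       stp_magnitude = if (any(is_stp)) mean(mag[is_stp], na.rm = TRUE)
                       else NA_real_,
       signed_ratio = ratio, ratio_capped = capped)
}
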