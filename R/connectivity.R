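#' Spike-time cross-correlogram of an electrode pair
#'
#' Counts ordered spike-time delays `t_j - t_i` within `[0, xcorr_max_lag_s)`
#' (default 0-500 ms), binned at `xcorr_bin_s` (default 5 ms), and normalizes
#' the counts by the geometric mean of the spike counts, `sqrt(N_i * N_j)` —
#' a normalization by spike counts that is symmetric under exchanging the
#' trains. An empty train yields an all-zero correlogram flagged `empty`.
#'
#' @param train_i,train_j [spike_train()] objects (or bare numeric time
#'   vectors).
#' @param params an [mea_params()].
#' @param window optional half-open window restricting both trains.
#' @return An object of class `correlogram`: list with `lag_edges_s` (bin
#'   edges), `counts`, `normalized`, `n_i`, `n_j`, `empty`.
#' @export
cross_correlogram <- function(train_i, train_j, params = mea_params(),
                              window = NULL) {
  ti <- if (inherits(train_i, "spike_train")) train_i$spike_times
        else as.numeric(train_i)
  tj <- if (inherits(train_j, "spike_train")) train_j$spike_times
        else as.numeric(train_j)
  if (!is.null(window)) {
    ti <- ti[ti >= window[1] & ti < window[2]]
    tj <- tj[tj >= window[1] & tj < window[2]]
  }
  max_lag <- params$xcorr_max_lag_s
  bin <- params$xcorr_bin_s
  nbins <- ceiling(max_lag / bin - 1e-9)
  edges <- seq(0, by = bin, length.out = nbins + 1L)
  empty <- length(ti) == 0L || length(tj) == 0L
  counts <- if (empty) integer(nbins)
            else delay_bin_counts(ti, tj, max_lag, bin)
  norm <- if (empty) rep(0, nbins)
          else counts / sqrt(length(ti) * length(tj))
  structure(list(lag_edges_s = edges, counts = counts, normalized = norm,
                 n_i = length(ti), n_j = length(tj), empty = empty),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Cross-correlogram: %d bins over [0, %g] s, N_i = %d, N_j = %d%s\n",
              length(x$counts), x$lag_edges_s[length(x$lag_edges_s)],
              x$n_i, x$n_j, if (x$empty) " (empty train)" else ""))
  invisible(x)
}

# scalar coupling strength of an ordered pair: peak normalized correlogram bin
pair_strength_ordered <- function(ti, tj, max_lag, bin) {
  if (!length(ti) || !length(tj)) return(0)
  max(delay_bin_counts(ti, tj, max_lag, bin)) / sqrt(length(ti) * length(tj))
}

#' Pairwise connectivity strengths
#'
#' Symmetric strength of every electrode pair: the peak normalized correlogram
#' bin, maximized over the two delay orderings.
#'
#' @param trains named list of spike-time vectors (already windowed).
#' @param params an [mea_params()].
#' @return Symmetric matrix of strengths with zero diagonal.
#' @keywords internal
pair_strength_matrix <- function(trains, params) {
  n <- length(trains)
  W <- matrix(0, n, n, dimnames = list(names(trains), names(trains)))
  if (n < 2) return(W)
  max_lag <- params$xcorr_max_lag_s
  bin <- params$xcorr_bin_s
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      s <- max(pair_strength_ordered(trains[[a]], trains[[b]], max_lag, bin),
               pair_strength_ordered(trains[[b]], trains[[a]], max_lag, bin))
      W[a, b] <- W[b, a] <- s
    }
  }
  W
}

# windowed spike-time vectors of the active electrodes, named by id
windowed_trains <- function(recording, window, active) {
  trains <- recording$trains[as.character(active)]
  out <- lapply(trains, function(tr) {
    t <- tr$spike_times
    t[t >= window[1] & t < window[2]]
  })
  names(out) <- as.character(active)
  out
}

#' Surrogate-calibrated edge threshold
#'
#' Builds the null distribution of pair strengths by jittering every spike
#' uniformly in `+/- surrogate_jitter_s` (default 50 ms) — which destroys
#' millisecond-scale coupling while preserving rates — over `n_surrogates`
#' surrogate recordings, and returns the `surrogate_quantile` (default 95th
#' percentile) of the pooled surrogate strengths. Uses the current RNG stream;
#' seed the caller for reproducibility.
#'
#' @param recording an [mea_recording()].
#' @param window half-open window, seconds.
#' @param params an [mea_params()].
#' @param active active electrode ids.
#' @return Numeric threshold.
#' @export
surrogate_threshold <- function(recording, window, params = mea_params(),
                                active = NULL) {
  if (is.null(active)) active <- active_electrodes(recording, window, params)
  if (length(active) < 2) return(Inf)
  stats::quantile(surrogate_strengths(recording, window, params, active),
                  probs = params$surrogate_quantile, names = FALSE, type = 7)
}

# pooled pair strengths of jittered surrogates of one window
surrogate_strengths <- function(recording, window, params, active) {
  trains <- windowed_trains(recording, window, active)
  jit <- params$surrogate_jitter_s
  pooled <- numeric(0)
  for (s in seq_len(params$n_surrogates)) {
    jtr <- lapply(trains, function(t) {
      if (!length(t)) return(t)
      sort(t + stats::runif(length(t), -jit, jit))
    })
    W <- pair_strength_matrix(jtr, params)
    pooled <- c(pooled, W[upper.tri(W)])
  }
  pooled
}

#' Build a functional connectivity graph
#'
#' Computes pairwise correlogram strengths over the active electrodes, keeps
#' edges whose strength strictly exceeds the threshold, and summarizes the
#' resulting undirected simple graph: network size (number of nodes with at
#' least one edge), density `2E / (N (N - 1))` over the `N` active nodes, and
#' the mean local clustering coefficient (nodes of degree < 2 contribute 0).
#' With fewer than two active electrodes the graph is flagged degenerate and
#' all metrics are 0.
#'
#' @param recording an [mea_recording()].
#' @param window half-open window, seconds.
#' @param params an [mea_params()]. If `params$edge_threshold` is `NULL` and no
#'   `threshold` is supplied, a surrogate-calibrated threshold is computed.
#' @param active active electrode ids; `NULL` determines them from `window`.
#' @param threshold optional numeric edge threshold overriding both
#'   `params$edge_threshold` and surrogate calibration.
#' @return An object of class `connectivity_graph`: `nodes`, `weights`
#'   (symmetric matrix), `threshold`, `edges` (two-column matrix of ids),
#'   `network_size`, `density`, `clustering`, `degenerate`.
#' @export
build_graph <- function(recording, window, params = mea_params(),
                        active = NULL, threshold = NULL) {
  if (is.null(active)) active <- active_electrodes(recording, window, params)
  if (length(active) < 2) {
    return(structure(list(nodes = active,
                          weights = matrix(0, length(active), length(active)),
                          threshold = NA_real_,
                          edges = matrix(integer(), 0, 2),
                          network_size = 0L, density = 0, clustering = 0,
                          degenerate = TRUE),
                     class = "connectivity_graph"))
  }
  trains <- windowed_trains(recording, window, active)
  W <- pair_strength_matrix(trains, params)
  if (is.null(threshold)) {
    threshold <- if (!is.null(params$edge_threshold)) params$edge_threshold
      else surrogate_threshold(recording, window, params, active)
  }
  graph_from_weights(W, threshold, active)
}

# assemble a connectivity_graph from a strength matrix and threshold
graph_from_weights <- function(W, threshold, nodes) {
  A <- (W > threshold) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  deg <- igraph::degree(g)
  n <- length(nodes)
  e <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  edges <- cbind(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
  structure(list(nodes = nodes, weights = W, threshold = threshold,
                 edges = edges,
                 network_size = sum(deg >= 1),
                 density = if (n >= 2) 2 * e / (n * (n - 1)) else 0,
                 clustering = if (length(cc)) mean(cc) else 0,
                 degenerate = FALSE),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf(
    "Connectivity graph: %d node(s), %d edge(s)%s\n  network size %d, density %.3f, clustering %.3f%s\n",
    length(x$nodes), nrow(x$edges),
    if (is.na(x$threshold)) "" else sprintf(" (threshold %.4g)", x$threshold),
    x$network_size, x$density, x$clustering,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Binned temporal dynamics of graph metrics
#'
#' Builds an independent connectivity graph in each consecutive
#' `dynamics_bin_s` bin (default 30 s) over the last `dynamics_span_s` before
#' the first stimulation epoch and the first `dynamics_span_s` after the last
#' (default 60 s each side — a 120 s window around stimulation). The active set
#' is determined once on the pre-stimulation window and held fixed across
#' bins. Spans exceeding the available data are truncated with a warning.
#'
#' The edge threshold for the bins is calibrated at bin scale: the correlogram
#' peak of a short window has larger sampling fluctuations than that of the
#' full 5-minute window, so a full-window threshold does not transfer. By
#' default the surrogate null is therefore rebuilt from jittered surrogates of
#' the pre-stimulation bins themselves (pooled across bins), unless a numeric
#' `threshold` or `params$edge_threshold` is supplied.
#'
#' @param recording an [mea_recording()] with stimulation epochs.
#' @param params an [mea_params()].
#' @param active optional fixed active set.
#' @param threshold optional fixed edge threshold.
#' @return Data frame with one row per bin: `phase` (`"pre"`/`"post"`),
#'   `bin_start_s`, `bin_end_s`, `network_size`, `density`, `clustering`.
#' @export
binned_dynamics <- function(recording, params = mea_params(),
                            active = NULL, threshold = NULL) {
  w <- analysis_windows(recording, params)
  if (is.null(w$post))
    stop("recording has no post-stimulation window", call. = FALSE)
  if (is.null(active)) active <- active_electrodes(recording, w$pre, params)
  bin <- params$dynamics_bin_s
  span <- params$dynamics_span_s
  pre_span <- min(span, diff(w$pre))
  post_span <- min(span, diff(w$post))
  if (pre_span < span || post_span < span)
    warning("dynamics span truncated to available data", call. = FALSE)
  mk_bins <- function(from, to, phase) {
    if (to - from < bin) return(NULL)
    starts <- seq(from, to - bin + 1e-9, by = bin)
    starts <- starts[starts + bin <= to + 1e-9]
    if (!length(starts)) return(NULL)
    data.frame(phase = phase, bin_start_s = starts, bin_end_s = starts + bin)
  }
  bins <- rbind(mk_bins(w$pre[2] - pre_span, w$pre[2], "pre"),
                mk_bins(w$post[1], w$post[1] + post_span, "post"))
  if (is.null(bins) || nrow(bins) == 0L) {
    warning("recording shorter than one dynamics bin; empty series",
            call. = FALSE)
    return(data.frame(phase = character(), bin_start_s = numeric(),
                      bin_end_s = numeric(), network_size = integer(),
                      density = numeric(), clustering = numeric()))
  }
  if (is.null(threshold)) {
    threshold <- if (!is.null(params$edge_threshold)) params$edge_threshold
      else if (length(active) < 2) Inf
      else {
        pre_bins <- bins[bins$phase == "pre", , drop = FALSE]
        pooled <- unlist(lapply(seq_len(nrow(pre_bins)), function(i)
          surrogate_strengths(recording,
                              c(pre_bins$bin_start_s[i],
                                pre_bins$bin_end_s[i]),
                              params, active)))
        stats::quantile(pooled, probs = params$surrogate_quantile,
                        names = FALSE, type = 7)
      }
  }
  metrics <- lapply(seq_len(nrow(bins)), function(i) {
    g <- build_graph(recording, c(bins$bin_start_s[i], bins$bin_end_s[i]),
                     params, active = active, threshold = threshold)
    data.frame(network_size = g$network_size, density = g$density,
               clustering = g$clustering)
  })
  cbind(bins, do.call(rbind, metrics))
}

#' Relative change, percent
#'
#' `(post - pre) / pre * 100`; negative values are reductions. A zero
#' pre-value gives a flagged missing value (`NA` with a warning), never zero.
#'
#' @param pre_value,post_value numeric (vectorized).
#' @return Percent change.
#' @examples
#' relative_change(10, 5)  # -50
#' relative_change(4, 5)   # +25
#' @export
relative_change <- function(pre_value, post_value) {
  out <- (post_value - pre_value) / pre_value * 100
  zero <- !is.na(pre_value) & pre_value == 0
  if (any(zero)) {
    warning("relative_change undefined for zero pre-value; returning NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Paired pre/post comparison
#'
#' Two-sided paired t test on per-organoid (post - pre) metric differences.
#' Zero variance of the differences is flagged degenerate (statistic 0 and
#' p = 1 when all differences are zero; `NA` p otherwise).
#'
#' @param pre,post numeric vectors of paired metric values.
#' @return List: `statistic`, `p_value`, `df`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_pre_post_test <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(statistic = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                p_value = if (all(d == 0)) 1 else NA_real_,
                df = length(d) - 1L, mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d),
       degenerate = FALSE)
}
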