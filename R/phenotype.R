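#' The default 18-feature electrophysiological phenotype
#'
#' Names (in order) of the 18 per-organoid features entering the PCA and radar
#' analyses, spanning resting-state activity, bursting, pre/post connectivity,
#' plasticity and stimulation response. The registry is data-driven: pass a
#' subset or a reordered/renamed registry to [extract_features()] to redefine
#' the phenotype.
#'
#' @return Character vector of 18 feature names.
#' @export
mea_features <- function() {
  c("mfr_pre_hz", "mean_amplitude_pre_uV", "n_active_electrodes",
    "scb_per_min", "mean_burst_duration_s", "mean_spikes_per_burst",
    "nb_per_min", "mean_nb_size",
    "network_size_pre", "density_pre", "clustering_pre",
    "network_size_post", "density_post", "clustering_post",
    "f_stp", "f_std", "stp_std_ratio", "network_size_change_pct")
}

#' Extract the feature vector of one recording
#'
#' Computes the full 18-feature electrophysiological phenotype of one organoid
#' session. The active set and the connectivity edge threshold are determined
#' once on the pre-stimulation window and reused for all post-window
#' quantities. Every feature is traceable to one upstream operation; upstream
#' missing values propagate as `NA` (flagged, never silently zero). The
#' stimulation-response feature is the relative change of the mean binned
#' network size across the pre/post dynamics bins.
#'
#' @param x an [mea_recording()] or a `list(recording=, truth=)` entry from
#'   [simulate_recording()].
#' @param params an [mea_params()].
#' @param features character vector of feature names (default the full
#'   registry of [mea_features()]).
#' @param seed optional integer seed for the surrogate threshold calibration.
#' @return One-row data frame: metadata columns (`organoid_id`, `patient_id`,
#'   `group_label`, `session_index`) followed by the requested features.
#' @export
extract_features <- function(x, params = mea_params(),
                             features = mea_features(), seed = NULL) {
  rec <- if (inherits(x, "mea_recording")) x else x$recording
  stopifnot(inherits(rec, "mea_recording"))
  unknown <- setdiff(features, mea_features())
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  local_seed(seed, {
    w <- analysis_windows(rec, params)
    active <- active_electrodes(rec, w$pre, params)
    mfr <- mean_firing_rate(rec, w$pre, params, active = active)
    amp <- amplitude_stats(rec, w$pre, params, active = active)
    br <- burst_rates(rec, w$pre, params, active = active)
    have_post <- !is.null(w$post)
    threshold <- NULL
    g_pre <- g_post <- NULL
    dyn <- NULL
    plast <- NULL
    if (length(active) >= 2) {
      threshold <- if (!is.null(params$edge_threshold)) params$edge_threshold
        else surrogate_threshold(rec, w$pre, params, active)
    }
    g_pre <- build_graph(rec, w$pre, params, active = active,
                         threshold = threshold)
    if (have_post) {
      g_post <- build_graph(rec, w$post, params, active = active,
                            threshold = threshold)
      dyn <- suppressWarnings(
        binned_dynamics(rec, params, active = active))
      plast <- classify_plasticity(rec, params, active = active)
    }
    ps <- summarize_plasticity(plast)
    nsc <- NA_real_
    if (have_post && nrow(dyn)) {
      pre_ns <- mean(dyn$network_size[dyn$phase == "pre"])
      post_ns <- mean(dyn$network_size[dyn$phase == "post"])
      nsc <- if (is.finite(pre_ns) && pre_ns > 0)
        suppressWarnings(relative_change(pre_ns, post_ns)) else NA_real_
    }
    all_feats <- list(
      mfr_pre_hz = mfr,
      mean_amplitude_pre_uV = amp$two_step_mean_uV,
      n_active_electrodes = length(active),
      scb_per_min = br$scb_per_min,
      mean_burst_duration_s = br$mean_burst_duration_s,
      mean_spikes_per_burst = br$mean_spikes_per_burst,
      nb_per_min = br$nb_per_min,
      mean_nb_size = br$mean_nb_size,
      network_size_pre = g_pre$network_size,
      density_pre = g_pre$density,
      clustering_pre = g_pre$clustering,
      network_size_post = if (have_post) g_post$network_size else NA_real_,
      density_post = if (have_post) g_post$density else NA_real_,
      clustering_post = if (have_post) g_post$clustering else NA_real_,
      f_stp = ps$f_stp,
      f_std = ps$f_std,
      stp_std_ratio = ps$signed_ratio,
      network_size_change_pct = nsc)
    meta <- data.frame(organoid_id = rec$organoid_id,
                       patient_id = rec$patient_id,
                       group_label = rec$group_label,
                       session_index = rec$session_index)
    cbind(meta, as.data.frame(all_feats[features]))
  })
}

#' Feature table of a cohort
#'
#' @param cohort an `mea_cohort` (or list of recordings / simulation entries).
#' @param params an [mea_params()].
#' @param features feature registry, as in [extract_features()].
#' @param seed optional seed; each recording's surrogate calibration uses a
#'   sub-seed drawn deterministically from it.
#' @return Data frame, one row per recording.
#' @export
extract_feature_table <- function(cohort, params = mea_params(),
                                  features = mea_features(), seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", length(cohort))
    else local_seed(seed, as.list(sample.int(.Machine$integer.max,
                                             length(cohort))))
  rows <- mapply(function(entry, s)
    extract_features(entry, params, features, seed = s),
    cohort, seeds, SIMPLIFY = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' PCA embedding of the feature table
#'
#' Standardizes each feature to zero mean and unit variance, then projects the
#' rows onto the first `n_components` principal components. Missing values are
#' median-imputed (rows with more than `max_missing` missing features are
#' dropped); constant features are dropped with a warning. Component signs are
#' fixed by convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param feature_table data frame from [extract_feature_table()] (metadata
#'   columns are carried through) or a bare numeric matrix/data frame.
#' @param n_components number of components (default 3).
#' @param max_missing maximum fraction of missing features per row before the
#'   row is dropped.
#' @return Object of class `mea_pca`: `scores` (n x k matrix), `loadings`
#'   (p x k), `center`, `scale`, `explained` (variance ratios of the kept
#'   components), `explained_all`, `meta` (metadata of retained rows),
#'   `dropped_rows`, `dropped_features`.
#' @export
embed_pca <- function(feature_table, n_components = 3, max_missing = 0.3) {
  meta_cols <- intersect(c("organoid_id", "patient_id", "group_label",
                           "session_index"), names(feature_table))
  X <- feature_table[, setdiff(names(feature_table), meta_cols), drop = FALSE]
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  miss_frac <- rowMeans(is.na(X))
  drop_rows <- which(miss_frac > max_missing)
  if (length(drop_rows)) X <- X[-drop_rows, , drop = FALSE]
  if (nrow(X) < 4)
    stop("need at least 4 rows with sufficient data for a PCA embedding",
         call. = FALSE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
  }
  const <- apply(X, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  dropped_feats <- colnames(X)[const]
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(dropped_feats, collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  ev_all <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  meta <- if (length(meta_cols)) {
    m <- feature_table[, meta_cols, drop = FALSE]
    if (length(drop_rows)) m <- m[-drop_rows, , drop = FALSE]
    m
  } else NULL
  structure(list(scores = scores, loadings = loadings,
                 center = pc$center, scale = pc$scale,
                 explained = ev_all[seq_len(k)], explained_all = ev_all,
                 meta = meta, dropped_rows = drop_rows,
                 dropped_features = dropped_feats),
            class = "mea_pca")
}

#' @export
print.mea_pca <- function(x, ...) {
  cat(sprintf("PCA embedding: %d row(s) x %d component(s)\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Per-patient aggregation of embedding scores
#'
#' Mean and standard error of the mean (SEM = sd / sqrt(n)) of the component
#' scores over each patient's organoids. A single-organoid patient has an
#' undefined (`NA`) SEM.
#'
#' @param embedding an `mea_pca` (its `meta` must carry `patient_id`), or a
#'   score matrix combined with `patient_id`.
#' @param patient_id optional vector of patient labels overriding the
#'   embedding metadata.
#' @return Data frame: `patient_id`, `group_label` (if known), `n`, then
#'   `mean_PCk` / `sem_PCk` per component.
#' @export
aggregate_patients <- function(embedding, patient_id = NULL) {
  if (inherits(embedding, "mea_pca")) {
    scores <- embedding$scores
    if (is.null(patient_id)) patient_id <- embedding$meta$patient_id
    groups <- embedding$meta$group_label
  } else {
    scores <- as.matrix(embedding)
    groups <- NULL
  }
  if (is.null(patient_id))
    stop("patient_id is required", call. = FALSE)
  k <- ncol(scores)
  rows <- lapply(split(seq_len(nrow(scores)), patient_id), function(idx) {
    s <- scores[idx, , drop = FALSE]
    out <- data.frame(patient_id = patient_id[idx[1]],
                      n = length(idx))
    if (!is.null(groups)) out$group_label <- groups[idx[1]]
    for (j in seq_len(k)) {
      out[[paste0("mean_PC", j)]] <- mean(s[, j])
      out[[paste0("sem_PC", j)]] <- if (length(idx) > 1)
        stats::sd(s[, j]) / sqrt(length(idx)) else NA_real_
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' PERMANOVA on embedding scores
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' between score rows: pseudo-F from the between/within sum-of-squares
#' partition of the distance matrix, with p-value
#' `(1 + #(permuted F >= observed)) / (1 + n_permutations)`. Labels are
#' permuted freely at the row (organoid) level by default; `strata` restricts
#' permutations to within-stratum swaps (e.g. within patients).
#'
#' @param scores numeric matrix (rows = organoids, e.g. PC1-PC3 scores).
#' @param groups group label per row (>= 2 groups, each with >= 2 rows).
#' @param n_permutations number of permutations (default 999).
#' @param strata optional factor restricting permutations.
#' @param seed optional seed for the permutation stream.
#' @return List of class `permanova`: `statistic` (pseudo-F), `p_value`, `df`,
#'   `ss_between`, `ss_within`, `n_permutations`.
#' @export
permanova <- function(scores, groups, n_permutations = 999, strata = NULL,
                      seed = NULL) {
  scores <- as.matrix(scores)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- table(droplevels(groups))
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  d2 <- as.matrix(stats::dist(scores))^2
  f_obs <- permanova_f(d2, groups)
  local_seed(seed, {
    n <- length(groups)
    count <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- permute_labels(n, strata)
      if (permanova_f(d2, groups[perm]) >= f_obs) count <- count + 1L
    }
    structure(list(statistic = f_obs,
                   p_value = (1 + count) / (1 + n_permutations),
                   df = c(between = nlevels(droplevels(groups)) - 1L,
                          within = n - nlevels(droplevels(groups))),
                   n_permutations = n_permutations),
              class = "permanova")
  })
}

# pseudo-F from a squared Euclidean distance matrix and group labels
permanova_f <- function(d2, groups) {
  groups <- droplevels(as.factor(groups))
  n <- nrow(d2)
  k <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      dg <- d2[idx, idx]
      ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

permute_labels <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (s in split(seq_len(n), strata)) perm[s] <- s[sample.int(length(s))]
  perm
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), p = %.4g (%d permutations)\n",
              x$statistic, x$df[1], x$df[2], x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with Holm adjustment
#'
#' Runs [permanova()] on every pair of groups and Holm-adjusts the p-values.
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `statistic`, `p_raw`, `p_adj`.
#' @export
pairwise_permanova <- function(scores, groups, n_permutations = 999,
                               strata = NULL, seed = NULL) {
  groups <- as.factor(groups)
  levs <- levels(droplevels(groups))
  combs <- utils::combn(levs, 2, simplify = FALSE)
  seeds <- local_seed(seed,
                      as.list(sample.int(.Machine$integer.max, length(combs))))
  if (is.null(seed)) seeds <- vector("list", length(combs))
  rows <- mapply(function(pair, s) {
    idx <- groups %in% pair
    res <- permanova(as.matrix(scores)[idx, , drop = FALSE],
                     droplevels(groups[idx]), n_permutations,
                     strata = if (is.null(strata)) NULL else strata[idx],
                     seed = s)
    data.frame(group1 = pair[1], group2 = pair[2],
               statistic = res$statistic, p_raw = res$p_value)
  }, combs, seeds, SIMPLIFY = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- pairwise_holm(out$p_raw)
  out
}

#' Holm step-down adjustment
#'
#' Step-down multiple-testing correction: sort the m p-values ascending,
#' multiply the k-th smallest by (m - k + 1), enforce monotonicity, cap at 1.
#' Dominates the raw p-values and never exceeds Bonferroni.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' pairwise_holm(c(0.01, 0.03, 0.04))  # 0.03 0.06 0.06
#' @export
pairwise_holm <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis H (with tie correction) across groups of (typically
#' per-patient) values, followed by Dunn's pairwise z tests on mean ranks with
#' a multiplicity adjustment (Holm by default; the method is recorded in the
#' output). All-identical values yield the H = 0, p = 1 convention, flagged.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups).
#' @param adjust adjustment method for the pairwise p-values (a
#'   [stats::p.adjust()] method).
#' @return List of class `kruskal_dunn`: `statistic` (H), `df`, `p_value`,
#'   `pairwise` (data frame `group1`, `group2`, `z`, `p_raw`, `p_adj`),
#'   `adjust`, `degenerate`.
#' @export
kruskal_dunn <- function(values, groups, adjust = "holm") {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(structure(list(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, pairwise = NULL, adjust = adjust,
                          degenerate = TRUE),
                     class = "kruskal_dunn"))
  }
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  levs <- levels(groups)
  combs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(combs, function(pair) {
    i1 <- groups == pair[1]; i2 <- groups == pair[2]
    n1 <- sum(i1); n2 <- sum(i2)
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
    z <- (mean(r[i1]) - mean(r[i2])) / se
    data.frame(group1 = pair[1], group2 = pair[2], z = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  })
  pw <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = adjust)
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pw, adjust = adjust,
                 degenerate = FALSE),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f (df %d), p = %.4g%s\n", x$statistic,
              x$df, x$p_value, if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$pairwise)) {
    cat(sprintf("Dunn pairwise comparisons (%s-adjusted):\n", x$adjust))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Per-bin Fisher's exact comparison of connected-node counts
#'
#' For each time bin, compares a group against the control with a two-sided
#' Fisher's exact test on the 2x2 table of (connected, unconnected) node
#' counts pooled over each group's organoids. An empty margin gives p = 1
#' (flagged).
#'
#' @param group_connected,group_unconnected integer vectors, one entry per
#'   bin: pooled counts of connected (degree >= 1) and unconnected nodes in
#'   the comparison group.
#' @param control_connected,control_unconnected same for the control group.
#' @return Data frame: `bin`, `p_value`, `degenerate`.
#' @export
per_bin_fisher <- function(group_connected, group_unconnected,
                           control_connected, control_unconnected) {
  n <- length(group_connected)
  if (!all(lengths(list(group_unconnected, control_connected,
                        control_unconnected)) == n))
    stop("all count vectors must have the same length", call. = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    tab <- matrix(c(group_connected[i], group_unconnected[i],
                    control_connected[i], control_unconnected[i]), nrow = 2)
    degen <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    p <- if (degen) 1 else stats::fisher.test(tab)$p.value
    data.frame(bin = i, p_value = p, degenerate = degen)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Radar table: group feature means normalized to control
#'
#' Each group's feature mean divided by the control group's feature mean, so
#' the control row is exactly 1 for every feature. Features whose control mean
#' is 0 (or missing) are flagged and omitted.
#'
#' @param feature_table data frame from [extract_feature_table()].
#' @param control_label label of the control group.
#' @return Data frame of normalized feature means, one row per group, with an
#'   attribute `omitted` naming any flagged features.
#' @export
radar_table <- function(feature_table, control_label = "Control") {
  if (!control_label %in% feature_table$group_label)
    stop("control group '", control_label, "' not present", call. = FALSE)
  meta_cols <- intersect(c("organoid_id", "patient_id", "group_label",
                           "session_index"), names(feature_table))
  feats <- setdiff(names(feature_table), meta_cols)
  means <- lapply(split(feature_table[, feats, drop = FALSE],
                        feature_table$group_label),
                  function(d) colMeans(as.matrix(d), na.rm = TRUE))
  M <- do.call(rbind, means)
  ctrl <- M[control_label, ]
  bad <- !is.finite(ctrl) | ctrl == 0
  if (any(bad))
    warning("feature(s) omitted from radar (control mean 0 or missing): ",
            paste(colnames(M)[bad], collapse = ", "), call. = FALSE)
  out <- sweep(M[, !bad, drop = FALSE], 2, ctrl[!bad], "/")
  out <- data.frame(group_label = rownames(out), out, row.names = NULL,
                    check.names = FALSE)
  attr(out, "omitted") <- colnames(M)[bad]
  out
}
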