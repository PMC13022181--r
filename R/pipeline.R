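#' Full analysis of one recording
#'
#' Convenience wrapper running every stage on one recording: per-electrode
#' metrics, two-step mean firing rate and amplitude summary, single-channel
#' and network bursts, plasticity classification, pre/post connectivity graphs
#' with a shared surrogate-calibrated threshold, binned dynamics, and the
#' feature vector.
#'
#' @param recording an [mea_recording()].
#' @param params an [mea_params()].
#' @param seed optional seed for the surrogate calibration.
#' @return Object of class `mea_analysis` with components `windows`, `active`,
#'   `metrics_pre`, `mfr_pre_hz`, `amplitude`, `bursts`, `plasticity`,
#'   `plasticity_summary`, `graph_pre`, `graph_post`, `dynamics`, `features`.
#' @export
analyze_recording <- function(recording, params = mea_params(), seed = NULL) {
  local_seed(seed, {
    w <- analysis_windows(recording, params)
    active <- active_electrodes(recording, w$pre, params)
    threshold <- if (!is.null(params$edge_threshold)) params$edge_threshold
      else if (length(active) >= 2)
        surrogate_threshold(recording, w$pre, params, active) else NA_real_
    have_post <- !is.null(w$post)
    plast <- if (have_post) classify_plasticity(recording, params, active)
             else NULL
    out <- list(
      windows = w,
      active = active,
      metrics_pre = electrode_metrics(recording, w$pre, params),
      mfr_pre_hz = mean_firing_rate(recording, w$pre, params, active),
      amplitude = amplitude_stats(recording, w$pre, params, active),
      bursts = burst_rates(recording, w$pre, params, active),
      plasticity = plast,
      plasticity_summary = summarize_plasticity(plast),
      graph_pre = build_graph(recording, w$pre, params, active,
                              threshold = threshold),
      graph_post = if (have_post)
        build_graph(recording, w$post, params, active, threshold = threshold)
        else NULL,
      dynamics = if (have_post) suppressWarnings(
        binned_dynamics(recording, params, active))
        else NULL,
      features = extract_features(recording, params))
    class(out) <- "mea_analysis"
    out
  })
}

#' @export
print.mea_analysis <- function(x, ...) {
  cat("MEA recording analysis\n")
  cat(sprintf("  active electrodes: %d\n", length(x$active)))
  cat(sprintf("  mean firing rate (pre): %s Hz\n",
              format(round(x$mfr_pre_hz, 3))))
  cat(sprintf("  SCB rate: %s /min; network bursts: %d\n",
              format(round(x$bursts$scb_per_min, 3)), x$bursts$n_nb))
  if (!is.null(x$plasticity))
    cat(sprintf("  plasticity: %.0f%% STD, %.0f%% STP, %.0f%% unchanged\n",
                100 * x$plasticity_summary$f_std,
                100 * x$plasticity_summary$f_stp,
                100 * x$plasticity_summary$f_none))
  cat(sprintf("  pre graph: size %d, density %.3f, clustering %.3f\n",
              x$graph_pre$network_size, x$graph_pre$density,
              x$graph_pre$clustering))
  invisible(x)
}

#' Multivariate phenotype of a cohort
#'
#' The central entry point: extracts the 18-feature phenotype of every
#' recording in a cohort, embeds the feature table into 3 principal
#' components, aggregates scores per patient (mean +/- SEM), and tests the
#' group effect in PCA space with PERMANOVA plus Holm-adjusted pairwise
#' comparisons. Returns a classed object with `print`, `summary` and `plot`
#' methods.
#'
#' @param cohort an `mea_cohort` from [simulate_cohort()], or a list of
#'   [mea_recording()] objects.
#' @param params an [mea_params()].
#' @param n_components embedding dimensionality (default 3).
#' @param control_label control group label used for the radar normalization.
#' @param seed optional seed driving surrogate calibration and permutations.
#' @return Object of class `mea_phenotype`: `features` (table), `pca`,
#'   `patients` (per-patient mean/SEM scores), `permanova`, `pairwise`,
#'   `radar` (or `NULL` without a control group), `params`.
#' @export
mea_phenotype <- function(cohort, params = mea_params(), n_components = 3,
                          control_label = "Control", seed = NULL) {
  seeds <- local_seed(seed, as.list(sample.int(.Machine$integer.max, 2)))
  if (is.null(seed)) seeds <- list(NULL, NULL)
  features <- extract_feature_table(cohort, params, seed = seeds[[1]])
  pca <- embed_pca(features, n_components = n_components)
  patients <- aggregate_patients(pca)
  groups <- pca$meta$group_label
  perm <- permanova(pca$scores, groups,
                    n_permutations = params$n_permutations,
                    seed = seeds[[2]])
  pairwise <- if (length(unique(groups)) > 2)
    pairwise_permanova(pca$scores, groups,
                       n_permutations = params$n_permutations,
                       seed = seeds[[2]]) else NULL
  radar <- if (control_label %in% features$group_label)
    suppressWarnings(radar_table(features, control_label)) else NULL
  structure(list(features = features, pca = pca, patients = patients,
                 permanova = perm, pairwise = pairwise, radar = radar,
                 control_label = control_label, params = params),
            class = "mea_phenotype")
}

#' @export
print.mea_phenotype <- function(x, ...) {
  cat(sprintf("MEA phenotype: %d recording(s), %d group(s)\n",
              nrow(x$features), length(unique(x$features$group_label))))
  cat("  explained variance (PC1..):",
      paste(sprintf("%.3f", x$pca$explained), collapse = ", "), "\n  ")
  print(x$permanova)
  invisible(x)
}

#' @export
summary.mea_phenotype <- function(object, ...) {
  cat("Feature table (", nrow(object$features), " recordings x ",
      ncol(object$features) - 4, " features)\n\n", sep = "")
  cat("Per-patient embedding (mean +/- SEM):\n")
  print(object$patients, row.names = FALSE, digits = 3)
  cat("\n")
  print(object$permanova)
  if (!is.null(object$pairwise)) {
    cat("Holm-adjusted pairwise PERMANOVA:\n")
    print(object$pairwise, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Plot a cohort phenotype
#'
#' `which = "scores"` draws the per-patient means with SEM bars on two
#' principal components; `which = "radar"` draws the control-normalized group
#' feature profiles as a line chart over the features.
#'
#' @param x an `mea_phenotype`.
#' @param which `"scores"` or `"radar"`.
#' @param components which two components to show.
#' @param ... further graphical arguments (unused).
#' @return `x`, invisibly.
#' @export
plot.mea_phenotype <- function(x, which = c("scores", "radar"),
                               components = c(1, 2), ...) {
  which <- match.arg(which)
  if (which == "scores") {
    pats <- x$patients
    cx <- paste0("mean_PC", components[1])
    cy <- paste0("mean_PC", components[2])
    sx <- paste0("sem_PC", components[1])
    sy <- paste0("sem_PC", components[2])
    grp <- as.factor(pats$group_label)
    cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")[as.integer(grp)]
    xr <- range(pats[[cx]] - pmax(pats[[sx]], 0, na.rm = TRUE),
                pats[[cx]] + pmax(pats[[sx]], 0, na.rm = TRUE), na.rm = TRUE)
    yr <- range(pats[[cy]] - pmax(pats[[sy]], 0, na.rm = TRUE),
                pats[[cy]] + pmax(pats[[sy]], 0, na.rm = TRUE), na.rm = TRUE)
    graphics::plot(pats[[cx]], pats[[cy]], col = cols, pch = 19,
                   xlim = xr, ylim = yr,
                   xlab = sprintf("PC%d (%.0f%%)", components[1],
                                  100 * x$pca$explained[components[1]]),
                   ylab = sprintf("PC%d (%.0f%%)", components[2],
                                  100 * x$pca$explained[components[2]]))
    graphics::arrows(pats[[cx]] - pats[[sx]], pats[[cy]],
                     pats[[cx]] + pats[[sx]], pats[[cy]],
                     angle = 90, code = 3, length = 0.03, col = cols)
    graphics::arrows(pats[[cx]], pats[[cy]] - pats[[sy]],
                     pats[[cx]], pats[[cy]] + pats[[sy]],
                     angle = 90, code = 3, length = 0.03, col = cols)
    graphics::legend("topright", legend = levels(grp), col =
                       grDevices::hcl.colors(nlevels(grp), "Dark 3"),
                     pch = 19, bty = "n", cex = 0.8)
  } else {
    if (is.null(x$radar)) stop("no radar table (control group absent)",
                               call. = FALSE)
    R <- x$radar
    feats <- setdiff(names(R), "group_label")
    M <- as.matrix(R[, feats])
    grp <- as.factor(R$group_label)
    cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
    graphics::matplot(t(M), type = "l", lty = 1, col = cols[as.integer(grp)],
                      xaxt = "n", xlab = "", ylab = "relative to control")
    graphics::abline(h = 1, col = "grey", lty = 2)
    graphics::axis(1, at = seq_along(feats), labels = feats, las = 2,
                   cex.axis = 0.6)
    graphics::legend("topleft", legend = levels(grp), col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' @useDynLib meapheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
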