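test_that("every recording yields the 18-feature phenotype", {
  expect_length(mea_features(), 18)
  prof <- group_profile(n_electrodes = 8, base_rate_hz = 2)
  sim <- simulate_recording(prof, seed = 91)
  f <- extract_features(sim$recording, seed = 92)
  expect_equal(ncol(f) - 4, 18)
  expect_named(f, c("organoid_id", "patient_id", "group_label",
                    "session_index", mea_features()))
  expect_error(extract_features(sim$recording, features = "not_a_feature"),
               "unknown feature")
})

test_that("a silent recording flags its features as missing, never zero", {
  rec <- mea_recording(list(spike_train(1, numeric(0))), 660,
                       stim_epochs = rbind(c(300, 360)))
  f <- extract_features(rec)
  expect_true(is.na(f$mfr_pre_hz))
  expect_true(is.na(f$scb_per_min))
  expect_equal(f$n_active_electrodes, 0)
  expect_true(is.na(f$f_std))
  expect_true(is.na(f$stp_std_ratio))
})

test_that("rate and burst features recover generator ground truth", {
  prof <- group_profile(n_electrodes = 10, base_rate_hz = 3,
                        rate_dispersion = 0, burst_rate_per_min = 2,
                        nb_rate_per_min = 1, coupling_strength = 0,
                        p_std = 0, p_stp = 0, p_none = 1)
  sim <- simulate_recording(prof, seed = 95)
  f <- extract_features(sim, seed = 96)
  burst_extra <- 2 * mean(pmax(sim$truth$bursts$n_spikes, 5)) / 60
  expect_lt(abs(f$mfr_pre_hz - (3 + burst_extra)) / (3 + burst_extra), 0.12)
  n_true_scb <- sum(sim$truth$bursts$start_s < 300)
  expect_lt(abs(f$scb_per_min - n_true_scb / 10 / 5) /
              (n_true_scb / 10 / 5), 0.15)
  n_true_nb <- sum(sim$truth$network_bursts$onset_s < 300)
  expect_equal(f$nb_per_min, n_true_nb / 5)
})

test_that("PCA embedding matches an independent eigen decomposition", {
  set.seed(101)
  X <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  emb <- embed_pca(as.data.frame(X), n_components = 3)
  ora <- oracle_pca_scores(X, 3)
  for (j in 1:3) {
    agree <- max(abs(emb$scores[, j] - ora$scores[, j]))
    flip <- max(abs(emb$scores[, j] + ora$scores[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
  expect_equal(emb$explained_all,
               ora$values / sum(ora$values), tolerance = 1e-10)
  # sign convention: largest-|loading| entry positive
  for (j in 1:3)
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
})

test_that("planar data yield explained variance (v1, v2, 0)", {
  set.seed(103)
  B <- matrix(rnorm(10 * 2), 10, 2)
  X <- B %*% matrix(rnorm(2 * 5), 2, 5)  # rank 2 in 5 dims
  emb <- embed_pca(as.data.frame(X), n_components = 3)
  expect_equal(sum(emb$explained[1:2]), 1, tolerance = 1e-8)
  expect_lt(emb$explained[3], 1e-8)
  expect_equal(ncol(emb$scores), 3)
})

test_that("embedding handles duplicates, constants, and missing data", {
  set.seed(107)
  X <- as.data.frame(matrix(rnorm(8 * 4), 8, 4))
  X2 <- rbind(X, X)
  emb <- embed_pca(X2, n_components = 2)
  expect_equal(emb$scores[1:8, ], emb$scores[9:16, ], ignore_attr = TRUE)

  Xc <- cbind(X, const = 1)
  expect_warning(embc <- embed_pca(Xc, n_components = 2), "constant")
  expect_equal(embc$dropped_features, "const")
  expect_equal(ncol(embc$loadings), 2)

  Xm <- X
  Xm[1, 1] <- NA           # light missingness: imputed
  Xm[2, ] <- NA            # heavy missingness: row dropped
  emb_m <- embed_pca(Xm, n_components = 2)
  expect_equal(emb_m$dropped_rows, 2L)
  expect_equal(nrow(emb_m$scores), 7)
  expect_error(embed_pca(X[1:3, ]), "at least 4 rows")
})

test_that("per-patient aggregation gives mean and SEM of scores", {
  scores <- matrix(c(1, 3, 5, 5, 2), ncol = 1)
  agg <- aggregate_patients(scores, patient_id = c("a", "a", "b", "b", "c"))
  expect_equal(agg$mean_PC1[agg$patient_id == "a"], 2)
  expect_equal(agg$sem_PC1[agg$patient_id == "a"], 1)
  expect_equal(agg$sem_PC1[agg$patient_id == "b"], 0)
  expect_true(is.na(agg$sem_PC1[agg$patient_id == "c"]))
})

test_that("PERMANOVA separates distinct groups and not duplicated ones", {
  set.seed(113)
  # two groups 10 within-group sds apart: decisive rejection
  a <- matrix(rnorm(10 * 3), 10, 3)
  b <- matrix(rnorm(10 * 3, mean = 10), 10, 3)
  res <- permanova(rbind(a, b), rep(c("A", "B"), each = 10),
                   n_permutations = 999, seed = 5)
  expect_lte(res$p_value, 0.01)

  # identical duplicate groups: F near the null, p large
  res0 <- permanova(rbind(a, a), rep(c("A", "B"), each = 10),
                    n_permutations = 199, seed = 6)
  expect_gt(res0$p_value, 0.5)

  expect_error(permanova(rbind(a, b[1, , drop = FALSE]),
                         c(rep("A", 10), "B"), 99), "size 1")
})

test_that("PERMANOVA pseudo-F agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(115)
  X <- matrix(rnorm(24 * 3), 24, 3)
  g <- rep(c("A", "B", "C"), each = 8)
  f_ours <- meapheno:::permanova_f(as.matrix(dist(X))^2, g)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 19)
  expect_equal(f_ours, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to rotations of the score matrix", {
  set.seed(117)
  X <- matrix(rnorm(18 * 3), 18, 3)
  g <- rep(c("A", "B", "C"), each = 6)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random orthogonal matrix
  f1 <- meapheno:::permanova_f(as.matrix(dist(X))^2, g)
  f2 <- meapheno:::permanova_f(as.matrix(dist(X %*% Q))^2, g)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("Holm adjustment follows the step-down formula and its bounds", {
  expect_equal(pairwise_holm(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(pairwise_holm(0.2), 0.2)
  expect_equal(pairwise_holm(rep(1, 4)), rep(1, 4))
  expect_error(pairwise_holm(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(119)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    h <- pairwise_holm(p)
    expect_true(all(h >= p))                       # dominates raw
    expect_true(all(h <= pmin(1, length(p) * p)))  # never above Bonferroni
  }
})

test_that("Kruskal-Wallis + Dunn matches hand rank computations", {
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn(vals, grp)
  expect_equal(res$statistic, oracle_kw_h(vals, grp), tolerance = 1e-10)
  expect_equal(res$statistic,
               unname(kruskal.test(vals, factor(grp))$statistic))
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  # extreme separation: a vs c has the largest |z|
  expect_equal(which.max(abs(res$pairwise$z)),
               which(res$pairwise$group1 == "a" & res$pairwise$group2 == "c"))

  res0 <- kruskal_dunn(rep(7, 6), rep(c("a", "b"), 3))
  expect_true(res0$degenerate)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("per-bin Fisher tests match fisher.test and handle degeneracy", {
  res <- per_bin_fisher(c(10, 5, 0), c(0, 5, 0), c(0, 5, 3), c(10, 5, 2))
  expect_equal(res$p_value[1], fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value)
  expect_equal(res$p_value[2], 1)   # perfectly homogeneous
  expect_true(res$degenerate[3])    # empty margin -> p = 1, flagged
  expect_equal(res$p_value[3], 1)
  # row swap leaves p unchanged
  a <- per_bin_fisher(7, 3, 2, 8)$p_value
  b <- per_bin_fisher(3, 7, 8, 2)$p_value
  expect_equal(a, b)
})

test_that("radar table normalizes group means to the control", {
  ft <- data.frame(organoid_id = letters[1:6],
                   patient_id = rep(c("p1", "p2"), 3),
                   group_label = rep(c("Control", "Hypo"), each = 3),
                   session_index = 1,
                   mfr = c(4, 4, 4, 1, 1, 1),
                   amp = c(10, 20, 30, 40, 40, 40),
                   zero_feat = c(0, 0, 0, 1, 1, 1))
  expect_warning(r <- radar_table(ft, "Control"), "omitted")
  expect_equal(attr(r, "omitted"), "zero_feat")
  ctrl <- r[r$group_label == "Control", ]
  expect_true(all(abs(as.numeric(ctrl[, -1]) - 1) < 1e-12))
  expect_equal(r$mfr[r$group_label == "Hypo"], 0.25)
  expect_equal(r$amp[r$group_label == "Hypo"], 2)
  expect_error(radar_table(ft, "Nope"), "not present")
})

test_that("the cohort phenotype pipeline is deterministic end to end", {
  profs <- list(group_profile("Control", n_electrodes = 6, base_rate_hz = 3),
                group_profile("Hypo", n_electrodes = 6, base_rate_hz = 1))
  coh <- simulate_cohort(profs, patients_per_group = 2,
                         organoids_per_patient = 2, sessions = 1,
                         pre_s = 120, post_s = 120, seed = 21)
  p <- mea_params(n_permutations = 99)
  ph1 <- suppressWarnings(mea_phenotype(coh, p, seed = 31))
  ph2 <- suppressWarnings(mea_phenotype(coh, p, seed = 31))
  expect_identical(ph1$features, ph2$features)
  expect_identical(ph1$permanova$p_value, ph2$permanova$p_value)
  expect_s3_class(ph1, "mea_phenotype")
  expect_equal(ncol(ph1$pca$scores), 3)
  # patient aggregation covers every patient
  expect_setequal(ph1$patients$patient_id, unique(ph1$features$patient_id))
})
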