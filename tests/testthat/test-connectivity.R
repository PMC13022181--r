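test_that("a shifted train puts all correlogram mass near the shift", {
  ti <- seq(1, 996, by = 5)  # spikes 5 s apart: only the shift delay counts
  cg <- cross_correlogram(ti, ti + 0.0125)  # mid-bin shift
  k <- findInterval(0.0125, cg$lag_edges_s)
  expect_equal(cg$counts[k], length(ti))
  expect_equal(sum(cg$counts[-k]), 0)
  expect_equal(cg$normalized[k], 1)
})

test_that("correlogram equals the brute-force delay enumeration oracle", {
  set.seed(25)
  p <- mea_params()
  for (i in 1:25) {
    ti <- random_train(sample(5:120, 1), dur = 5)
    tj <- random_train(sample(5:120, 1), dur = 5)
    got <- cross_correlogram(ti, tj, p)
    want <- oracle_correlogram(ti, tj, p$xcorr_max_lag_s, p$xcorr_bin_s)
    expect_equal(got$counts, want)
    expect_equal(got$normalized,
                 want / sqrt(length(ti) * length(tj)))
  }
})

test_that("empty trains give a flagged all-zero correlogram", {
  cg <- cross_correlogram(numeric(0), c(1, 2, 3))
  expect_true(cg$empty)
  expect_true(all(cg$normalized == 0))
  expect_length(cg$counts, 100)
})

test_that("independent Poisson pairs give a flat correlogram", {
  set.seed(55)
  ti <- sort(runif(300, 0, 300))
  tj <- sort(runif(300, 0, 300))
  cg <- cross_correlogram(ti, tj)
  lam <- 300 * 300 * 0.005 / 300  # expected coincidences per 5-ms bin
  expect_true(all(abs(cg$counts - lam) < 4 * sqrt(lam) + 1))
})

test_that("graph construction reproduces closed-form metrics", {
  p <- mea_params(edge_threshold = 0.5)
  # complete graph on 5 nodes: density 1, clustering 1
  W <- matrix(1, 5, 5); diag(W) <- 0
  g <- meapheno:::graph_from_weights(W, 0.5, 1:5)
  expect_equal(g$network_size, 5)
  expect_equal(g$density, 1)
  expect_equal(g$clustering, 1)

  # 4-cycle: density 4/6, clustering 0
  W4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W4[e[1], e[2]] <- W4[e[2], e[1]] <- 1
  g4 <- meapheno:::graph_from_weights(W4, 0.5, 1:4)
  expect_equal(g4$network_size, 4)
  expect_equal(g4$density, 4 / 6)
  expect_equal(g4$clustering, 0)

  # threshold above all weights: empty graph
  g0 <- meapheno:::graph_from_weights(W4, 2, 1:4)
  expect_equal(g0$network_size, 0)
  expect_equal(g0$density, 0)
  expect_equal(g0$clustering, 0)
})

test_that("graph metrics are invariant under node relabeling", {
  set.seed(61)
  prof <- group_profile(n_electrodes = 8, base_rate_hz = 3,
                        rate_dispersion = 0, coupling_strength = 0.4)
  sim <- simulate_recording(prof, protocol = NULL, pre_s = 120, post_s = 0,
                            seed = 62)
  rec <- sim$recording
  g1 <- build_graph(rec, c(0, 120), mea_params(edge_threshold = 0.05))
  # relabel electrodes by a permutation
  perm <- sample(8)
  trains2 <- lapply(seq_along(rec$trains), function(i)
    spike_train(perm[i], rec$trains[[i]]$spike_times,
                rec$trains[[i]]$amplitudes))
  rec2 <- mea_recording(trains2, rec$duration_s)
  g2 <- build_graph(rec2, c(0, 120), mea_params(edge_threshold = 0.05))
  expect_equal(g1$network_size, g2$network_size)
  expect_equal(g1$density, g2$density)
  expect_equal(g1$clustering, g2$clustering)
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(63)
  prof <- group_profile(n_electrodes = 8, base_rate_hz = 3,
                        coupling_strength = 0.3)
  sim <- simulate_recording(prof, protocol = NULL, pre_s = 120, post_s = 0,
                            seed = 64)
  thresholds <- seq(0.01, 0.4, length.out = 8)
  edges <- vapply(thresholds, function(thr)
    nrow(build_graph(sim$recording, c(0, 120), threshold = thr)$edges),
    numeric(1))
  expect_true(all(diff(edges) <= 0))
})

test_that("fewer than two active electrodes give a flagged degenerate graph", {
  rec <- make_recording(list(c(10, 20)), 300)
  g <- build_graph(rec, c(0, 300))
  expect_true(g$degenerate)
  expect_equal(g$network_size, 0)
  expect_equal(g$density, 0)
})

test_that("binned dynamics cover 60 s on each side in 30-s bins", {
  prof <- group_profile(n_electrodes = 6, base_rate_hz = 3,
                        coupling_strength = 0.4)
  sim <- simulate_recording(prof, seed = 77)
  dyn <- binned_dynamics(sim$recording, mea_params(edge_threshold = 0.05))
  expect_equal(nrow(dyn), 4)
  expect_equal(dyn$phase, c("pre", "pre", "post", "post"))
  expect_equal(dyn$bin_end_s - dyn$bin_start_s, rep(30, 4))
  # pre bins end at stimulation onset; post bins start after the last epoch
  expect_equal(dyn$bin_end_s[2], 300)
  expect_equal(dyn$bin_start_s[3], 360)
})

test_that("a recording shorter than one bin yields an empty series with warning", {
  rec <- make_recording(list(seq(0.5, 24.5, by = 0.5)), 25,
                        stim_epochs = rbind(c(10, 12)))
  p <- mea_params(window_s = 10, edge_threshold = 0.5)
  expect_warning(expect_warning(dyn <- binned_dynamics(rec, p),
                                "shorter|truncated"))
  expect_equal(nrow(dyn), 0)
})

test_that("relative change follows (post-pre)/pre x 100", {
  expect_equal(relative_change(10, 5), -50)
  expect_equal(relative_change(8, 8), 0)
  expect_equal(relative_change(4, 5), 25)
  expect_warning(out <- relative_change(0, 5), "undefined")
  expect_true(is.na(out))
  expect_equal(suppressWarnings(relative_change(c(10, 0), c(5, 1))),
               c(-50, NA))
})

test_that("paired pre/post test matches the textbook formula", {
  pre <- c(10, 12, 11)
  post <- c(8, 9, 8)
  res <- paired_pre_post_test(pre, post)
  expect_equal(res$statistic, oracle_paired_t(pre, post))
  expect_equal(res$p_value,
               2 * pt(-abs(oracle_paired_t(pre, post)), df = 2))
  expect_false(res$degenerate)

  # all-equal pairs: degenerate, statistic 0
  res0 <- paired_pre_post_test(c(5, 6, 7), c(5, 6, 7))
  expect_true(res0$degenerate)
  expect_equal(res0$statistic, 0)
  expect_error(paired_pre_post_test(1, 2), "at least 2")
})

test_that("post-stimulation decoupling shows up in the binned dynamics", {
  set.seed(83)
  hits <- 0
  n_runs <- 8
  prof <- group_profile(n_electrodes = 10, base_rate_hz = 3,
                        rate_dispersion = 0, burst_rate_per_min = 0,
                        nb_rate_per_min = 0, coupling_strength = 0.5,
                        p_std = 0, p_stp = 0, p_none = 1,
                        post_coupling_factor = 0.05)
  for (i in seq_len(n_runs)) {
    sim <- simulate_recording(prof, seed = 100 + i)
    a <- analyze_recording(sim$recording, seed = 200 + i)
    pre_ns <- mean(a$dynamics$network_size[a$dynamics$phase == "pre"])
    post_ns <- mean(a$dynamics$network_size[a$dynamics$phase == "post"])
    hits <- hits + (post_ns < pre_ns)
  }
  expect_gte(hits / n_runs, 0.9)
})
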