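test_that("profile invariants are enforced", {
  expect_error(group_profile(p_std = 0.5, p_stp = 0.1, p_none = 0.1),
               "must equal 1")
  expect_error(group_profile(coupling_strength = 1.5), "\\[0, 1\\]")
  expect_error(group_profile(base_rate_hz = -1), ">= 0")
})

test_that("simulation is deterministic given (profile, seed)", {
  prof <- group_profile(n_electrodes = 6)
  a <- simulate_recording(prof, seed = 9, pre_s = 60, post_s = 60)
  b <- simulate_recording(prof, seed = 9, pre_s = 60, post_s = 60)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth$stim_label, b$truth$stim_label)
  c <- simulate_recording(prof, seed = 10, pre_s = 60, post_s = 60)
  expect_false(identical(a$recording, c$recording))

  dir <- withr::local_tempdir()
  coh1 <- simulate_cohort(list(prof), 1, 1, sessions = 1, pre_s = 30,
                          post_s = 30, seed = 4)
  coh2 <- simulate_cohort(list(prof), 1, 1, sessions = 1, pre_s = 30,
                          post_s = 30, seed = 4)
  write_cohort(coh1, file.path(dir, "a"))
  write_cohort(coh2, file.path(dir, "b"))
  fa <- list.files(file.path(dir, "a"), full.names = TRUE)
  fb <- list.files(file.path(dir, "b"), full.names = TRUE)
  expect_identical(lapply(fa, readLines), lapply(fb, readLines))
})

test_that("pre-window spike counts match the Poisson construction", {
  # 10 electrodes at 1 Hz for 300 s: total pre count ~ Poisson(3000)
  prof <- group_profile(n_electrodes = 10, base_rate_hz = 1,
                        rate_dispersion = 0, burst_rate_per_min = 0,
                        nb_rate_per_min = 0, coupling_strength = 0)
  sim <- simulate_recording(prof, seed = 21)
  total <- sum(vapply(sim$recording$trains, function(tr)
    sum(tr$spike_times < 300), numeric(1)))
  expect_lt(abs(total - 3000), 4 * sqrt(3000))
})

test_that("empirical electrode rates converge to truth over long recordings", {
  prof <- group_profile(n_electrodes = 3, base_rate_hz = 2,
                        rate_dispersion = 0.3, burst_rate_per_min = 0,
                        nb_rate_per_min = 0, coupling_strength = 0)
  sim <- simulate_recording(prof, protocol = NULL, pre_s = 3000, post_s = 0,
                            seed = 33)
  for (e in 1:3) {
    emp <- length(sim$recording$trains[[e]]$spike_times) / 3000
    expect_lt(abs(emp / sim$truth$base_rate_hz[e] - 1), 0.05)
  }
})

test_that("an all-STD stimulation effect halves post/pre rates", {
  prof <- group_profile(n_electrodes = 12, base_rate_hz = 4,
                        rate_dispersion = 0, burst_rate_per_min = 0,
                        nb_rate_per_min = 0, coupling_strength = 0,
                        p_std = 1, p_stp = 0, p_none = 0, std_effect = 0.5)
  sim <- simulate_recording(prof, seed = 13)
  w <- analysis_windows(sim$recording)
  ratios <- vapply(sim$recording$trains, function(tr) {
    pre <- sum(tr$spike_times >= w$pre[1] & tr$spike_times < w$pre[2])
    post <- sum(tr$spike_times >= w$post[1] & tr$spike_times < w$post[2])
    post / pre
  }, numeric(1))
  expect_true(all(sim$truth$stim_label == "STD"))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
  expect_true(all(abs(ratios - 0.5) < 4 * sqrt(0.5 / 1200) * 2))
})

test_that("cohorts have the expected size, ids, and hierarchy", {
  profs <- list(group_profile("A", n_electrodes = 3),
                group_profile("B", n_electrodes = 3))
  coh <- simulate_cohort(profs, patients_per_group = 2,
                         organoids_per_patient = 3, sessions = 2,
                         pre_s = 20, post_s = 20, seed = 8)
  expect_length(coh, 2 * 2 * 3 * 2)
  ids <- vapply(coh, function(e)
    sprintf("%s_S%d", e$recording$organoid_id, e$recording$session_index),
    character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_error(simulate_cohort(list(group_profile("A"), group_profile("A")),
                               seed = 1),
               "duplicate group name")
})

test_that("a fourfold rate difference is recovered by the downstream MFR", {
  ctrl <- group_profile("Control", n_electrodes = 6, base_rate_hz = 2)
  hypo <- group_profile("Hypo", n_electrodes = 6, base_rate_hz = 0.5)
  recovered <- 0L
  for (s in 1:20) {
    sim_c <- simulate_recording(ctrl, protocol = NULL, pre_s = 120,
                                post_s = 0, seed = 700 + s)
    sim_h <- simulate_recording(hypo, protocol = NULL, pre_s = 120,
                                post_s = 0, seed = 800 + s)
    m_c <- mean_firing_rate(sim_c$recording, c(0, 120))
    m_h <- mean_firing_rate(sim_h$recording, c(0, 120))
    recovered <- recovered + (!is.na(m_c) && !is.na(m_h) && m_c > m_h)
  }
  expect_gte(recovered / 20, 0.95)
})

test_that("every injected burst is detectable at default parameters", {
  # constructive guarantee: injected bursts use a 4 ms ISI and >= 5 spikes
  prof <- group_profile(n_electrodes = 5, base_rate_hz = 1,
                        burst_rate_per_min = 3, nb_rate_per_min = 0,
                        coupling_strength = 0)
  sim <- simulate_recording(prof, seed = 17, pre_s = 120, post_s = 120)
  truth <- sim$truth$bursts
  for (k in seq_len(nrow(truth))) {
    tr <- sim$recording$trains[[truth$electrode[k]]]
    det <- detect_scb(tr)
    hit <- any(det$start_s <= truth$end_s[k] & det$end_s >= truth$start_s[k])
    expect_true(hit, label = sprintf("burst %d detected", k))
  }
})

test_that("zero-rate profiles give valid silent recordings", {
  prof <- group_profile(n_electrodes = 4, base_rate_hz = 0,
                        rate_dispersion = 0, burst_rate_per_min = 0,
                        nb_rate_per_min = 0, coupling_strength = 0)
  sim <- simulate_recording(prof, seed = 2, pre_s = 30, post_s = 30)
  expect_s3_class(sim$recording, "mea_recording")
  expect_equal(sum(vapply(sim$recording$trains, function(t)
    length(t$spike_times), integer(1))), 0)
  expect_error(simulate_recording(prof, pre_s = 0), "positive")
})

test_that("coupled pairs share correlated spikes, uncoupled do not", {
  base <- group_profile(n_electrodes = 2, base_rate_hz = 3,
                        rate_dispersion = 0, burst_rate_per_min = 0,
                        nb_rate_per_min = 0,
                        coupling_pairs = cbind(1, 2))
  coupled <- base; coupled$coupling_strength <- 0.5
  indep <- base; indep$coupling_strength <- 0
  sim_c <- simulate_recording(coupled, protocol = NULL, pre_s = 300,
                              post_s = 0, seed = 5)
  sim_i <- simulate_recording(indep, protocol = NULL, pre_s = 300,
                              post_s = 0, seed = 5)
  p <- mea_params()
  s_c <- cross_correlogram(sim_c$recording$trains[[1]],
                           sim_c$recording$trains[[2]], p)
  s_i <- cross_correlogram(sim_i$recording$trains[[1]],
                           sim_i$recording$trains[[2]], p)
  # coupling jitter is 0-20 ms: the first four bins hold the induced peak
  expect_gt(max(s_c$normalized[1:4]), 2 * max(s_i$normalized))
  # independence: no bin deviates grossly from the flat Poisson expectation
  expe <- s_i$n_i * s_i$n_j * 0.005 / 300 / sqrt(s_i$n_i * s_i$n_j)
  expect_true(all(abs(s_i$normalized - expe) <
                    4 * sqrt(expe / sqrt(s_i$n_i * s_i$n_j)) + 5e-3))
})
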