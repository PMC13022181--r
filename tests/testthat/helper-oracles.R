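# Independent brute-force oracles used across tests. Deliberately slow and
# simple, and independent of the package's implementations.

# exhaustive sliding-window burst oracle: every window anchored at a spike
# with >= m spikes within span w marks its spikes burst-qualified; spikes i
# and i+1 belong to the same event iff one such window contains both.
oracle_scb <- function(times, m = 5, w = 0.030) {
  n <- length(times)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_spikes = integer())
  if (n < m) return(empty)
  hi <- vapply(seq_len(n),
               function(a) max(which(times <= times[a] + w)), integer(1))
  qual <- which(hi - seq_len(n) + 1L >= m)
  if (!length(qual)) return(empty)
  covered <- rep(FALSE, n)
  linked <- rep(FALSE, n)  # linked[i]: i and i+1 share a qualifying window
  for (a in qual) {
    covered[a:hi[a]] <- TRUE
    if (hi[a] > a) linked[a:(hi[a] - 1L)] <- TRUE
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!covered[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && covered[j + 1L] && linked[j]) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(start_s = times[i],
                                          end_s = times[j],
                                          n_spikes = j - i + 1L)
    i <- j + 1L
  }
  do.call(rbind, out)
}

# brute-force delay enumeration: all ordered pairs, O(Ni * Nj)
oracle_correlogram <- function(ti, tj, max_lag = 0.5, bin = 0.005) {
  nbins <- ceiling(max_lag / bin - 1e-9)
  counts <- integer(nbins)
  for (a in seq_along(ti)) {
    for (b in seq_along(tj)) {
      d <- tj[b] - ti[a]
      if (d >= 0 && d < max_lag) {
        k <- min(floor(d / bin) + 1L, nbins)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  counts
}

# exhaustive hypergeometric enumeration for a two-sided Fisher exact p
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# eigen-decomposition PCA oracle on the standardized data
oracle_pca_scores <- function(X, k = 3) {
  Z <- scale(X)
  ev <- eigen(stats::cov(Z), symmetric = TRUE)
  scores <- Z %*% ev$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores, values = ev$values)
}

# textbook paired t statistic
oracle_paired_t <- function(pre, post) {
  d <- post - pre
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# hand Kruskal-Wallis H without ties
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  groups <- as.factor(groups)
  s <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  12 / (n * (n + 1)) * sum(s^2 / ns) - 3 * (n + 1)
}

# deterministic tiny recording: trains given as a named list of time vectors
make_recording <- function(times_by_electrode, duration_s,
                           amplitudes = NULL, stim_epochs = NULL, ...) {
  trains <- lapply(seq_along(times_by_electrode), function(i) {
    t <- times_by_electrode[[i]]
    a <- if (is.null(amplitudes)) rep(-50, length(t)) else amplitudes[[i]]
    spike_train(i, t, a)
  })
  mea_recording(trains, duration_s, stim_epochs = stim_epochs, ...)
}

# random sorted spike train on [0, dur)
random_train <- function(n, dur = 10) sort(runif(n, 0, dur))
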