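# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive everything with explicit loops so they share no code
# with the implementation they check.

# Leave-one-out spike-distance matrix by direct enumeration: for every trial,
# rebuild every class template from scratch excluding that trial.
brute_locv_distances <- function(trial_spikes, labels, window, bin_width) {
  n_bins <- max(1, round(window$duration / bin_width))
  X <- matrix(0, length(trial_spikes), n_bins)
  for (i in seq_along(trial_spikes)) {
    for (sp in trial_spikes[[i]]) {
      b <- floor((sp - window$start) / bin_width) + 1
      if (b >= 1 && b <= n_bins && sp < window$start + n_bins * bin_width) {
        X[i, b] <- X[i, b] + 1
      }
    }
  }
  f <- factor(labels)
  D <- matrix(NA_real_, length(labels), nlevels(f))
  for (i in seq_along(labels)) {
    for (c in seq_len(nlevels(f))) {
      idx <- setdiff(which(as.integer(f) == c), i)
      tmpl <- colMeans(X[idx, , drop = FALSE])
      D[i, c] <- sqrt(sum((X[i, ] - tmpl)^2))
    }
  }
  D
}

# Confidence-weighted population decode by direct summation over units.
brute_population_percent <- function(unit_spikes, labels, window) {
  f <- factor(labels)
  k <- nlevels(f)
  n <- length(labels)
  wsum <- matrix(0, n, k)
  for (u in unit_spikes) {
    D <- brute_locv_distances(u, labels, window, window$duration)
    for (i in seq_len(n)) {
      est <- which.min(D[i, ])  # fixtures are built tie-free
      w <- 1 - D[i, est] / sum(D[i, ])
      wsum[i, est] <- wsum[i, est] + w
    }
  }
  est <- apply(wsum, 1, which.max)
  100 * mean(est == as.integer(f))
}

# A deterministic two-class toy: class "a" trials spike densely, class "b"
# trials are silent, so any window yields perfect separation without ties.
noiseless_two_class <- function(n_per_class = 3, epoch = c(-0.5, 1.5)) {
  dense <- seq(epoch[1] + 0.001, epoch[2] - 0.001, by = 0.001)
  spikes <- c(replicate(n_per_class, dense, simplify = FALSE),
              replicate(n_per_class, numeric(0), simplify = FALSE))
  list(spikes = spikes, labels = rep(c("a", "b"), each = n_per_class))
}

# Homogeneous-Poisson unit over a balanced trial table.
poisson_unit_fixture <- function(rate = 15, n_trials = 40, n_classes = 2,
                                 seed = 1, epoch = c(-0.5, 1.5)) {
  set.seed(seed)
  spikes <- replicate(n_trials, {
    n <- rpois(1, rate * diff(epoch))
    sort(runif(n, epoch[1], epoch[2]))
  }, simplify = FALSE)
  list(spikes = spikes,
       labels = rep(seq_len(n_classes), length.out = n_trials))
}

# Vowel-tuned simulated unit via the generator (shared by several tests).
tuned_unit_fixture <- function(gain = 40, latency = 0.02, duration = 0.1,
                               baseline = 10, n_per_vowel = 20, seed = 1) {
  tt <- generate_trial_table(trials_per_condition = n_per_vowel,
                             feature_values = 200, p_correct = 1,
                             seed = seed)
  tun <- unit_tuning(baseline, kernels = list(
    list(feature = "vowel", latency = latency, duration = duration,
         gain = c(u = gain, e = 0))))
  ds <- generate_dataset(list(u1 = tun), tt, seed = seed + 1)
  list(spikes = spikes_by_trial(ds, tt, "u1"), trials = tt)
}
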