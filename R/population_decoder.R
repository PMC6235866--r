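#' Confidence weight of a single-unit estimate
#'
#' Given a unit's spike distances d_1..d_n from a test trial to its n class
#' templates, the estimate is the nearest template and its confidence weight
#' is
#' \deqn{w = 1 - d_{min} / \sum_j d_j,}
#' bounded in [1 - 1/n, 1]: w = 1 when the nearest template matches exactly
#' (d_min = 0) and w = 1 - 1/n exactly when all distances are equal (an
#' uninformative estimate). If every distance is zero the estimate is a
#' seeded random guess carrying the floor weight.
#'
#' @param distances numeric vector of per-class distances, length >= 2, all
#'   non-negative.
#' @param seed RNG seed for degenerate tie-breaking.
#' @return list of class \code{unit_estimate}: estimate (class index), w,
#'   d_min, distances, n.
#' @export
confidence_weight <- function(distances, seed = NULL) {
  n <- length(distances)
  if (n < 2) stop("need at least two classes", call. = FALSE)
  if (any(distances < 0)) stop("distances must be non-negative",
                               call. = FALSE)
  total <- sum(distances)
  est <- with_seed(seed, argmin_random_tie(distances))
  if (total == 0) {
    w <- 1 - 1 / n
  } else {
    w <- 1 - distances[est] / total
  }
  structure(list(estimate = est, w = w, d_min = distances[est],
                 distances = distances, n = n),
            class = "unit_estimate")
}

#' Confidence-weighted population decoding
#'
#' Each member unit estimates the stimulus class on every trial by the
#' leave-one-out spike-distance rule within the given window and contributes
#' its confidence weight to its estimated class; the class with the largest
#' summed weight is the population estimate for that trial (argmax ties
#' broken by a seeded uniform draw). Within the window the response is a
#' single spike-count bin by default.
#'
#' @param unit_spikes list over units; each element is a list of per-trial
#'   spike-time vectors aligned to the same trials.
#' @param labels per-trial class labels.
#' @param window decoding window (default the onset window [0, 0.1) s; the
#'   main analysis roves a 100 ms window).
#' @param bin_width bin width in seconds; defaults to the window duration
#'   (single-bin counts).
#' @param min_trials per-class floor (the population analysis requires at
#'   least 8 trials per vowel).
#' @param seed RNG seed.
#' @return list of class \code{population_decode_result}: percent_correct,
#'   estimates (per trial), weight_sums (trials x classes), n_units, window.
#' @export
population_decode <- function(unit_spikes, labels,
                              window = decoding_window(0, 0.1),
                              bin_width = NULL, min_trials = 8,
                              seed = NULL) {
  f <- factor(labels)
  k <- nlevels(f)
  cls <- as.integer(f)
  nc <- table(f)
  if (any(nc < max(2, min_trials))) {
    stop(sprintf("insufficient data: class '%s' has %d trials (minimum %d)",
                 names(nc)[which.min(nc)], min(nc), min_trials),
         call. = FALSE)
  }
  if (is.null(bin_width)) bin_width <- window$duration
  n_trials <- length(labels)
  with_seed(seed, {
    wsum <- matrix(0, n_trials, k, dimnames = list(NULL, levels(f)))
    for (u in unit_spikes) {
      X <- bin_trials(u, window, bin_width)
      D <- locv_distances(X, cls, k)
      tot <- rowSums(D)
      for (i in seq_len(n_trials)) {
        est <- argmin_random_tie(D[i, ])
        w <- if (tot[i] == 0) 1 - 1 / k else 1 - D[i, est] / tot[i]
        wsum[i, est] <- wsum[i, est] + w
      }
    }
    pop_est <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      pop_est[i] <- argmin_random_tie(-wsum[i, ])
    }
    structure(list(percent_correct = 100 * mean(pop_est == cls),
                   estimates = factor(levels(f)[pop_est],
                                      levels = levels(f)),
                   weight_sums = wsum, n_units = length(unit_spikes),
                   window = window),
              class = "population_decode_result")
  })
}

#' Sample unit combinations for population decoding
#'
#' Draws combinations of units of a given size, without replacement within a
#' combination, from the pool of units ranked by their correct-trial vowel
#' decoding (pools of up to 74 units, the point at which population
#' performance typically saturates). Combinations are de-duplicated where the
#' pool permits fewer than \code{n_combos} distinct sets.
#'
#' @param pool vector of unit ids (already restricted/ranked by the caller).
#' @param size population size, between 1 and length(pool).
#' @param n_combos number of combinations requested (default 100).
#' @param seed RNG seed.
#' @return list of unit-id vectors (each sorted), at most n_combos, unique.
#' @export
sample_populations <- function(pool, size, n_combos = 100, seed = NULL) {
  if (size < 1 || size > length(pool)) {
    stop("population size must be between 1 and the pool size",
         call. = FALSE)
  }
  n_possible <- choose(length(pool), size)
  with_seed(seed, {
    combos <- list()
    seen <- character(0)
    attempts <- 0L
    max_attempts <- n_combos * 50L
    while (length(combos) < min(n_combos, n_possible) &&
           attempts < max_attempts) {
      s <- sort(sample(pool, size))
      key <- paste(s, collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        combos[[length(combos) + 1L]] <- s
      }
      attempts <- attempts + 1L
    }
    combos
  })
}

#' Population decoding time course in a roving window
#'
#' Decodes the population in a fixed-length window roved across the trial
#' epoch and reports performance against window-center time, together with
#' the center of peak performance (first maximum for ties).
#'
#' @inheritParams population_decode
#' @param window_length roving window length in seconds (default 0.1).
#' @param step interval between window starts in seconds.
#' @param t_min,t_max range of window start times in seconds.
#' @return list of class \code{population_curve}: curve (data.frame with
#'   start, center, percent_correct), peak_time, peak_performance.
#' @export
roving_population_curve <- function(unit_spikes, labels,
                                    window_length = 0.1, step = 0.05,
                                    t_min = -0.2, t_max = 0.9,
                                    min_trials = 8, seed = NULL) {
  starts <- seq(t_min, t_max, by = step)
  perf <- with_seed(seed, vapply(starts, function(s) {
    population_decode(unit_spikes, labels,
                      decoding_window(s, window_length),
                      min_trials = min_trials)$percent_correct
  }, numeric(1)))
  curve <- data.frame(start = starts, center = starts + window_length / 2,
                      percent_correct = perf)
  peak <- which.max(perf)
  structure(list(curve = curve, peak_time = curve$center[peak],
                 peak_performance = perf[peak]),
            class = "population_curve")
}

#' Permutation test of peak-decoding times between orthogonal dimensions
#'
#' For each pair of orthogonal dimensions, the statistic is the difference in
#' mean peak-decoding time across populations; the null is built by shuffling
#' the dimension labels of the pooled peak times and recomputing the
#' difference on each iteration. Two-sided p-values.
#'
#' @param peak_times numeric vector of peak times (s), one per population.
#' @param dimensions factor or character vector labeling the orthogonal
#'   dimension each population was drawn from.
#' @param n_iter permutation iterations (default 1e4).
#' @param seed RNG seed.
#' @return data.frame with one row per dimension pair: dim_a, dim_b,
#'   observed_diff (mean a - mean b), p.
#' @export
dimension_timing_permutation <- function(peak_times, dimensions,
                                         n_iter = 1e4, seed = NULL) {
  g <- factor(dimensions)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  with_seed(seed, {
    rows <- lapply(pairs, function(pr) {
      sel <- g %in% pr
      x <- peak_times[sel]
      gg <- droplevels(g[sel])
      obs <- mean(x[gg == pr[1]]) - mean(x[gg == pr[2]])
      null <- vapply(seq_len(n_iter), function(i) {
        sh <- sample(gg)
        mean(x[sh == pr[1]]) - mean(x[sh == pr[2]])
      }, numeric(1))
      data.frame(dim_a = pr[1], dim_b = pr[2], observed_diff = obs,
                 p = mean(abs(null) >= abs(obs)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
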