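#' Null distribution of optimized decoding performance
#'
#' Repeats the full decoding procedure — including the exhaustive
#' window optimization — with the decoded feature randomly shuffled between
#' trials. Because the best window is re-selected on every shuffle, the null
#' best-performances sit above nominal chance; shuffling without
#' re-optimization would understate the null. Only the decoded label is
#' permuted; any orthogonal feature stays attached to its trial.
#'
#' @inheritParams decode_surface
#' @param n_shuffles number of label shuffles (default 100; fewer than 10 is
#'   refused because the Gaussian fit is unstable).
#' @param seed RNG seed covering shuffles and tie-breaks.
#' @return numeric vector of length n_shuffles: best performance per shuffle.
#' @export
shuffle_null <- function(trial_spikes, labels, grid = make_window_grid(),
                         bin_width = 0.01, n_shuffles = 100,
                         min_trials = 5, seed = NULL) {
  if (n_shuffles < 10) {
    stop("need at least 10 shuffles for a stable Gaussian fit", call. = FALSE)
  }
  f <- factor(labels)
  cls <- as.integer(f)
  binned <- precompute_grid_bins(trial_spikes, grid, bin_width)
  with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      best_over_grid(binned, sample(cls), nlevels(f))$best_performance
    }, numeric(1))
  })
}

#' Gaussian upper-tail probability of an observed performance
#'
#' Fits a Gaussian to the shuffled null best-performances (sample mean and
#' standard deviation) and returns the upper-tail probability of the observed
#' performance, clamped to (1e-10, 1]. The parametric fit trades the
#' empirical null's resolution for far fewer shuffles. A degenerate null
#' (all shuffles identical) gives p = 1 when the observed value does not
#' exceed it and the clamp floor when it does.
#'
#' @param observed observed percent correct.
#' @param null_values numeric vector of shuffled best-performances.
#' @param eps lower clamp for p.
#' @return list: p, null_mean, null_sd, observed, n_shuffles.
#' @export
gaussian_tail_p <- function(observed, null_values, eps = 1e-10) {
  mu <- mean(null_values)
  sd <- stats::sd(null_values)
  if (is.na(sd) || sd == 0) {
    p <- if (observed <= mu) 1 else eps
  } else {
    p <- stats::pnorm(observed, mean = mu, sd = sd, lower.tail = FALSE)
    p <- min(1, max(eps, p))
  }
  list(p = p, null_mean = mu, null_sd = if (is.na(sd)) 0 else sd,
       observed = observed, n_shuffles = length(null_values))
}

#' Flag an informative unit
#'
#' A unit is informative about a feature when the probability of observing
#' its real optimized decoding performance under the shuffled null is
#' strictly below alpha.
#'
#' @param result list with element \code{p} (e.g. from
#'   \code{\link{gaussian_tail_p}}) or a numeric p-value.
#' @param alpha significance level (default 0.05).
#' @return logical flag.
#' @export
classify_informative <- function(result, alpha = 0.05) {
  p <- if (is.list(result)) result$p else result
  p < alpha
}

#' Permutation significance of one unit's optimized decoding
#'
#' Convenience wrapper: observed \code{\link{decode_surface}}, shuffled null,
#' Gaussian tail probability and informative flag in one call.
#'
#' @inheritParams shuffle_null
#' @param alpha significance level.
#' @return list of class \code{significance_result}: observed (best
#'   performance), best_window, null_mean, null_sd, p, informative,
#'   n_shuffles, null_values.
#' @export
unit_significance <- function(trial_spikes, labels,
                              grid = make_window_grid(), bin_width = 0.01,
                              n_shuffles = 100, alpha = 0.05,
                              min_trials = 5, seed = NULL) {
  f <- factor(labels)
  cls <- as.integer(f)
  nc <- table(f)
  if (any(nc < max(2, min_trials))) {
    stop(sprintf("insufficient data: class '%s' has %d trials (minimum %d)",
                 names(nc)[which.min(nc)], min(nc), min_trials),
         call. = FALSE)
  }
  if (n_shuffles < 10) {
    stop("need at least 10 shuffles for a stable Gaussian fit", call. = FALSE)
  }
  binned <- precompute_grid_bins(trial_spikes, grid, bin_width)
  res <- with_seed(seed, {
    obs <- best_over_grid(binned, cls, nlevels(f))
    nulls <- vapply(seq_len(n_shuffles), function(s) {
      best_over_grid(binned, sample(cls), nlevels(f))$best_performance
    }, numeric(1))
    list(obs = obs, nulls = nulls)
  })
  g <- gaussian_tail_p(res$obs$best_performance, res$nulls)
  b <- res$obs$best_index
  structure(list(observed = res$obs$best_performance,
                 best_window = decoding_window(grid$start[b],
                                               grid$duration[b]),
                 null_mean = g$null_mean, null_sd = g$null_sd, p = g$p,
                 informative = classify_informative(g, alpha),
                 alpha = alpha, n_shuffles = n_shuffles,
                 null_values = res$nulls),
            class = "significance_result")
}

#' Unit-identity permutation for dual-feature units
#'
#' Tests whether units informative about two features jointly ("dual-feature
#' units") occur more often than expected from each feature's informative
#' fraction alone. Each iteration permutes unit identity of one flag set and
#' recounts the joint units; p is the fraction of permuted counts strictly
#' above the observed count (ties-inclusive variant behind
#' \code{include_ties}). When every permutation reproduces the observed count
#' (a degenerate null with no variability, e.g. one flag set all TRUE), p = 1.
#' Under the null the joint count follows the hypergeometric law.
#'
#' @param flags_a,flags_b logical vectors of per-unit informative flags over
#'   the same units.
#' @param n_iter permutation iterations (default 1e4).
#' @param include_ties count permuted values equal to the observed as
#'   extreme.
#' @param seed RNG seed.
#' @return list: observed joint count, p, null_counts, n_iter.
#' @export
dual_feature_permutation <- function(flags_a, flags_b, n_iter = 1e4,
                                     include_ties = FALSE, seed = NULL) {
  if (length(flags_a) != length(flags_b)) {
    stop("flag vectors must cover the same units", call. = FALSE)
  }
  observed <- sum(flags_a & flags_b)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_iter),
           function(i) sum(flags_a & sample(flags_b)), integer(1))
  })
  if (all(null_counts == observed)) {
    p <- 1
  } else if (include_ties) {
    p <- mean(null_counts >= observed)
  } else {
    p <- mean(null_counts > observed)
  }
  list(observed = observed, p = p, null_counts = null_counts,
       n_iter = n_iter)
}
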