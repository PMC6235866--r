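#' Decoding window
#'
#' A response window [start, start + duration) in seconds relative to
#' first-token onset. The window center, start + duration / 2, is the
#' statistic used in all timing analyses.
#'
#' @param start start time in seconds.
#' @param duration window duration in seconds, > 0.
#' @return list with start, duration and center.
#' @export
decoding_window <- function(start, duration) {
  stopifnot_scalar(start, "start")
  stopifnot_scalar(duration, "duration")
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  list(start = start, duration = duration, center = start + duration / 2)
}

#' Exhaustive window grid
#'
#' Cartesian grid of window start times and durations, inclusive endpoints,
#' ordered by start then duration (the lexicographic tie-break order used
#' when several windows share the best performance). The defaults give the
#' 31 x 50 = 1550-window grid used throughout: starts -0.5 to 1 s and
#' durations 10 to 500 ms.
#'
#' @param start_min,start_max,start_step start-time range and step (s).
#' @param dur_min,dur_max,dur_step duration range and step (s).
#' @return data.frame with columns start, duration, center.
#' @export
make_window_grid <- function(start_min = -0.5, start_max = 1,
                             start_step = 0.05,
                             dur_min = 0.01, dur_max = 0.5, dur_step = 0.01) {
  starts <- seq(start_min, start_max, by = start_step)
  durs <- seq(dur_min, dur_max, by = dur_step)
  g <- expand.grid(duration = durs, start = starts)[, c("start", "duration")]
  g$center <- g$start + g$duration / 2
  rownames(g) <- NULL
  g
}

#' Bin spikes within a decoding window
#'
#' Counts spikes in half-open bins tiling the window; a spike exactly at the
#' window end is excluded. The vector length is round(duration / bin_width).
#'
#' @param spikes numeric vector of spike times (s).
#' @param window a \code{\link{decoding_window}} or list with start/duration.
#' @param bin_width bin width in seconds.
#' @return Integer count vector.
#' @export
bin_window_response <- function(spikes, window, bin_width = 0.01) {
  n_bins <- max(1L, round(window$duration / bin_width))
  breaks <- window$start + bin_width * (0:n_bins)
  idx <- findInterval(spikes, breaks)
  tabulate(idx[idx >= 1L & idx <= n_bins &
                 spikes < breaks[n_bins + 1L]], n_bins)
}

# Bin every trial of one unit for one window: n_trials x n_bins matrix.
bin_trials <- function(trial_spikes, window, bin_width = 0.01) {
  n_bins <- max(1L, round(window$duration / bin_width))
  breaks <- window$start + bin_width * (0:n_bins)
  X <- matrix(0, nrow = length(trial_spikes), ncol = n_bins)
  for (i in seq_along(trial_spikes)) {
    sp <- trial_spikes[[i]]
    idx <- findInterval(sp, breaks)
    keep <- idx >= 1L & idx <= n_bins & sp < breaks[n_bins + 1L]
    if (any(keep)) X[i, ] <- tabulate(idx[keep], n_bins)
  }
  X
}

# Leave-one-out Euclidean distances from each trial to each class template.
# Templates are mean PSTHs over all *other* trials; for the test trial's own
# class the distance to the hold-out template equals nc/(nc-1) times the
# distance to the full-class mean, which avoids recomputing templates per
# trial. Returns an n x k matrix of distances.
locv_distances <- function(X, cls, n_cls) {
  nc <- tabulate(cls, n_cls)
  S <- rowsum(X, cls, reorder = TRUE)          # class sums, k x b
  M <- S / nc
  d2 <- outer(rowSums(X * X), rowSums(M * M), "+") - 2 * (X %*% t(M))
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  own <- cbind(seq_len(nrow(X)), cls)
  D[own] <- D[own] * nc[cls] / (nc[cls] - 1)
  D
}

# fast inner decode used by surfaces and shuffles: estimates + percent correct
locv_core <- function(X, cls, n_cls, tie_tol = 1e-9) {
  D <- locv_distances(X, cls, n_cls)
  est <- integer(nrow(D))
  for (i in seq_len(nrow(D))) est[i] <- argmin_random_tie(D[i, ], tie_tol)
  list(estimates = est, distances = D,
       percent_correct = 100 * mean(est == cls))
}

#' Spike-distance decoder with leave-one-out cross-validation
#'
#' For each trial, class templates are the mean peri-stimulus time histograms
#' (spike counts per bin) over all other trials, and the trial is assigned to
#' the template with the smallest Euclidean distance. Ties between
#' equidistant templates are resolved by a seeded uniform random guess.
#' Performance is the percentage of trials whose label is correctly
#' recovered.
#'
#' @param trial_spikes list of per-trial spike-time vectors (one unit).
#' @param labels per-trial class labels (factor, character or numeric).
#' @param window a \code{\link{decoding_window}}.
#' @param bin_width bin width in seconds (default 10 ms); set equal to the
#'   window duration for a single-bin count decoder.
#' @param min_trials minimum trials per class (default 5, the study floor);
#'   lower values are permitted for small worked examples.
#' @param seed RNG seed for tie-breaking.
#' @return list of class \code{decode_result}: percent_correct, estimates
#'   (class labels per trial), distances (n x k), confusion matrix,
#'   n_per_class, window, bin_width.
#' @export
locv_decode <- function(trial_spikes, labels, window, bin_width = 0.01,
                        min_trials = 5, seed = NULL) {
  if (length(trial_spikes) != length(labels)) {
    stop("one label per trial required", call. = FALSE)
  }
  f <- factor(labels)
  nc <- table(f)
  if (any(nc < max(2, min_trials))) {
    stop(sprintf("insufficient data: class '%s' has %d trials (minimum %d)",
                 names(nc)[which.min(nc)], min(nc), min_trials),
         call. = FALSE)
  }
  X <- bin_trials(trial_spikes, window, bin_width)
  res <- with_seed(seed, locv_core(X, as.integer(f), nlevels(f)))
  est <- factor(levels(f)[res$estimates], levels = levels(f))
  structure(list(percent_correct = res$percent_correct,
                 estimates = est,
                 distances = res$distances,
                 confusion = table(truth = f, estimate = est),
                 n_per_class = as.integer(nc),
                 classes = levels(f),
                 window = window, bin_width = bin_width),
            class = "decode_result")
}

# Precompute binned responses for every window of a grid (shared across the
# observed decode and every label shuffle).
precompute_grid_bins <- function(trial_spikes, grid, bin_width = 0.01) {
  lapply(seq_len(nrow(grid)), function(i) {
    bin_trials(trial_spikes,
               list(start = grid$start[i], duration = grid$duration[i]),
               bin_width)
  })
}

# Best performance over a precomputed grid for a given label assignment.
# Grid rows are in (start, duration) lexicographic order, so the first
# maximum implements the earliest-start / shortest-duration tie-break.
best_over_grid <- function(binned, cls, n_cls) {
  perf <- vapply(binned,
                 function(X) locv_core(X, cls, n_cls)$percent_correct,
                 numeric(1))
  best <- which.max(perf)
  list(performance = perf, best_index = best, best_performance = perf[best])
}

#' Decoding-performance surface over a window grid
#'
#' Runs \code{\link{locv_decode}} in every window of the grid and reports the
#' best cell. When several windows tie at the maximum, the window with the
#' earliest start time and, within that, the shortest duration is reported.
#'
#' @inheritParams locv_decode
#' @param grid window grid from \code{\link{make_window_grid}}.
#' @return list of class \code{performance_surface}: surface (grid data.frame
#'   with a percent_correct column), best_window, best_performance.
#' @export
decode_surface <- function(trial_spikes, labels, grid = make_window_grid(),
                           bin_width = 0.01, min_trials = 5, seed = NULL) {
  f <- factor(labels)
  nc <- table(f)
  if (any(nc < max(2, min_trials))) {
    stop(sprintf("insufficient data: class '%s' has %d trials (minimum %d)",
                 names(nc)[which.min(nc)], min(nc), min_trials),
         call. = FALSE)
  }
  binned <- precompute_grid_bins(trial_spikes, grid, bin_width)
  res <- with_seed(seed, best_over_grid(binned, as.integer(f), nlevels(f)))
  surface <- grid
  surface$percent_correct <- res$performance
  b <- res$best_index
  structure(list(surface = surface,
                 best_window = decoding_window(grid$start[b],
                                               grid$duration[b]),
                 best_performance = res$best_performance,
                 bin_width = bin_width, classes = levels(f)),
            class = "performance_surface")
}

#' Classify a unit as sound-responsive
#'
#' A unit is sound-responsive when its per-trial spike count in the 300 ms
#' after first-token onset differs significantly from spontaneous activity in
#' a 300 ms baseline window (paired sign-rank test, p < 0.05). Units whose
#' evoked and baseline counts are identical on every trial are not
#' responsive.
#'
#' @param trial_spikes list of per-trial spike-time vectors.
#' @param baseline_window c(start, end) of the baseline epoch in seconds
#'   (default the 300 ms before onset).
#' @param evoked_window c(start, end) of the evoked epoch (default [0, 0.3)).
#' @param alpha significance level.
#' @return list: responsive flag, p, mean evoked and baseline counts.
#' @export
classify_sound_responsive <- function(trial_spikes,
                                      baseline_window = c(-0.3, 0),
                                      evoked_window = c(0, 0.3),
                                      alpha = 0.05) {
  count_in <- function(sp, w) sum(sp >= w[1] & sp < w[2])
  ev <- vapply(trial_spikes, count_in, numeric(1), evoked_window)
  bl <- vapply(trial_spikes, count_in, numeric(1), baseline_window)
  p <- tryCatch(
    stats::wilcox.test(ev, bl, paired = TRUE, exact = FALSE)$p.value,
    error = function(e) 1)
  if (is.na(p)) p <- 1
  list(responsive = p < alpha, p = p,
       mean_evoked = mean(ev), mean_baseline = mean(bl))
}
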