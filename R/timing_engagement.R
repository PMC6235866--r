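#' Center time of a decoding window
#'
#' start + duration / 2; the statistic used to compare when information about
#' different features is available (temporal multiplexing).
#'
#' @param window a \code{\link{decoding_window}} or list with start and
#'   duration.
#' @return center time in seconds.
#' @export
center_time <- function(window) {
  window$start + window$duration / 2
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step function reaching 1, as used for the center-time
#' CDFs. Thin wrapper over \code{stats::ecdf}.
#'
#' @param values numeric vector.
#' @return An \code{ecdf} function.
#' @export
empirical_cdf <- function(values) {
  stats::ecdf(values)
}

#' Compare best-window timing between groups
#'
#' Dispatches to the standard test for the design: paired two-group
#' comparisons use the Wilcoxon sign-rank test with the median paired
#' difference as the effect size; unpaired two-group comparisons use the
#' rank-sum test with the difference of group medians; three or more groups
#' use the Kruskal-Wallis omnibus test with pairwise rank-sum post-hoc
#' comparisons (Holm corrected). The sign convention of \code{delta_t} is
#' group 1 minus group 2.
#'
#' @param groups named list of per-unit center times (seconds), one element
#'   per group.
#' @param paired logical; paired designs require equal-length groups ordered
#'   by the same units.
#' @return list of class \code{timing_comparison}: test, delta_t (two-group
#'   designs), p, and for multi-group designs statistic and posthoc (matrix
#'   of pairwise Holm-adjusted p-values).
#' @export
compare_timing <- function(groups, paired = FALSE) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (length(groups) == 2) {
    a <- groups[[1]]
    b <- groups[[2]]
    if (paired) {
      if (length(a) != length(b)) {
        stop("paired comparison requires identical unit sets", call. = FALSE)
      }
      d <- a - b
      p <- if (all(d == 0)) 1 else
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
      out <- list(test = "sign-rank", delta_t = stats::median(d), p = p)
    } else {
      p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
      out <- list(test = "rank-sum",
                  delta_t = stats::median(a) - stats::median(b), p = p)
    }
  } else {
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
    kw <- stats::kruskal.test(values, g)
    ph <- stats::pairwise.wilcox.test(values, g, p.adjust.method = "holm",
                                      exact = FALSE)
    out <- list(test = "kruskal-wallis", statistic = unname(kw$statistic),
                p = kw$p.value, posthoc = ph$p.value)
  }
  out$groups <- names(groups)
  class(out) <- "timing_comparison"
  out
}

#' Roving firing-rate time course
#'
#' Mean firing rate across trials in overlapping bins (default 100 ms bins at
#' 50 ms intervals) after stimulus onset.
#'
#' @param trial_spikes list of per-trial spike-time vectors.
#' @param bin bin width in seconds.
#' @param step interval between bin starts in seconds.
#' @param t_min,t_max range of bin start times in seconds.
#' @return data.frame with columns start, center, rate_hz.
#' @export
roving_rate <- function(trial_spikes, bin = 0.1, step = 0.05,
                        t_min = 0, t_max = 1) {
  starts <- seq(t_min, t_max - bin, by = step)
  rate <- vapply(starts, function(s) {
    counts <- vapply(trial_spikes,
                     function(sp) sum(sp >= s & sp < s + bin), numeric(1))
    mean(counts) / bin
  }, numeric(1))
  data.frame(start = starts, center = starts + bin / 2, rate_hz = rate)
}

#' Normalize rates to a pre-stimulus baseline
#'
#' Divides (default) or subtracts the mean firing rate in a pre-stimulus
#' baseline period (default the 450 ms before onset). Units with zero
#' baseline cannot be ratio-normalized; they are flagged \code{undefined} and
#' should be excluded from normalized analyses.
#'
#' @param rates numeric vector of rates in Hz.
#' @param trial_spikes list of per-trial spike-time vectors used to measure
#'   the baseline.
#' @param baseline_window c(start, end) of the baseline epoch in seconds.
#' @param mode "ratio" (default) or "difference".
#' @return list: normalized (numeric), baseline_rate_hz, undefined flag.
#' @export
normalize_to_baseline <- function(rates, trial_spikes,
                                  baseline_window = c(-0.45, 0),
                                  mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  dur <- diff(baseline_window)
  counts <- vapply(trial_spikes,
                   function(sp) sum(sp >= baseline_window[1] &
                                      sp < baseline_window[2]), numeric(1))
  baseline <- mean(counts) / dur
  if (mode == "ratio") {
    if (baseline == 0) {
      return(list(normalized = rep(NA_real_, length(rates)),
                  baseline_rate_hz = 0, undefined = TRUE))
    }
    norm <- rates / baseline
  } else {
    norm <- rates - baseline
  }
  list(normalized = norm, baseline_rate_hz = baseline, undefined = FALSE)
}

#' Engaged-vs-passive contrast for a population of units
#'
#' Paired comparison of onset firing rate (default the 100 ms after stimulus
#' onset) and of vowel-decoding performance between task-engaged and passive
#' trials, for units recorded in both states. In \code{mode = "fixed"} both
#' states are decoded in the fixed onset window; in \code{mode = "optimized"}
#' each state gets its own exhaustive window optimization and the comparison
#' uses each state's best window (rates are then measured in the state's own
#' best window).
#'
#' @param units list with one element per unit; each element is a list with
#'   components \code{engaged} and \code{passive}, each a list of per-trial
#'   spike vectors, plus matching \code{engaged_labels} and
#'   \code{passive_labels}.
#' @param window fixed onset window (default [0, 0.1) s).
#' @param mode "fixed" or "optimized".
#' @param grid window grid for optimized mode.
#' @param bin_width decoder bin width in seconds.
#' @param min_trials decoder per-class floor.
#' @param seed RNG seed.
#' @return list of class \code{engagement_contrast}: per-unit data.frame
#'   (rates and performances per state, and best-window centers in optimized
#'   mode) and sign-rank p-values and z statistics for the rate and decoding
#'   contrasts.
#' @export
engaged_passive_contrast <- function(units,
                                     window = decoding_window(0, 0.1),
                                     mode = c("fixed", "optimized"),
                                     grid = make_window_grid(),
                                     bin_width = 0.01, min_trials = 5,
                                     seed = NULL) {
  mode <- match.arg(mode)
  mean_rate <- function(trial_spikes, w) {
    mean(vapply(trial_spikes,
                function(sp) sum(sp >= w$start & sp < w$start + w$duration),
                numeric(1))) / w$duration
  }
  rows <- with_seed(seed, lapply(seq_along(units), function(i) {
    u <- units[[i]]
    if (mode == "fixed") {
      we <- window
      wp <- window
      pe <- locv_decode(u$engaged, u$engaged_labels, window, bin_width,
                        min_trials)$percent_correct
      pp <- locv_decode(u$passive, u$passive_labels, window, bin_width,
                        min_trials)$percent_correct
    } else {
      se <- decode_surface(u$engaged, u$engaged_labels, grid, bin_width,
                           min_trials)
      sp <- decode_surface(u$passive, u$passive_labels, grid, bin_width,
                           min_trials)
      we <- se$best_window
      wp <- sp$best_window
      pe <- se$best_performance
      pp <- sp$best_performance
    }
    data.frame(unit = i,
               rate_engaged = mean_rate(u$engaged, we),
               rate_passive = mean_rate(u$passive, wp),
               perf_engaged = pe, perf_passive = pp,
               center_engaged = center_time(we),
               center_passive = center_time(wp))
  }))
  df <- do.call(rbind, rows)
  signrank <- function(a, b) {
    if (all(a == b)) return(list(p = 1, z = 0))
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                             correct = FALSE)
    # normal-approximation z from the sign-rank statistic
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    list(p = wt$p.value, z = (unname(wt$statistic) - mu) / sigma)
  }
  rate_test <- signrank(df$rate_engaged, df$rate_passive)
  perf_test <- signrank(df$perf_engaged, df$perf_passive)
  structure(list(per_unit = df, mode = mode,
                 rate_p = rate_test$p, rate_z = rate_test$z,
                 decoding_p = perf_test$p, decoding_z = perf_test$z),
            class = "engagement_contrast")
}
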