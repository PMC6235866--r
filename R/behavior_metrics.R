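#' Filter a trial table for behavioral analysis
#'
#' Removes correction trials and trials on which the animal failed to respond
#' within the trial window, keeping probe-trial flags intact. Idempotent.
#'
#' @param trials a trial table.
#' @param response_window maximum response time in seconds (default 60).
#' @return Filtered trial table.
#' @export
filter_analysis_trials <- function(trials, response_window = 60) {
  keep <- trials$trial_type != "correction" &
    !is.na(trials$response_time) & trials$response_time <= response_window
  trials[keep, , drop = FALSE]
}

#' Behavioral constancy summary across an orthogonal feature
#'
#' For each value of the orthogonal feature: trial count, percent correct and
#' a binomial test against chance (50%). Across values, a logistic regression
#' of correct ~ feature; perceptual constancy is reported when the feature
#' coefficient is non-significant (p >= 0.05), i.e. the orthogonal dimension
#' does not affect the likelihood of responding correctly.
#'
#' @param trials a trial table (correction trials are removed first).
#' @param feature orthogonal feature column name ("f0", "level", "location"
#'   or "voicing").
#' @param chance chance percent-correct level (default 50).
#' @return list of class \code{behavior_summary}: per_value data.frame
#'   (value, n, percent_correct, binomial_p), regression (coefficient, p),
#'   constancy flag. Empty feature groups are dropped.
#' @export
constancy_summary <- function(trials, feature, chance = 50) {
  tr <- filter_analysis_trials(trials)
  vals <- unique(tr[[feature]])
  per <- do.call(rbind, lapply(vals, function(v) {
    sub <- tr[tr[[feature]] == v, ]
    if (nrow(sub) == 0) return(NULL)
    k <- sum(sub$correct)
    data.frame(value = v, n = nrow(sub),
               percent_correct = 100 * k / nrow(sub),
               binomial_p = stats::binom.test(k, nrow(sub),
                                              chance / 100)$p.value)
  }))
  x <- tr[[feature]]
  if (is.character(x)) x <- factor(x)
  fit <- stats::glm(correct ~ x, data = data.frame(correct = tr$correct,
                                                   x = x),
                    family = stats::binomial())
  coefs <- summary(fit)$coefficients
  # feature effect: smallest p among non-intercept terms
  feat_p <- if (nrow(coefs) > 1) min(coefs[-1, 4]) else 1
  feat_coef <- if (nrow(coefs) > 1) coefs[2, 1] else 0
  structure(list(per_value = per,
                 regression = list(coefficient = feat_coef, p = feat_p),
                 constancy = feat_p >= 0.05, feature = feature),
            class = "behavior_summary")
}

#' Trials to significant performance on a novel feature value
#'
#' Starting from the first trial on which a novel orthogonal value was
#' experienced, performance is computed over nested windows of the first L
#' trials (L = 1, 2, ...). The null randomizes the required response across
#' trials (each trial correct with probability 1/2) and recomputes percent
#' correct; the reported value is the smallest L at which the observed
#' performance has a false-positive probability below alpha. An error-free
#' subject reaches significance at the smallest L with 0.5^L < alpha (L = 10
#' at alpha = 0.001). One-sided (above chance) by default.
#'
#' @param correct logical vector of trial outcomes ordered from the first
#'   exposure.
#' @param n_iter Monte-Carlo iterations (mode "permutation").
#' @param alpha false-positive threshold (default 0.001).
#' @param mode "exact" uses the closed-form binomial tail
#'   P(X >= k | L, 1/2); "permutation" estimates it by simulation.
#' @param windows "nested" (default) grows windows from trial 1, as the
#'   procedure states; "sliding" instead advances a fixed-length window
#'   (\code{slide_length} trials) by one trial at a time and reports the
#'   trial count at which the window covering the most recent trials first
#'   reaches significance.
#' @param slide_length window length for the sliding variant.
#' @param seed RNG seed.
#' @return list: n_trials (smallest significant L or NA), p_at_n, table
#'   (L, percent_correct, p).
#' @export
generalization_test <- function(correct, n_iter = 1e4, alpha = 0.001,
                                mode = c("exact", "permutation"),
                                windows = c("nested", "sliding"),
                                slide_length = 10, seed = NULL) {
  mode <- match.arg(mode)
  windows <- match.arg(windows)
  n <- length(correct)
  tail_p <- function(k, L) {
    if (mode == "exact") {
      stats::pbinom(k - 1, L, 0.5, lower.tail = FALSE)
    } else {
      null <- stats::rbinom(n_iter, L, 0.5)
      mean(null >= k)
    }
  }
  rows <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(L) {
      idx <- if (windows == "nested") seq_len(L) else
        seq.int(max(1L, L - slide_length + 1L), L)
      k <- sum(correct[idx])
      data.frame(L = L, percent_correct = 100 * k / length(idx),
                 p = tail_p(k, length(idx)))
    }))
  })
  sig <- which(rows$p < alpha)
  n_sig <- if (length(sig)) rows$L[sig[1]] else NA_integer_
  list(n_trials = n_sig,
       p_at_n = if (length(sig)) rows$p[sig[1]] else NA_real_,
       table = rows)
}

#' Long-term performance by resampled trial sequences
#'
#' Distribution of percent correct over randomly selected contiguous
#' sequences of a set window length drawn from the entire record, repeated
#' \code{n_iter} times — the long-term benchmark against which initial
#' (generalization) performance is compared.
#'
#' @param correct logical vector of trial outcomes in session order.
#' @param window_length trials per resampled sequence.
#' @param n_iter resampling iterations (default 1e4).
#' @param seed RNG seed.
#' @return numeric vector of percent-correct values, length n_iter.
#' @export
longterm_performance_resample <- function(correct, window_length,
                                          n_iter = 1e4, seed = NULL) {
  n <- length(correct)
  if (window_length > n) stop("window longer than the record", call. = FALSE)
  with_seed(seed, {
    starts <- sample.int(n - window_length + 1L, n_iter, replace = TRUE)
    vapply(starts, function(s) {
      100 * mean(correct[s:(s + window_length - 1L)])
    }, numeric(1))
  })
}

#' Classify a unit as single- or multi-unit from its inter-spike intervals
#'
#' Single units have less than 1% (strict) of inter-spike intervals shorter
#' than 1 ms.
#'
#' @param isi numeric vector of inter-spike intervals in seconds.
#' @param threshold refractory threshold in seconds (default 1 ms).
#' @param max_fraction maximum allowed fraction of short intervals.
#' @return logical: TRUE for single unit.
#' @export
classify_single_unit <- function(isi, threshold = 0.001,
                                 max_fraction = 0.01) {
  if (length(isi) == 0) return(TRUE)
  mean(isi < threshold) < max_fraction
}
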