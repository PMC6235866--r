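#' Generate a behavioral trial table
#'
#' Simulates the two-choice vowel discrimination task: a balanced grid of
#' vowel x orthogonal-feature conditions, Bernoulli outcomes under a
#' per-condition probability of responding correctly, whispered probe trials
#' on a configured fraction of trials (any response rewarded, no correction
#' follows), and a correction trial inserted after every error on a test
#' trial.
#'
#' @param vowels vowel labels (default the /u/ vs /e/ pair).
#' @param feature name of the orthogonal dimension roved in the session:
#'   "f0", "level", "location" or "voicing".
#' @param feature_values values of the orthogonal dimension (e.g. the five
#'   F0s 149, 200, 263, 330, 459 Hz).
#' @param trials_per_condition test trials per vowel x feature-value cell
#'   (before correction trials are added).
#' @param p_correct probability of a correct choice: a scalar, or a function
#'   of the assembled test-trial data.frame returning one probability per
#'   trial.
#' @param probe_rate whispered probe trials as a fraction of test trials,
#'   in [0, 0.2].
#' @param contingency named character vector mapping vowel to the rewarded
#'   response side.
#' @param engagement "engaged" or "passive", recorded per trial.
#' @param response_time function(n) drawing n response times in seconds from
#'   first-token onset.
#' @param seed RNG seed.
#' @return data.frame of class \code{trial_table} with columns trial_id,
#'   vowel, f0, location, level, voicing, choice, correct, response_time,
#'   trial_type, engagement.
#' @export
generate_trial_table <- function(vowels = c("u", "e"),
                                 feature = "f0",
                                 feature_values = c(149, 200, 263, 330, 459),
                                 trials_per_condition = 20,
                                 p_correct = 0.75,
                                 probe_rate = 0,
                                 contingency = c(u = "left", e = "right"),
                                 engagement = "engaged",
                                 response_time = function(n) stats::runif(n, 0.8, 3),
                                 seed = NULL) {
  if (probe_rate < 0 || probe_rate > 0.2) {
    stop("'probe_rate' must lie in [0, 0.2]", call. = FALSE)
  }
  if (!all(vowels %in% names(contingency))) {
    stop("'contingency' must name every vowel", call. = FALSE)
  }
  with_seed(seed, {
    grid <- expand.grid(vowel = vowels, fval = feature_values,
                        rep = seq_len(trials_per_condition),
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    tt <- data.frame(vowel = grid$vowel,
                     f0 = 200, location = 0, level = 70, voicing = "voiced",
                     stringsAsFactors = FALSE)
    if (feature == "voicing") {
      tt$voicing <- as.character(grid$fval)
    } else {
      tt[[feature]] <- grid$fval
    }
    tt$trial_type <- "test"
    tt <- tt[sample.int(n), , drop = FALSE]

    n_probe <- round(probe_rate * n)
    if (n_probe > 0) {
      pr <- tt[sample.int(n, n_probe, replace = TRUE), , drop = FALSE]
      pr$voicing <- "whispered"
      pr$trial_type <- "probe"
      pos <- sort(sample.int(n + n_probe, n_probe))
      merged <- vector("list", n + n_probe)
      merged[pos] <- split(pr, seq_len(n_probe))
      merged[setdiff(seq_len(n + n_probe), pos)] <- split(tt, seq_len(n))
      tt <- do.call(rbind, merged)
    }

    p <- if (is.function(p_correct)) p_correct(tt) else
      rep_len(p_correct, nrow(tt))
    tt$correct <- stats::runif(nrow(tt)) < p

    # assemble final order, duplicating each erroneous test trial as a
    # correction trial (probe errors are not corrected)
    rows <- vector("list", nrow(tt))
    for (i in seq_len(nrow(tt))) {
      row <- tt[i, , drop = FALSE]
      if (!row$correct && row$trial_type == "test") {
        corr <- row
        corr$trial_type <- "correction"
        corr$correct <- stats::runif(1) < p[i]
        rows[[i]] <- rbind(row, corr)
      } else {
        rows[[i]] <- row
      }
    }
    tt <- do.call(rbind, rows)
    other <- function(side) ifelse(side == "left", "right", "left")
    target <- unname(contingency[tt$vowel])
    tt$choice <- ifelse(tt$correct, target, other(target))
    tt$response_time <- response_time(nrow(tt))
    tt$engagement <- engagement
    tt$trial_id <- seq_len(nrow(tt))
    rownames(tt) <- NULL
    tt <- tt[, c("trial_id", "vowel", "f0", "location", "level", "voicing",
                 "choice", "correct", "response_time", "trial_type",
                 "engagement")]
    class(tt) <- c("trial_table", "data.frame")
    tt
  })
}

#' Unit tuning specification
#'
#' Parameterizes one synthetic auditory-cortical unit: a baseline firing rate
#' plus feature-specific temporal kernels. Each kernel is a half-cosine bump
#' over [latency, latency + duration] whose amplitude is a per-feature-value
#' gain, so different features can be encoded at distinct latencies (temporal
#' multiplexing). Behavioral modulation is expressed through kernels on the
#' "choice" and "correct" columns; task engagement scales the evoked (not
#' baseline) rate during stimulus presentation.
#'
#' @param baseline_rate spontaneous rate in Hz.
#' @param kernels list of kernels, each a list with elements \code{feature}
#'   (a trial-table column name: "vowel", "f0", "level", "location",
#'   "voicing", "choice" or "correct"), \code{latency} and \code{duration}
#'   in seconds (the bump must lie within [-0.5, 1.5] s), and \code{gain}, a
#'   named numeric vector mapping feature values to peak rate contributions
#'   in Hz.
#' @param engagement_scale multiplicative factor applied to the evoked rate
#'   during [0, 1] s on engaged trials (1 = no suppression).
#' @param is_single_unit logical flag, recorded as metadata.
#' @return An object of class \code{unit_tuning}.
#' @examples
#' unit_tuning(10, kernels = list(
#'   list(feature = "vowel", latency = 0.02, duration = 0.1,
#'        gain = c(u = 30, e = 0))))
#' @export
unit_tuning <- function(baseline_rate = 10, kernels = list(),
                        engagement_scale = 1, is_single_unit = TRUE) {
  stopifnot_scalar(baseline_rate, "baseline_rate")
  if (baseline_rate < 0) stop("'baseline_rate' must be >= 0", call. = FALSE)
  for (k in kernels) {
    if (!all(c("feature", "latency", "duration", "gain") %in% names(k))) {
      stop("each kernel needs feature, latency, duration and gain",
           call. = FALSE)
    }
    if (k$latency < -0.5 || k$latency + k$duration > 1.5 || k$duration <= 0) {
      stop("kernel window must lie within [-0.5, 1.5] s", call. = FALSE)
    }
  }
  structure(list(baseline_rate = baseline_rate, kernels = kernels,
                 engagement_scale = engagement_scale,
                 is_single_unit = is_single_unit),
            class = "unit_tuning")
}

halfcos_bump <- function(t, latency, duration) {
  u <- (t - latency) / duration
  ifelse(u >= 0 & u <= 1, sin(pi * u), 0)
}

#' Firing-rate profile of a unit on one trial
#'
#' Evaluates \code{max(0, baseline + scale * sum(kernels))} where the sum runs
#' over the tuning kernels evaluated at the trial's feature values, and
#' \code{scale} is the engagement factor during [0, 1] s on engaged trials.
#'
#' @param tuning a \code{\link{unit_tuning}}.
#' @param trial one row of a trial table (list or 1-row data.frame).
#' @return function(t) returning the rate in Hz (vectorized over t).
#' @export
rate_profile <- function(tuning, trial) {
  trial <- as.list(trial)
  kern <- list()
  for (k in tuning$kernels) {
    val <- as.character(trial[[k$feature]])
    g <- if (val %in% names(k$gain)) unname(k$gain[val]) else 0
    if (g != 0) kern[[length(kern) + 1L]] <-
        list(g = g, latency = k$latency, duration = k$duration)
  }
  engaged <- identical(trial$engagement, "engaged")
  scale <- tuning$engagement_scale
  baseline <- tuning$baseline_rate
  function(t) {
    evoked <- numeric(length(t))
    for (k in kern) evoked <- evoked + k$g * halfcos_bump(t, k$latency,
                                                          k$duration)
    if (engaged && scale != 1) {
      evoked <- evoked * ifelse(t >= 0 & t < 1, scale, 1)
    }
    pmax(0, baseline + evoked)
  }
}

#' Sample spikes from a rate function
#'
#' Inhomogeneous Poisson sampling by thinning: candidates are drawn from a
#' homogeneous process at the rate ceiling and retained with probability
#' rate(t) / ceiling, so counts in any interval are Poisson with mean equal
#' to the integrated rate.
#'
#' @param rate function(t) in Hz.
#' @param epoch c(start, end) in seconds (default the full covered epoch
#'   [-0.5, 1.5] s).
#' @param seed RNG seed.
#' @param rate_max optional ceiling in Hz; estimated from a 1 ms grid when
#'   missing (rate profiles here are smooth half-cosine sums, so the grid
#'   maximum is a valid bound up to negligible error).
#' @return Sorted numeric vector of spike times in seconds.
#' @export
sample_spikes <- function(rate, epoch = c(-0.5, 1.5), seed = NULL,
                          rate_max = NULL) {
  if (is.null(rate_max)) {
    grid <- seq(epoch[1], epoch[2], by = 0.001)
    rate_max <- max(rate(grid))
  }
  if (rate_max <= 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- stats::rpois(1, rate_max * diff(epoch))
    if (n_cand == 0) return(numeric(0))
    t_cand <- stats::runif(n_cand, epoch[1], epoch[2])
    keep <- stats::runif(n_cand) * rate_max < rate(t_cand)
    sort(t_cand[keep])
  })
}

#' Generate a spike dataset for a population
#'
#' Samples spike trains for every unit on every trial, independently across
#' units conditional on the trial. Fully reproducible given the seed.
#'
#' @param population list of \code{\link{unit_tuning}} specs; names become
#'   unit ids (defaults to unit_1, unit_2, ...).
#' @param trials a trial table from \code{\link{generate_trial_table}}.
#' @param epoch covered epoch in seconds.
#' @param seed RNG seed.
#' @return data.frame of class \code{spike_dataset} with columns unit_id,
#'   trial_id, spike_time_s, plus a "units" attribute (unit metadata).
#' @export
generate_dataset <- function(population, trials, epoch = c(-0.5, 1.5),
                             seed = NULL) {
  ids <- names(population)
  if (is.null(ids)) ids <- paste0("unit_", seq_along(population))
  with_seed(seed, {
    out <- vector("list", length(population) * nrow(trials))
    idx <- 1L
    for (u in seq_along(population)) {
      tun <- population[[u]]
      for (i in seq_len(nrow(trials))) {
        r <- rate_profile(tun, trials[i, ])
        sp <- sample_spikes(r, epoch)
        if (length(sp)) {
          out[[idx]] <- data.frame(unit_id = ids[u],
                                   trial_id = trials$trial_id[i],
                                   spike_time_s = sp,
                                   stringsAsFactors = FALSE)
          idx <- idx + 1L
        }
      }
    }
    spikes <- do.call(rbind, out[seq_len(idx - 1L)])
    if (is.null(spikes)) {
      spikes <- data.frame(unit_id = character(0), trial_id = integer(0),
                           spike_time_s = numeric(0))
    }
    attr(spikes, "units") <- data.frame(
      unit_id = ids,
      is_single_unit = vapply(population, function(x) x$is_single_unit,
                              logical(1)),
      stringsAsFactors = FALSE)
    class(spikes) <- c("spike_dataset", "data.frame")
    spikes
  })
}

#' Split a unit's spikes into per-trial spike-time vectors
#'
#' @param spikes a \code{spike_dataset} (long format).
#' @param trials trial table giving the trial order.
#' @param unit_id unit to extract; may be omitted if the dataset holds a
#'   single unit.
#' @return Named list (by trial_id) of sorted spike-time vectors, one per
#'   trial row, empty trials included.
#' @export
spikes_by_trial <- function(spikes, trials, unit_id = NULL) {
  if (!is.null(unit_id)) spikes <- spikes[spikes$unit_id == unit_id, ]
  out <- split(spikes$spike_time_s,
               factor(spikes$trial_id, levels = trials$trial_id))
  lapply(out, sort)
}
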