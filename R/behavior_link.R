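#' Build a matched vowel x choice x outcome dataset
#'
#' Subsamples a trial table so that every occupied cell of the vowel (2) x
#' choice (2) x outcome (2) design holds exactly N trials, where N is the
#' minimum count over the cells in which any trials were tested. Under a
#' fixed stimulus-response contingency the outcome is determined by vowel and
#' choice, so four of the eight cells occur (e.g. left responses to /u/ are
#' by definition correct); balancing those at N makes the label priors of all
#' three decoded variables uniform, so sound, choice and accuracy decoding
#' are mutually unconfounded — and behavioral percent correct over the set is
#' exactly 50%. Exclusions follow the study rules: whispered trials, trials
#' below the level floor, correction trials, and trials with fast behavioral
#' responses (to keep the trial outcome — reward or time-out — outside the
#' decoding window).
#'
#' @param trials a trial table with vowel, choice, correct, voicing, level,
#'   response_time and trial_type columns.
#' @param level_floor minimum sound level in dB; trials at or below it are
#'   excluded (60 dB for three ferrets, 70 dB for one).
#' @param response_floor minimum response time in seconds (default 1).
#' @param rt_anchor "first_token" anchors the response-time exclusion to
#'   first-token onset (the procedures-section convention, default);
#'   "second_token" anchors it to second-token onset at 0.5 s, i.e. excludes
#'   responses before \code{0.5 + response_floor} s.
#' @param min_n minimum acceptable N (default 5); smaller limiting cells
#'   raise an error naming the cell.
#' @param seed RNG seed for the uniform down-sampling.
#' @return list of class \code{matched_dataset}: trial_ids, n_per_cell (N),
#'   cells (counts before matching), trials (the selected rows) and
#'   exclusions (named counts of trials removed per rule).
#' @export
build_matched_dataset <- function(trials, level_floor = 60,
                                  response_floor = 1,
                                  rt_anchor = c("first_token",
                                                "second_token"),
                                  min_n = 5, seed = NULL) {
  rt_anchor <- match.arg(rt_anchor)
  rt_cut <- response_floor + if (rt_anchor == "second_token") 0.5 else 0
  excl <- c(correction = sum(trials$trial_type == "correction"),
            whispered = 0, level = 0, fast_response = 0)
  keep <- trials[trials$trial_type != "correction", , drop = FALSE]
  excl["whispered"] <- sum(keep$voicing == "whispered")
  keep <- keep[keep$voicing != "whispered", , drop = FALSE]
  excl["level"] <- sum(keep$level <= level_floor)
  keep <- keep[keep$level > level_floor, , drop = FALSE]
  excl["fast_response"] <- sum(keep$response_time < rt_cut)
  keep <- keep[keep$response_time >= rt_cut, , drop = FALSE]

  cell <- interaction(keep$vowel, keep$choice, keep$correct, drop = TRUE)
  counts <- table(cell)
  if (length(counts) == 0 || min(counts) < min_n) {
    lim <- if (length(counts)) names(counts)[which.min(counts)] else "(none)"
    stop(sprintf(
      "insufficient data: limiting cell '%s' has %d trials (minimum %d)",
      lim, if (length(counts)) min(counts) else 0L, min_n), call. = FALSE)
  }
  n <- min(counts)
  sel <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(keep)), cell), function(idx) {
      if (length(idx) == n) idx else idx[sample.int(length(idx), n)]
    }), use.names = FALSE)
  })
  sel <- sort(sel)
  matched <- keep[sel, , drop = FALSE]
  structure(list(trial_ids = matched$trial_id, n_per_cell = as.integer(n),
                 cells = counts, trials = matched, exclusions = excl,
                 level_floor = level_floor, response_floor = response_floor,
                 rt_anchor = rt_anchor),
            class = "matched_dataset")
}

#' Decode sound, choice and accuracy from a matched dataset
#'
#' Runs the optimized spike-distance decoder and its permutation significance
#' test independently for three label columns of the matched trials: vowel
#' identity (sound), behavioral choice (left/right) and accuracy
#' (correct/error).
#'
#' @param matched a \code{\link{build_matched_dataset}} result.
#' @param spikes a \code{spike_dataset}.
#' @param unit_id unit to decode.
#' @param grid window grid.
#' @param bin_width decoder bin width in seconds.
#' @param n_shuffles shuffles for the permutation test.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return named list (sound, choice, accuracy) of
#'   \code{significance_result}s.
#' @export
decode_sound_choice_accuracy <- function(matched, spikes, unit_id,
                                         grid = make_window_grid(),
                                         bin_width = 0.01, n_shuffles = 100,
                                         alpha = 0.05, seed = NULL) {
  tr <- matched$trials
  ts <- spikes_by_trial(spikes, tr, unit_id)
  labels <- list(sound = tr$vowel, choice = tr$choice, accuracy = tr$correct)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list(seed + seq_along(labels))
  out <- lapply(seq_along(labels), function(i) {
    unit_significance(ts, labels[[i]], grid = grid, bin_width = bin_width,
                      n_shuffles = n_shuffles, alpha = alpha,
                      min_trials = matched$n_per_cell, seed = seeds[[i]])
  })
  names(out) <- names(labels)
  out
}

#' Decode correct and error trials separately
#'
#' Correct trials are decoded with the standard leave-one-out procedure.
#' Error trials are decoded against fixed templates built from all correct
#' trials, so a unit that encodes the animal's choice rather than the
#' stimulus decodes the vowel below chance on errors (choice is
#' anti-correlated with vowel when the animal is wrong).
#'
#' @param trial_spikes list of per-trial spike-time vectors.
#' @param labels per-trial stimulus labels.
#' @param correct logical vector: was the behavioral response correct.
#' @param window decoding window.
#' @param bin_width bin width in seconds.
#' @param min_trials per-class floor for the correct-trial LOCV.
#' @param seed RNG seed.
#' @return list of class \code{error_trial_result}: correct
#'   (\code{decode_result}), error_percent_correct, error_estimates,
#'   n_error. Raises a condition of class \code{no_error_trials} when the
#'   animal made no errors.
#' @export
error_trial_decode <- function(trial_spikes, labels, correct, window,
                               bin_width = 0.01, min_trials = 5,
                               seed = NULL) {
  if (!any(!correct)) {
    stop(structure(class = c("no_error_trials", "error", "condition"),
                   list(message = "no error trials to decode",
                        call = sys.call())))
  }
  f <- factor(labels)
  idx_c <- which(correct)
  idx_e <- which(!correct)
  res_c <- locv_decode(trial_spikes[idx_c], f[idx_c], window, bin_width,
                       min_trials, seed = seed)
  # fixed templates: class-mean PSTHs over all correct trials
  Xc <- bin_trials(trial_spikes[idx_c], window, bin_width)
  cls_c <- as.integer(factor(f[idx_c], levels = levels(f)))
  M <- rowsum(Xc, cls_c, reorder = TRUE) / tabulate(cls_c, nlevels(f))
  Xe <- bin_trials(trial_spikes[idx_e], window, bin_width)
  d2 <- outer(rowSums(Xe * Xe), rowSums(M * M), "+") - 2 * (Xe %*% t(M))
  d2[d2 < 0] <- 0
  est_e <- with_seed(seed, {
    apply(sqrt(d2), 1, argmin_random_tie)
  })
  est_e <- factor(levels(f)[est_e], levels = levels(f))
  structure(list(correct = res_c,
                 error_percent_correct = 100 * mean(est_e == f[idx_e]),
                 error_estimates = est_e, n_error = length(idx_e)),
            class = "error_trial_result")
}
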