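TRIAL_REQUIRED_COLS <- c("trial_id", "vowel", "choice", "correct",
                         "response_time", "trial_type")
SPIKE_REQUIRED_COLS <- c("unit_id", "trial_id", "spike_time_s")

#' Read and write trial tables
#'
#' Trial tables are stored as plain CSV with one row per trial. Times are in
#' seconds from first-token onset, levels in dB; unknown columns are
#' preserved. Required columns: trial_id, vowel, choice, correct,
#' response_time, trial_type.
#'
#' @param path file path.
#' @return \code{read_trials}: a trial table data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) warning("empty trial table: ", path, call. = FALSE)
  missing <- setdiff(TRIAL_REQUIRED_COLS, names(df))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$correct <- as.logical(df$correct)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @rdname read_trials
#' @param trials trial table to write.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_REQUIRED_COLS, names(trials))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read and write spike datasets
#'
#' Long-format CSV: unit_id, trial_id, spike_time_s (seconds relative to
#' first-token onset). Spike times are sorted within unit and trial on read.
#'
#' @param path file path.
#' @return \code{read_spikes}: a \code{spike_dataset} data.frame.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SPIKE_REQUIRED_COLS, names(df))
  if (length(missing)) {
    stop("spike table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$unit_id, df$trial_id, df$spike_time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_dataset", "data.frame")
  df
}

#' @rdname read_spikes
#' @param spikes spike dataset to write.
#' @export
write_spikes <- function(spikes, path) {
  missing <- setdiff(SPIKE_REQUIRED_COLS, names(spikes))
  if (length(missing)) {
    stop("spike table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(as.data.frame(spikes)[, SPIKE_REQUIRED_COLS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit). Samples are clipped to [-1, 1]
#' before quantization.
#'
#' @param w a \code{waveform}.
#' @param path output path.
#' @export
write_wav <- function(w, path) {
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  fs <- as.integer(w$sample_rate)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path input path.
#' @return A \code{waveform}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fs <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found",
                                               call. = FALSE)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = size - 8)
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only 16-bit mono PCM supported", call. = FALSE)
      }
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size %/% 2, size = 2,
                     endian = "little")
      return(new_waveform(pcm / 32767, fs))
    } else {
      readBin(con, raw(), n = size)
    }
  }
}

#' Run the full analysis pipeline on a simulated or loaded dataset
#'
#' Sequence: sound-responsiveness filter, per-unit optimized decoding with
#' permutation significance for the target and orthogonal features, timing
#' comparison of best-window centers, matched vowel/choice/accuracy decoding,
#' and population decoding at increasing population sizes. Intended for
#' desk-scale runs; the `analysis/` scripts drive the same functions with
#' narrative output.
#'
#' @param trials a trial table.
#' @param spikes a \code{spike_dataset}.
#' @param target target feature column (default "vowel").
#' @param orthogonal orthogonal feature column (default "f0").
#' @param grid window grid.
#' @param bin_width decoder bin width in seconds.
#' @param n_shuffles permutation shuffles per unit.
#' @param pop_sizes population sizes to test.
#' @param n_combos combinations per population size.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list: units (per-unit summary data.frame), timing
#'   (\code{timing_comparison} of dual-feature center times, or NULL),
#'   population (data.frame of size, combo, percent_correct).
#' @export
run_pipeline <- function(trials, spikes, target = "vowel",
                         orthogonal = "f0", grid = make_window_grid(),
                         bin_width = 0.01, n_shuffles = 100,
                         pop_sizes = c(1, 2, 5, 10), n_combos = 10,
                         seed = 1) {
  unit_ids <- unique(spikes$unit_id)
  rows <- list()
  keep_spikes <- list()
  for (i in seq_along(unit_ids)) {
    uid <- unit_ids[i]
    ts <- spikes_by_trial(spikes, trials, uid)
    resp <- classify_sound_responsive(ts)
    if (!resp$responsive) next
    sig_t <- unit_significance(ts, trials[[target]], grid, bin_width,
                               n_shuffles, seed = seed + 13 * i)
    sig_o <- unit_significance(ts, trials[[orthogonal]], grid, bin_width,
                               n_shuffles, seed = seed + 13 * i + 1)
    keep_spikes[[uid]] <- ts
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = uid,
      target_performance = sig_t$observed, target_p = sig_t$p,
      target_informative = sig_t$informative,
      target_center = center_time(sig_t$best_window),
      orth_performance = sig_o$observed, orth_p = sig_o$p,
      orth_informative = sig_o$informative,
      orth_center = center_time(sig_o$best_window),
      stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, rows)
  timing <- NULL
  if (!is.null(units)) {
    dual <- units$target_informative & units$orth_informative
    if (sum(dual) >= 3) {
      timing <- compare_timing(
        list(target = units$target_center[dual],
             orthogonal = units$orth_center[dual]), paired = TRUE)
    }
  }
  pop <- NULL
  if (!is.null(units) && nrow(units) > 0) {
    ranked <- units$unit_id[order(-units$target_performance)]
    pop_rows <- list()
    for (size in pop_sizes[pop_sizes <= length(ranked)]) {
      combos <- sample_populations(ranked, size, n_combos,
                                   seed = seed + size)
      for (ci in seq_along(combos)) {
        pd <- population_decode(keep_spikes[combos[[ci]]],
                                trials[[target]],
                                min_trials = 2, seed = seed + 1000 + ci)
        pop_rows[[length(pop_rows) + 1L]] <- data.frame(
          size = size, combo = ci, percent_correct = pd$percent_correct)
      }
    }
    pop <- do.call(rbind, pop_rows)
  }
  list(units = units, timing = timing, population = pop)
}
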