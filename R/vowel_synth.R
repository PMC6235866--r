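#' Vowel specification
#'
#' Describes an artificial vowel as four parallel formant resonances excited by
#' either a glottal click train (voiced) or broadband noise (whispered).
#' Formant frequencies and bandwidths for the four vowels used in the ferret
#' discrimination task are available through \code{\link{vowel_table}}.
#'
#' @param name vowel label, e.g. "u", "e", "a", "i".
#' @param formants four formant center frequencies F1-F4 in Hz, strictly
#'   increasing.
#' @param bandwidths four formant bandwidths in Hz, all positive.
#' @param f0 fundamental frequency in Hz for voiced vowels, or NA for
#'   whispered vowels.
#' @param duration token duration in seconds.
#' @param level presentation level in dB SPL under the digital convention
#'   (see \code{\link{set_level}}).
#' @param sample_rate sample rate in Hz; must be at least twice F4.
#' @return An object of class \code{vowel_spec}.
#' @examples
#' spec <- vowel_spec("u", formants = c(460, 1105, 2857, 4205),
#'                    bandwidths = c(80, 70, 160, 300), f0 = 200)
#' @export
vowel_spec <- function(name, formants, bandwidths, f0 = NA_real_,
                       duration = 0.25, level = 70, sample_rate = 48000) {
  if (length(formants) != 4L || any(!is.finite(formants)) ||
      any(diff(formants) <= 0)) {
    stop("'formants' must be four strictly increasing finite frequencies",
         call. = FALSE)
  }
  if (length(bandwidths) != 4L || any(!is.finite(bandwidths)) ||
      any(bandwidths <= 0)) {
    stop("'bandwidths' must be four positive values", call. = FALSE)
  }
  stopifnot_scalar(duration, "duration")
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  voiced <- !is.na(f0)
  if (voiced && f0 <= 0) stop("voiced vowel requires f0 > 0", call. = FALSE)
  if (sample_rate < 2 * formants[4]) {
    stop("'sample_rate' must be at least twice F4", call. = FALSE)
  }
  structure(list(name = name, formants = as.numeric(formants),
                 bandwidths = as.numeric(bandwidths),
                 f0 = as.numeric(f0), voiced = voiced,
                 duration = duration, level = level,
                 sample_rate = sample_rate),
            class = "vowel_spec")
}

#' Formant table for the task vowels
#'
#' Formant center frequencies (Hz) for /u/, /e/ (epsilon), /a/ and /i/ with
#' the shared bandwidths 80, 70, 160 and 300 Hz (F1-F4).
#'
#' @return data.frame with columns vowel, F1..F4, BW1..BW4.
#' @export
vowel_table <- function() {
  data.frame(
    vowel = c("u", "e", "a", "i"),
    F1 = c(460, 730, 936, 437),
    F2 = c(1105, 2058, 1551, 2761),
    F3 = c(2857, 2857, 2975, 2975),
    F4 = c(4205, 4205, 4263, 4263),
    BW1 = 80, BW2 = 70, BW3 = 160, BW4 = 300,
    stringsAsFactors = FALSE
  )
}

#' Look up a task vowel by name
#'
#' @inheritParams vowel_spec
#' @param vowel one of "u", "e", "a", "i".
#' @return A \code{\link{vowel_spec}}.
#' @export
task_vowel <- function(vowel, f0 = 200, duration = 0.25, level = 70,
                       sample_rate = 48000) {
  tab <- vowel_table()
  row <- tab[tab$vowel == vowel, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown vowel '%s'; expected one of %s", vowel,
                 paste(tab$vowel, collapse = ", ")), call. = FALSE)
  }
  vowel_spec(vowel, formants = unlist(row[, c("F1", "F2", "F3", "F4")]),
             bandwidths = unlist(row[, c("BW1", "BW2", "BW3", "BW4")]),
             f0 = f0, duration = duration, level = level,
             sample_rate = sample_rate)
}

new_waveform <- function(samples, sample_rate) {
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' Glottal source: click train or broadband noise
#'
#' Voiced sources are unit impulse trains with period
#' \code{round(sample_rate / f0)} samples starting at the first sample
#' (deterministic phase); whispered sources are zero-mean white Gaussian
#' noise.
#'
#' @param voiced logical; click train if TRUE, noise if FALSE.
#' @param f0 fundamental frequency in Hz (voiced only).
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param seed seed for the noise source.
#' @return A \code{waveform}.
#' @export
make_source <- function(voiced, f0 = NA_real_, duration = 0.25,
                        sample_rate = 48000, seed = NULL) {
  n <- round(duration * sample_rate)
  if (voiced) {
    if (is.na(f0) || f0 <= 0) stop("voiced source requires f0 > 0",
                                   call. = FALSE)
    period <- round(sample_rate / f0)
    x <- numeric(n)
    x[seq(1L, n, by = period)] <- 1
  } else {
    x <- with_seed(seed, stats::rnorm(n))
  }
  new_waveform(x, sample_rate)
}

# frequency response magnitude of one two-pole resonator at frequency f (Hz)
resonator_gain <- function(b0, r, theta, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  Mod(b0 / (1 - 2 * r * cos(theta) / z + r^2 / z^2))
}

#' Parallel formant filter
#'
#' Passes the source through four two-pole resonators in parallel, one per
#' formant. Each resonator has poles at radius \code{exp(-pi * BW / fs)} and
#' angle \code{2 * pi * F / fs}, with its numerator scaled for unity gain at
#' the formant center frequency; the four outputs are summed with equal
#' weights.
#'
#' @param source a \code{waveform} from \code{\link{make_source}}.
#' @param spec a \code{\link{vowel_spec}}; sample rates must match.
#' @return Filtered \code{waveform}.
#' @export
formant_filter <- function(source, spec) {
  fs <- source$sample_rate
  if (fs != spec$sample_rate) {
    stop("source and spec sample rates differ", call. = FALSE)
  }
  if (any(spec$formants >= fs / 2)) {
    stop("formant frequency at or above Nyquist", call. = FALSE)
  }
  out <- numeric(length(source$samples))
  for (j in 1:4) {
    f <- spec$formants[j]
    bw <- spec$bandwidths[j]
    r <- exp(-pi * bw / fs)
    theta <- 2 * pi * f / fs
    # recursive part y[i] = b0*x[i] + a1*y[i-1] + a2*y[i-2]
    a1 <- 2 * r * cos(theta)
    a2 <- -r^2
    b0 <- 1 / resonator_gain(1, r, theta, f, fs)
    y <- stats::filter(b0 * source$samples, filter = c(a1, a2),
                       method = "recursive")
    out <- out + as.numeric(y)
  }
  new_waveform(out, fs)
}

#' Raised-cosine onset/offset ramps
#'
#' Scales the first and last \code{ramp} seconds by half-cosine envelopes so
#' the waveform starts and ends at zero amplitude.
#'
#' @param w a \code{waveform}.
#' @param ramp ramp duration in seconds (default 5 ms); \code{ramp = 0} is the
#'   identity.
#' @return Ramped \code{waveform}.
#' @export
apply_cosine_ramps <- function(w, ramp = 0.005) {
  if (ramp == 0) return(w)
  n <- length(w$samples)
  nr <- round(ramp * w$sample_rate)
  if (2 * nr > n) stop("ramps longer than the waveform", call. = FALSE)
  t <- seq(0, ramp, length.out = nr)
  env <- 0.5 * (1 - cos(pi * t / ramp))
  x <- w$samples
  x[seq_len(nr)] <- x[seq_len(nr)] * env
  x[seq(n - nr + 1L, n)] <- x[seq(n - nr + 1L, n)] * rev(env)
  new_waveform(x, w$sample_rate)
}

#' Set presentation level
#'
#' Physical dB SPL cannot be calibrated in software, so levels follow a fixed
#' digital convention: 70 dB corresponds to an RMS of 0.05 full scale, and
#' every other level is the exact attenuation/gain relative to that reference,
#' \code{rms = 0.05 * 10^((level - 70) / 20)}. Level differences therefore
#' match the printed dB differences exactly.
#'
#' @param w a \code{waveform} with non-zero RMS.
#' @param level target level in dB (digital SPL convention).
#' @param ref_level,ref_rms the convention anchor (70 dB at RMS 0.05).
#' @return Rescaled \code{waveform}.
#' @export
set_level <- function(w, level, ref_level = 70, ref_rms = 0.05) {
  cur <- sqrt(mean(w$samples^2))
  if (cur == 0) stop("cannot set the level of a silent waveform",
                     call. = FALSE)
  target <- ref_rms * 10^((level - ref_level) / 20)
  new_waveform(w$samples * target / cur, w$sample_rate)
}

#' Synthesize one vowel token
#'
#' Full pipeline: source (click train or noise) -> parallel formant filter ->
#' 5 ms cosine ramps -> level scaling.
#'
#' @param spec a \code{\link{vowel_spec}}.
#' @param seed noise seed for whispered vowels.
#' @param ramp ramp duration in seconds.
#' @return A \code{waveform} of exactly \code{spec$duration} seconds.
#' @export
synthesize_vowel <- function(spec, seed = NULL, ramp = 0.005) {
  src <- make_source(spec$voiced, spec$f0, spec$duration, spec$sample_rate,
                     seed = seed)
  w <- formant_filter(src, spec)
  w <- apply_cosine_ramps(w, ramp)
  set_level(w, spec$level)
}

#' Two-token trial stimulus
#'
#' The behavioral stimulus is one vowel token repeated once after a 250 ms
#' silent interval: token + gap + identical token.
#'
#' @param w a single-token \code{waveform}.
#' @param gap silent interval in seconds (default 0.25).
#' @return A \code{waveform}; 0.75 s for a 0.25 s token.
#' @export
two_token_stimulus <- function(w, gap = 0.25) {
  silence <- numeric(round(gap * w$sample_rate))
  new_waveform(c(w$samples, silence, w$samples), w$sample_rate)
}

#' Smoothed spectral envelope
#'
#' Helper for checking formant peaks: the FFT power spectrum smoothed with a
#' moving average wide enough to bridge the harmonic line spacing of voiced
#' sounds, returned in dB.
#'
#' @param w a \code{waveform}.
#' @param smooth_hz smoothing width in Hz; for voiced vowels use at least the
#'   fundamental frequency.
#' @return data.frame with columns freq (Hz) and level_db.
#' @export
spectral_envelope <- function(w, smooth_hz = 250) {
  n <- length(w$samples)
  pow <- Mod(stats::fft(w$samples))[seq_len(n %/% 2)]^2
  freq <- (seq_len(n %/% 2) - 1) * w$sample_rate / n
  k <- max(1L, round(smooth_hz / (w$sample_rate / n)))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(pow, rep(1 / k, k), sides = 2)
  keep <- !is.na(sm) & sm > 0
  data.frame(freq = freq[keep], level_db = 10 * log10(as.numeric(sm[keep])))
}

#' Magnitude response of the parallel formant filter
#'
#' Evaluates the summed complex frequency response of the four resonators at
#' the requested frequencies — the deterministic spectral envelope the filter
#' imposes, free of source structure.
#'
#' @param spec a \code{\link{vowel_spec}}.
#' @param freq frequencies in Hz.
#' @return numeric vector of magnitudes (linear).
#' @export
formant_filter_response <- function(spec, freq) {
  fs <- spec$sample_rate
  z <- exp(1i * 2 * pi * freq / fs)
  H <- 0 + 0i
  for (j in 1:4) {
    r <- exp(-pi * spec$bandwidths[j] / fs)
    theta <- 2 * pi * spec$formants[j] / fs
    b0 <- 1 / resonator_gain(1, r, theta, spec$formants[j], fs)
    H <- H + b0 / (1 - 2 * r * cos(theta) / z + r^2 / z^2)
  }
  Mod(H)
}
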