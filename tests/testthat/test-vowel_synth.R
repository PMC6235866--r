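test_that("voiced source is a click train with the exact period", {
  fs <- 48000
  w <- make_source(TRUE, f0 = 200, duration = 0.25, sample_rate = fs)
  expect_equal(sum(w$samples), 50)  # duration * f0 impulses
  expect_true(all(w$samples %in% c(0, 1)))

  w149 <- make_source(TRUE, f0 = 149, duration = 0.25, sample_rate = fs)
  gaps <- diff(which(w149$samples == 1))
  expect_true(all(gaps == round(fs / 149)))

  expect_error(make_source(TRUE, f0 = 0), "f0")
})

test_that("whispered source is zero-mean white noise", {
  w <- make_source(FALSE, duration = 0.25, sample_rate = 48000, seed = 7)
  x <- w$samples
  expect_lt(abs(mean(x)), 0.05)
  lag <- round(0.005 * 48000)
  r <- cor(x[-(1:lag)], x[1:(length(x) - lag)])
  expect_lt(abs(r), 0.05)
  # seeded: reproducible
  w2 <- make_source(FALSE, duration = 0.25, sample_rate = 48000, seed = 7)
  expect_identical(w$samples, w2$samples)
})

test_that("formant filter puts envelope peaks at the specified formants", {
  freq <- seq(100, 6000, by = 2)
  for (v in vowel_table()$vowel) {
    spec <- task_vowel(v)
    H <- formant_filter_response(spec, freq)
    for (f in spec$formants) {
      near <- abs(freq - f) < 200
      pk <- freq[near][which.max(H[near])]
      # parallel resonator interference shifts peaks by at most a few bins
      expect_lt(abs(pk - f), 25)
    }
  }
})

test_that("voiced vowel spectral envelope peaks near each formant", {
  spec <- task_vowel("u", f0 = 200)
  env <- spectral_envelope(synthesize_vowel(spec), smooth_hz = 250)
  for (f in spec$formants) {
    near <- abs(env$freq - f) < 300
    pk <- env$freq[near][which.max(env$level_db[near])]
    expect_lt(abs(pk - f), 250)  # within one smoothing bin
  }
})

test_that("resonator -3 dB widths follow the specified bandwidths", {
  # widely separated formants isolate each resonance
  spec <- vowel_spec("x", formants = c(500, 2000, 5000, 9000),
                     bandwidths = c(80, 70, 160, 300), f0 = 200,
                     sample_rate = 48000)
  freq <- seq(100, 10000, by = 1)
  H <- formant_filter_response(spec, freq)
  width_at <- function(f) {
    near <- which(abs(freq - f) < 400)
    pk <- near[which.max(H[near])]
    half <- H[pk] / sqrt(2)
    lo <- pk; while (lo > 1 && H[lo] > half) lo <- lo - 1
    hi <- pk; while (hi < length(H) && H[hi] > half) hi <- hi + 1
    freq[hi] - freq[lo]
  }
  expect_equal(width_at(500), 80, tolerance = 0.15)
  expect_equal(width_at(2000), 70, tolerance = 0.15)
  # F1 peak wider than F2 peak with the task bandwidths (80 vs 70 Hz)
  specu <- task_vowel("u")
  frequ <- seq(100, 5000, by = 1)
  Hu <- formant_filter_response(specu, frequ)
  wu <- vapply(specu$formants[1:2], function(f) {
    near <- which(abs(frequ - f) < 300)
    pk <- near[which.max(Hu[near])]
    half <- Hu[pk] / sqrt(2)
    lo <- pk; while (lo > 1 && Hu[lo] > half) lo <- lo - 1
    hi <- pk; while (hi < length(Hu) && Hu[hi] > half) hi <- hi + 1
    frequ[hi] - frequ[lo]
  }, numeric(1))
  expect_gt(wu[1], wu[2])
})

test_that("voiced vowel energy is concentrated at harmonics of F0", {
  fs <- 48000
  spec <- task_vowel("u", f0 = 200)  # period 240 samples, integer cycles
  w <- synthesize_vowel(spec)
  n <- length(w$samples)
  pow <- Mod(stats::fft(w$samples))[2:(n %/% 2)]^2
  freq <- (1:(n %/% 2 - 1)) * fs / n
  harmonic <- abs(freq / 200 - round(freq / 200)) * 200 < 2 * fs / n
  expect_gt(sum(pow[harmonic]) / sum(pow), 0.9)
})

test_that("cosine ramps zero the endpoints and pass the midpoint at half", {
  fs <- 48000
  w <- new_w <- vowelconstancy:::new_waveform(rep(1, fs %/% 4), fs)
  r <- apply_cosine_ramps(w, ramp = 0.005)
  expect_equal(r$samples[1], 0)
  expect_equal(r$samples[length(r$samples)], 0)
  mid <- round(0.0025 * fs)
  expect_equal(r$samples[mid], 0.5, tolerance = 0.01)
  # interior untouched
  expect_equal(r$samples[round(0.1 * fs)], 1)
  expect_identical(apply_cosine_ramps(w, 0), w)
  expect_error(apply_cosine_ramps(w, ramp = 0.2), "ramps")
})

test_that("set_level follows the digital SPL convention and is linear", {
  fs <- 48000
  w <- vowelconstancy:::new_waveform(sin(2 * pi * 1000 * (0:11999) / fs), fs)
  rms <- function(x) sqrt(mean(x$samples^2))
  w70 <- set_level(w, 70)
  expect_equal(rms(w70), 0.05)
  expect_equal(rms(set_level(w, 70)), rms(set_level(w70, 70)))
  expect_equal(rms(set_level(w, 50)), 0.05 * 0.1)
  ladder <- vapply(seq(45, 82.5, by = 7.5),
                   function(l) rms(set_level(w, l)), numeric(1))
  expect_true(all(diff(ladder) > 0))
  # level linearity: re-leveling overrides the previous level
  expect_equal(rms(set_level(set_level(w, 45), 60)),
               rms(set_level(w, 60)))
  silent <- vowelconstancy:::new_waveform(numeric(100), fs)
  expect_error(set_level(silent, 70), "silent")
})

test_that("two-token stimulus is token + 250 ms gap + identical token", {
  spec <- task_vowel("e", f0 = 149)
  w <- synthesize_vowel(spec, seed = 3)
  s <- two_token_stimulus(w)
  fs <- w$sample_rate
  expect_equal(length(s$samples), 3 * length(w$samples))
  n <- length(w$samples)
  expect_true(all(s$samples[(n + 1):(2 * n)] == 0))
  expect_identical(s$samples[(2 * n + 1):(3 * n)], s$samples[1:n])
})

test_that("vowel specs validate their invariants", {
  expect_error(vowel_spec("x", c(500, 400, 3000, 4000), rep(100, 4)),
               "increasing")
  expect_error(vowel_spec("x", c(500, 1000, 3000, 4000), c(100, -1, 5, 5)),
               "positive")
  expect_error(vowel_spec("x", c(500, 1000, 3000, 4000), rep(100, 4),
                          f0 = -5), "f0")
  expect_error(vowel_spec("x", c(500, 1000, 3000, 25000), rep(100, 4)),
               "twice F4")
  expect_error(task_vowel("q"), "unknown vowel")
})
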