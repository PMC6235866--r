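test_that("confidence weights follow the distance-ratio rule and its bounds", {
  expect_equal(confidence_weight(c(1, 1))$w, 0.5)   # equidistant: 1 - 1/n
  expect_equal(confidence_weight(c(0, 5))$w, 1)     # exact match
  w13 <- confidence_weight(c(1, 3))
  expect_equal(w13$w, 0.75)
  expect_equal(w13$estimate, 1)
  # bounds 1 - 1/n <= w <= 1 for arbitrary non-negative distances
  set.seed(1)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    d <- rexp(n)
    est <- confidence_weight(d)
    expect_gte(est$w, 1 - 1 / n)
    expect_lte(est$w, 1)
  }
  # all-equal distances pin w to the floor exactly
  expect_equal(confidence_weight(rep(2.5, 4))$w, 1 - 1 / 4)
  # degenerate all-zero distances: floor weight, seeded tie-break
  z <- confidence_weight(c(0, 0, 0), seed = 2)
  expect_equal(z$w, 1 - 1 / 3)
  expect_error(confidence_weight(5), "two classes")
  expect_error(confidence_weight(c(-1, 2)), "non-negative")
})

test_that("a population of one decodes exactly as that unit", {
  fx <- tuned_unit_fixture(gain = 30, n_per_vowel = 10, seed = 3)
  win <- decoding_window(0, 0.1)
  single <- locv_decode(fx$spikes, fx$trials$vowel, win, bin_width = 0.1,
                        min_trials = 8, seed = 4)
  pop <- population_decode(list(fx$spikes), fx$trials$vowel, win, seed = 4)
  expect_equal(pop$percent_correct, single$percent_correct)
  expect_identical(as.character(pop$estimates),
                   as.character(single$estimates))
  # identical copies of the unit vote identically: same result
  pop3 <- population_decode(rep(list(fx$spikes), 3), fx$trials$vowel, win,
                            seed = 4)
  expect_equal(pop3$percent_correct, single$percent_correct)
})

test_that("population decoding matches a brute-force weighted vote", {
  set.seed(5)
  # three units with distinct, tie-free responses over 2 x 9 trials
  labels <- rep(c("u", "e"), each = 9)
  units <- lapply(1:3, function(u) {
    lapply(seq_along(labels), function(i) {
      rate <- if (labels[i] == "u") 3 + u else 8 + u
      sort(runif(rpois(1, rate) + 1, 0, 0.1))
    })
  })
  win <- decoding_window(0, 0.1)
  pd <- population_decode(units, labels, win, min_trials = 8, seed = 6)
  expect_equal(pd$percent_correct,
               brute_population_percent(units, labels, win))
  # weight sums must respect the per-unit bound: <= n_units, >= 0
  expect_true(all(pd$weight_sums >= 0))
  expect_true(all(rowSums(pd$weight_sums) <= 3))
})

test_that("the higher-confidence correct vote outweighs a wrong vote", {
  labels <- rep(c("u", "e"), each = 8)
  spk <- function(k) if (k == 0) numeric(0) else
    seq(0.005, by = 0.01, length.out = k)
  # strong unit: perfectly separated counts, votes correctly with w = 1
  strong <- lapply(labels, function(l) if (l == "u") spk(10) else spk(0))
  # weak unit: "u" counts alternate 0/10 while "e" counts sit at 4; the
  # zero-count "u" trials land nearer the "e" template (leave-one-out "u"
  # template ~5.7) — wrong votes, but with w < 1
  weak <- vector("list", length(labels))
  weak[labels == "u"] <- lapply(rep(c(0, 10), 4), spk)
  weak[labels == "e"] <- lapply(rep(4, 8), spk)
  win <- decoding_window(0, 0.1)
  wrong_alone <- population_decode(list(weak), labels, win, seed = 7)
  expect_equal(wrong_alone$percent_correct, 75)  # zero-count "u" trials wrong
  pd <- population_decode(list(strong, weak), labels, win, seed = 7)
  expect_equal(pd$percent_correct, 100)
})

test_that("population sampling is unique, seeded and bounded by the pool", {
  pool <- paste0("u", 1:5)
  combos <- sample_populations(pool, 2, n_combos = 100, seed = 8)
  expect_equal(length(combos), 10)  # choose(5, 2): pool permits only 10
  expect_equal(length(unique(vapply(combos, paste, "", collapse = "|"))),
               10)
  expect_identical(sample_populations(pool, 2, 5, seed = 9),
                   sample_populations(pool, 2, 5, seed = 9))
  expect_equal(sample_populations(pool, 5, 3, seed = 10),
               list(pool))
  expect_error(sample_populations(pool, 6), "pool size")
})

test_that("roving curves localize the informative epoch", {
  fx <- tuned_unit_fixture(gain = 60, latency = 0.0, duration = 0.1,
                           baseline = 5, n_per_vowel = 15, seed = 11)
  units <- rep(list(fx$spikes), 5)
  curve <- roving_population_curve(units, fx$trials$vowel, t_min = -0.2,
                                   t_max = 0.5, seed = 12)
  expect_equal(curve$peak_performance,
               max(curve$curve$percent_correct))
  expect_equal(curve$peak_time,
               curve$curve$center[which.max(curve$curve$percent_correct)])
  # peak near the onset kernel
  expect_lt(abs(curve$peak_time - 0.05), 0.15)
  # flat null population stays near chance
  nullu <- poisson_unit_fixture(rate = 15, n_trials = 30, seed = 13)
  nc <- roving_population_curve(rep(list(nullu$spikes), 3),
                                rep(c("u", "e"), 15), t_min = -0.2,
                                t_max = 0.5, seed = 14)
  expect_lt(mean(nc$curve$percent_correct), 70)
  expect_gt(mean(nc$curve$percent_correct), 30)
})

test_that("dimension timing permutation is calibrated and powered", {
  set.seed(15)
  same <- rnorm(40, 0.2, 0.05)
  res_same <- dimension_timing_permutation(c(same, same),
                                           rep(c("f0", "level"), each = 40),
                                           n_iter = 2000, seed = 16)
  expect_gt(res_same$p, 0.2)
  shifted <- c(rnorm(40, 0.1, 0.02), rnorm(40, 0.5, 0.02))
  res_shift <- dimension_timing_permutation(shifted,
                                            rep(c("f0", "voicing"),
                                                each = 40),
                                            n_iter = 2000, seed = 17)
  expect_lte(res_shift$p, 1e-3)
  expect_equal(res_shift$observed_diff, -0.4, tolerance = 0.05)
  # three dimensions: one row per pair
  res3 <- dimension_timing_permutation(rnorm(60), rep(letters[1:3], 20),
                                       n_iter = 200, seed = 18)
  expect_equal(nrow(res3), 3)
})
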