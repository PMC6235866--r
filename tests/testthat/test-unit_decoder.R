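test_that("bin_window_response uses half-open bins tiling the window", {
  w <- decoding_window(0, 0.2)
  expect_equal(bin_window_response(c(0.05, 0.15), w, 0.1), c(1, 1))
  expect_equal(bin_window_response(numeric(0), w, 0.1), c(0, 0))
  expect_equal(bin_window_response(0.2, w, 0.1), c(0, 0))   # end excluded
  expect_equal(bin_window_response(0.0, w, 0.1), c(1, 0))   # start included
  expect_length(bin_window_response(numeric(0), decoding_window(0, 0.35),
                                    0.01), 35)
})

test_that("window grid arithmetic matches the stated counts", {
  expect_equal(nrow(make_window_grid()), 1550)              # 31 x 50
  expect_equal(nrow(make_window_grid(start_step = 0.1)), 800)  # 16 x 50
  g1 <- make_window_grid(0, 0, 0.1, 0.1, 0.1, 0.1)
  expect_equal(nrow(g1), 1)
  g <- make_window_grid()
  expect_equal(g$center, g$start + g$duration / 2)
  # lexicographic (start, duration) ordering for the tie-break convention
  expect_true(!is.unsorted(g$start))
  expect_true(all(diff(g$duration)[diff(g$start) == 0] > 0))
})

test_that("locv_decode matches brute-force enumeration of all distances", {
  win <- decoding_window(0, 0.3)
  set.seed(42)
  for (case in 1:8) {
    n_classes <- sample(2:3, 1)
    n_per <- sample(3:4, 1)
    bw <- sample(c(0.1, 0.15, 0.3), 1)  # 3, 2 or 1 bins
    spikes <- replicate(n_classes * n_per, {
      sort(runif(rpois(1, 4), 0, 0.3))
    }, simplify = FALSE)
    labels <- rep(letters[1:n_classes], each = n_per)
    res <- locv_decode(spikes, labels, win, bin_width = bw, min_trials = 3,
                       seed = 1)
    oracle <- brute_locv_distances(spikes, labels, win, bw)
    expect_equal(unname(res$distances), oracle, tolerance = 1e-10)
    # where the oracle has a unique minimum the estimates must agree
    unique_min <- apply(oracle, 1, function(d) sum(d == min(d)) == 1)
    expect_identical(as.integer(res$estimates)[unique_min],
                     apply(oracle, 1, which.min)[unique_min])
  }
})

test_that("perfectly separated classes decode at 100%", {
  toy <- noiseless_two_class(4)
  res <- locv_decode(toy$spikes, toy$labels, decoding_window(0, 0.2),
                     min_trials = 4)
  expect_equal(res$percent_correct, 100)
  expect_equal(sum(res$confusion), 8)
  expect_equal(unname(rowSums(res$confusion)), res$n_per_class)
})

test_that("label shuffling yields chance performance", {
  fx <- poisson_unit_fixture(rate = 15, n_trials = 100, n_classes = 2,
                             seed = 10)
  win <- decoding_window(0, 0.25)
  set.seed(11)
  pc2 <- replicate(60, locv_decode(fx$spikes, sample(fx$labels),
                                   win)$percent_correct)
  expect_equal(mean(pc2), 50, tolerance = 0.06)

  fx5 <- poisson_unit_fixture(rate = 15, n_trials = 100, n_classes = 5,
                              seed = 12)
  set.seed(13)
  pc5 <- replicate(60, locv_decode(fx5$spikes, sample(fx5$labels),
                                   win)$percent_correct)
  expect_equal(mean(pc5), 20, tolerance = 0.15)
})

test_that("decoding is reproducible bit-for-bit given a seed", {
  fx <- poisson_unit_fixture(rate = 5, n_trials = 20, seed = 14)
  win <- decoding_window(0, 0.05)  # sparse counts force ties
  r1 <- locv_decode(fx$spikes, fx$labels, win, seed = 99)
  r2 <- locv_decode(fx$spikes, fx$labels, win, seed = 99)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$percent_correct, r2$percent_correct)
})

test_that("class floors are enforced", {
  toy <- noiseless_two_class(4)
  expect_error(locv_decode(toy$spikes, toy$labels, decoding_window(0, 0.1)),
               "insufficient data")
  expect_error(locv_decode(toy$spikes[1:7], toy$labels[1:7],
                           decoding_window(0, 0.1), min_trials = 4),
               "'b' has 3")
})

test_that("decode_surface reports the max and breaks ties lexicographically", {
  toy <- noiseless_two_class(3)  # dense spikes: every window decodes at 100%
  grid <- make_window_grid(-0.2, 0.2, 0.1, 0.1, 0.3, 0.1)
  surf <- decode_surface(toy$spikes, toy$labels, grid, min_trials = 3,
                         seed = 1)
  expect_equal(surf$best_performance, max(surf$surface$percent_correct))
  expect_true(all(surf$surface$percent_correct == 100))
  expect_equal(surf$best_window$start, -0.2)  # earliest start
  expect_equal(surf$best_window$duration, 0.1)  # shortest duration
})

test_that("best window localizes an onset kernel", {
  fx <- tuned_unit_fixture(gain = 60, latency = 0.0, duration = 0.1,
                           baseline = 5, seed = 20)
  grid <- make_window_grid(-0.4, 0.6, 0.1, 0.1, 0.3, 0.1)
  surf <- decode_surface(fx$spikes, fx$trials$vowel, grid, seed = 2)
  w <- surf$best_window
  expect_true(w$start < 0.1 & w$start + w$duration > 0.0)
  expect_gt(surf$best_performance, 75)
})

test_that("duplicating an informative bin never hurts noiseless decoding", {
  X <- rbind(c(5, 0), c(5, 0), c(5, 0), c(0, 1), c(0, 1), c(0, 1))
  cls <- rep(1:2, each = 3)
  base <- vowelconstancy:::locv_core(X, cls, 2)$percent_correct
  dup <- vowelconstancy:::locv_core(cbind(X, X[, 1]), cls,
                                    2)$percent_correct
  expect_gte(dup, base)
})

test_that("sound-responsiveness uses a paired sign-rank criterion", {
  set.seed(30)
  onset <- replicate(50, c(sort(runif(rpois(1, 3), -0.3, 0)),
                           sort(runif(rpois(1, 9), 0, 0.3))),
                     simplify = FALSE)
  expect_true(classify_sound_responsive(onset)$responsive)
  # identical evoked and baseline counts -> not responsive
  same <- replicate(20, c(-0.1, 0.2), simplify = FALSE)
  res <- classify_sound_responsive(same)
  expect_false(res$responsive)
  expect_equal(res$p, 1)
})
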