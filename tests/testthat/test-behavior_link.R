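# builds a trial table with explicit vowel x choice x outcome cell counts
table_with_cells <- function(counts, level = 70, rt = 2) {
  cells <- expand.grid(vowel = c("u", "e"), choice = c("left", "right"),
                       correct = c(TRUE, FALSE), stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    if (counts[i] == 0) return(NULL)
    data.frame(vowel = cells$vowel[i], choice = cells$choice[i],
               correct = cells$correct[i], f0 = 200, location = 0,
               level = level, voicing = "voiced", response_time = rt,
               trial_type = "test", engagement = "engaged",
               stringsAsFactors = FALSE)[rep(1, counts[i]), ]
  }))
  rows$trial_id <- seq_len(nrow(rows))
  rows
}

test_that("matched datasets are exactly balanced at the minimum cell count", {
  counts <- c(6, 5, 7, 9, 5, 8, 6, 11)
  tt <- table_with_cells(counts)
  m <- build_matched_dataset(tt, seed = 1)
  expect_equal(m$n_per_cell, 5)
  expect_equal(nrow(m$trials), 40)  # 8 cells x 5
  cell <- table(interaction(m$trials$vowel, m$trials$choice,
                            m$trials$correct))
  expect_true(all(cell == 5))
  # outcome balance makes behavioral percent correct exactly 50
  expect_equal(100 * mean(m$trials$correct), 50)
})

test_that("an already balanced table is retained in full", {
  tt <- table_with_cells(rep(6, 8))
  m <- build_matched_dataset(tt, seed = 2)
  expect_equal(sort(m$trial_ids), tt$trial_id)
})

test_that("the N >= 5 floor names the limiting cell", {
  counts <- c(6, 5, 7, 9, 4, 8, 6, 11)
  expect_error(build_matched_dataset(table_with_cells(counts), seed = 3),
               "4 trials \\(minimum 5\\)")
})

test_that("exclusion rules remove whispered, quiet and fast-response trials", {
  # rows 1-8 are cell 1, 9-16 cell 2, ...: spread exclusions across cells
  tt <- table_with_cells(rep(8, 8))
  tt$voicing[1:2] <- "whispered"
  tt$level[9:10] <- 55
  tt$response_time[17:18] <- 0.4
  tt$trial_type[25] <- "correction"
  m <- build_matched_dataset(tt, level_floor = 60, seed = 4)
  expect_equal(unname(m$exclusions["whispered"]), 2)
  expect_equal(unname(m$exclusions["level"]), 2)
  expect_equal(unname(m$exclusions["fast_response"]), 2)
  expect_equal(unname(m$exclusions["correction"]), 1)
  expect_equal(m$n_per_cell, 6)
  expect_true(all(!m$trial_ids %in% c(1:2, 9:10, 17:18, 25)))
  # second-token anchoring shifts the response-time cut by 0.5 s
  tt2 <- table_with_cells(rep(8, 8), rt = 1.2)
  expect_error(build_matched_dataset(tt2, rt_anchor = "second_token"),
               "insufficient data")
})

test_that("subsampling is seeded but N is seed-invariant", {
  tt <- table_with_cells(c(10, 9, 8, 12, 7, 9, 10, 8))
  m1 <- build_matched_dataset(tt, seed = 5)
  m2 <- build_matched_dataset(tt, seed = 5)
  m3 <- build_matched_dataset(tt, seed = 6)
  expect_identical(m1$trial_ids, m2$trial_ids)
  expect_false(identical(m1$trial_ids, m3$trial_ids))
  expect_equal(m1$n_per_cell, m3$n_per_cell)
})

test_that("matched decoding separates stimulus from choice units", {
  # trials with decorrelated vowel/choice/outcome (balanced by design)
  tt <- table_with_cells(rep(8, 8))
  m <- build_matched_dataset(tt, seed = 7)
  grid <- make_window_grid(0, 0.2, 0.1, 0.1, 0.3, 0.1)
  stim_unit <- unit_tuning(5, kernels = list(
    list(feature = "vowel", latency = 0.0, duration = 0.15,
         gain = c(u = 60, e = 0))))
  choice_unit <- unit_tuning(5, kernels = list(
    list(feature = "choice", latency = 0.3, duration = 0.2,
         gain = c(left = 60, right = 0))))
  ds <- generate_dataset(list(stim = stim_unit, choice = choice_unit),
                         m$trials, seed = 8)
  res_s <- decode_sound_choice_accuracy(m, ds, "stim", grid,
                                        n_shuffles = 30, seed = 9)
  expect_true(res_s$sound$informative)
  expect_false(res_s$choice$informative)
  expect_false(res_s$accuracy$informative)
  res_c <- decode_sound_choice_accuracy(m, ds, "choice", grid,
                                        n_shuffles = 30, seed = 10)
  expect_false(res_c$sound$informative)
  expect_true(res_c$choice$informative)
})

test_that("error trials reveal choice coding as below-chance vowel decoding", {
  # 30 correct + 10 error trials; on errors choice is anti-correlated with
  # the vowel, so a pure choice unit mis-decodes vowels on errors
  tt <- table_with_cells(c(15, 0, 0, 15, 0, 5, 5, 0))
  win <- decoding_window(0.0, 0.3)
  choice_unit <- unit_tuning(5, kernels = list(
    list(feature = "choice", latency = 0.05, duration = 0.2,
         gain = c(left = 80, right = 0))))
  stim_unit <- unit_tuning(5, kernels = list(
    list(feature = "vowel", latency = 0.05, duration = 0.2,
         gain = c(u = 80, e = 0))))
  ds <- generate_dataset(list(ch = choice_unit, st = stim_unit), tt,
                         seed = 11)
  ch <- error_trial_decode(spikes_by_trial(ds, tt, "ch"), tt$vowel,
                           tt$correct, win, seed = 12)
  expect_lt(ch$error_percent_correct, 35)  # well below 50% chance
  expect_gt(ch$correct$percent_correct, 75)
  st <- error_trial_decode(spikes_by_trial(ds, tt, "st"), tt$vowel,
                           tt$correct, win, seed = 13)
  expect_gt(st$error_percent_correct, 75)
  expect_equal(st$n_error, 10)
  # no-errors signal
  ttc <- table_with_cells(c(15, 0, 0, 15, 0, 0, 0, 0))
  expect_error(error_trial_decode(spikes_by_trial(ds, ttc, "st"), ttc$vowel,
                                  ttc$correct, win),
               class = "no_error_trials")
})
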