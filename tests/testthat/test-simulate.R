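test_that("degenerate parameters give an event-free monotone staircase", {
  p <- group_preset("tdc", regression_prob = 0, blink_rate = 0, noise_sd = 0,
                    seed = 1)
  rec <- simulate_recording(p, text_spec(1, "Arial", 16, 24, 2))
  expect_length(rec$ground_truth$blink_times, 0)
  expect_length(rec$ground_truth$regression_times, 0)
  # the only decreasing stretches are the line-return sweeps: one maximal run
  # of negative first differences per line
  d <- diff(rec$horizontal)
  runs <- rle(d < 0)
  n_lines <- ceiling(24 / p$words_per_line)
  expect_equal(sum(runs$values), n_lines)
  # within lines (outside sweeps) the staircase never decreases
  expect_true(all(d[d < 0] < -0.1))  # every decrease belongs to a large sweep
  # vertical channel is exactly zero without blinks/noise
  expect_equal(rec$vertical, rep(0, length(rec$vertical)))
})

test_that("a fixed seed reproduces the recording bit-identically", {
  p <- group_preset("dyslexia", seed = 99)
  tx <- text_spec(3, "BonvenoCF", 18, 40, 3)
  r1 <- simulate_recording(p, tx)
  r2 <- simulate_recording(p, tx)
  expect_identical(r1$horizontal, r2$horizontal)
  expect_identical(r1$vertical, r2$vertical)
  expect_identical(r1$ground_truth, r2$ground_truth)
})

test_that("injected regressions replay the documented Bernoulli draw", {
  wc <- 200L
  p <- group_preset("tdc", regression_prob = 0.2, seed = 4711)
  rec <- simulate_recording(p, text_spec(1, "Arial", 16, wc, 2))
  # independent replay: the first RNG consumption after seeding is one
  # uniform draw per word; a word is eligible unless it opens a line
  wpl <- p$words_per_line
  n_lines <- ceiling(wc / wpl)
  line_sizes <- c(rep(wpl, n_lines - 1), wc - wpl * (n_lines - 1))
  expected <- withr::with_seed(4711, {
    u <- runif(wc)
    sum(u < 0.2 & sequence(line_sizes) >= 2)
  })
  expect_equal(length(rec$ground_truth$regression_times), expected)
})

test_that("ground-truth event times are increasing and inside the recording", {
  for (seed in c(1, 2, 3)) {
    rec <- simulate_recording(group_preset("dyslexia", seed = seed),
                              text_spec(1, "Arial", 16, 60, 2))
    gt <- rec$ground_truth
    for (times in list(gt$blink_times, gt$regression_times)) {
      expect_true(all(diff(times) > 0))
      expect_true(all(times >= 0 & times <= gt$reading_time))
    }
    expect_equal(gt$reading_time, length(rec$horizontal) / rec$sampling_rate)
  }
})

test_that("simulation rejects invalid parameters", {
  expect_error(sim_params(regression_prob = 1.5), "regression_prob")
  expect_error(sim_params(sampling_rate = 15), "sampling_rate")
  expect_error(sim_params(fixation_duration_mean = Inf), "finite")
  expect_error(sim_params(blink_rate = -1), "non-negative")
  p <- group_preset("tdc")
  expect_error(simulate_recording(p, text_spec(1, "Arial", 16, 4, 2)),
               "words_per_line")
})

test_that("make_dataset yields one recording per subject and text", {
  recs <- make_dataset(2, default_texts(28, word_count = 8), seed = 7)
  expect_length(recs, 2 * 2 * 28)
  groups <- vapply(recs, `[[`, character(1), "group_label")
  expect_equal(unname(table(groups)), c(56, 56), ignore_attr = TRUE)
  expect_error(make_dataset(2, list()), "non-empty")
  # deterministic under seed
  recs2 <- make_dataset(2, default_texts(28, word_count = 8), seed = 7)
  expect_identical(recs[[5]]$horizontal, recs2[[5]]$horizontal)
})

test_that("the dyslexia preset yields more ground-truth regressions per word", {
  texts <- default_texts(2, word_count = 40)
  recs <- make_dataset(10, texts, seed = 31)
  rate <- vapply(recs, function(r) {
    length(r$ground_truth$regression_times) / r$ground_truth$word_count
  }, numeric(1))
  grp <- vapply(recs, `[[`, character(1), "group_label")
  expect_gt(mean(rate[grp == "dyslexia"]), mean(rate[grp == "tdc"]))
})

test_that("mean regression count is monotone in regression probability", {
  tx <- text_spec(1, "Arial", 16, 16, 2)
  mean_count <- vapply(c(0.02, 0.1, 0.3), function(pr) {
    counts <- vapply(1:100, function(i) {
      p <- group_preset("tdc", regression_prob = pr, seed = 5000 + i)
      length(simulate_recording(p, tx)$ground_truth$regression_times)
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  expect_true(all(diff(mean_count) >= 0))
})
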