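test_that("reading time is the marker difference in seconds", {
  rec <- simulate_recording(group_preset("tdc", seed = 1),
                            text_spec(1, "Arial", 16, 24, 2))
  rec$markers <- c(0L, 3000L)
  rec$horizontal <- numeric(3000); rec$vertical <- numeric(3000)
  expect_equal(reading_time(rec), 30)

  rec$markers <- c(500L, 500L)
  expect_error(reading_time(rec), "non-positive")
  expect_error(reading_time(rec, text_index = 2), "marker pair")

  sim <- simulate_recording(group_preset("tdc", seed = 8),
                            text_spec(1, "Arial", 16, 60, 2))
  expect_equal(reading_time(sim), sim$ground_truth$reading_time,
               tolerance = 0.02)
})

test_that("blink detection applies the up-crossing-to-crest latency window", {
  fs <- 100
  expect_equal(nrow(detect_blinks(numeric(2000), fs)), 0)

  # constructed pulse: deterministic low-amplitude baseline sets the robust
  # threshold; a triangular pulse with a known rise time sits far above it
  make_pulse <- function(rise_s, amp = 1) {
    t <- seq(0, 30, by = 1 / fs)
    x <- 0.01 * sin(2 * pi * 1.3 * t)
    i0 <- 1500L
    nr <- round(rise_s * fs)
    x[i0 + seq_len(nr)] <- amp * seq_len(nr) / nr
    x[i0 + nr + seq_len(nr)] <- amp * rev(seq_len(nr)) / nr
    x
  }
  ev <- detect_blinks(make_pulse(0.2), fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "blink")
  expect_lt(abs(ev$peak - ev$onset - 0.2), 0.021)  # one-sample quantisation

  # 600 ms rise violates the 50--400 ms window
  expect_equal(nrow(detect_blinks(make_pulse(0.6), fs)), 0)
  # sub-threshold pulses are never returned
  thr_probe <- detect_blinks(make_pulse(0.2, amp = 0.012), fs)
  expect_equal(nrow(thr_probe), 0)
  expect_error(detect_blinks(make_pulse(0.2), fs = -1), "fs")
})

test_that("blink detector recovers simulated blinks with high precision/recall", {
  tot <- c(tp = 0, fp = 0, fn = 0)
  n_injected <- 0
  for (i in 1:20) {
    p <- group_preset("dyslexia", seed = 1000 + i)
    rec <- simulate_recording(p, text_spec(1, "Arial", 16, 220, 3))
    n_injected <- n_injected + length(rec$ground_truth$blink_times)
    pre <- quiet_preprocess(rec)
    ev <- detect_blinks(pre$vertical, rec$sampling_rate)
    tot <- tot + match_events(ev$peak, rec$ground_truth$blink_times)
  }
  expect_gt(n_injected, 500)
  pr <- precision_recall(tot)
  expect_gte(pr["precision"], 0.95)
  expect_gte(pr["recall"], 0.95)
})

test_that("regression detection ignores forward steps and line sweeps", {
  fs <- 100
  # monotone staircase: no leftward movement, nothing to find
  stair <- rep(seq(0, 7), each = 30) + rnorm(240, 0, 0.01)
  expect_equal(nrow(detect_regressions(stair, fs)), 0)

  # simulator with sweeps only (regression_prob = 0, zero noise): the
  # line-return exclusion must yield zero false positives
  p0 <- group_preset("tdc", regression_prob = 0, noise_sd = 0, seed = 21)
  rec0 <- simulate_recording(p0, text_spec(1, "Arial", 16, 120, 2))
  pre0 <- quiet_preprocess(rec0)
  expect_equal(nrow(detect_regressions(pre0$horizontal, fs)), 0)

  # injected regressions are recovered within +/- 1 event
  for (seed in c(5, 6, 7)) {
    p <- group_preset("tdc", regression_prob = 0.15, seed = seed)
    rec <- simulate_recording(p, text_spec(1, "Arial", 16, 80, 2))
    pre <- quiet_preprocess(rec)
    ev <- detect_regressions(pre$horizontal, fs)
    expect_lte(abs(nrow(ev) - length(rec$ground_truth$regression_times)), 1)
  }
})

test_that("regression detector precision and recall reach 0.9 on default noise", {
  tot <- c(tp = 0, fp = 0, fn = 0)
  for (i in 1:10) {
    p <- group_preset("dyslexia", seed = 3000 + i)
    rec <- simulate_recording(p, text_spec(1, "Arial", 16, 200, 3))
    pre <- quiet_preprocess(rec)
    ev <- detect_regressions(pre$horizontal, rec$sampling_rate)
    tot <- tot + match_events(ev$peak, rec$ground_truth$regression_times,
                              tol = 0.2)
  }
  pr <- precision_recall(tot)
  expect_gte(pr["precision"], 0.9)
  expect_gte(pr["recall"], 0.9)
})

test_that("signal energy is a sum of squares with its invariances", {
  expect_equal(signal_energy(numeric(100)), 0)
  expect_equal(signal_energy(c(1, 2, 3)), 14)
  a <- rnorm(100); b <- rnorm(50)
  expect_equal(signal_energy(c(a, b)), signal_energy(a) + signal_energy(b))
  expect_equal(signal_energy(rev(a)), signal_energy(a))
  expect_equal(signal_energy(-a), signal_energy(a))
  expect_error(signal_energy(c(1, NaN)), "non-finite")
})

test_that("the feature set satisfies its rate identities", {
  recs <- make_dataset(2, default_texts(2, word_count = 40), seed = 13)
  feats <- quiet_features(recs)
  expect_equal(nrow(feats), length(recs))
  expect_true(all(feats$reading_time > 0))
  expect_equal(feats$blink_rate, feats$n_blinks / (feats$reading_time / 60))
  expect_equal(feats$regression_rate, feats$n_regressions / feats$word_count)
  expect_true(all(feats$energy >= 0))
})

test_that("group means separate in the expected direction on default presets", {
  recs <- make_dataset(6, default_texts(1, word_count = 40), seed = 17)
  feats <- quiet_features(recs)
  m <- tapply(feats$reading_time, feats$group, mean)
  expect_gt(m[["dyslexia"]], m[["tdc"]])
  m <- tapply(feats$regression_rate, feats$group, mean)
  expect_gt(m[["dyslexia"]], m[["tdc"]])
  m <- tapply(feats$energy, feats$group, mean)
  expect_gt(m[["dyslexia"]], m[["tdc"]])
})

test_that("group report flags identical groups with a zero t statistic", {
  recs <- make_dataset(3, default_texts(1, word_count = 30), seed = 23)
  feats <- quiet_features(recs)
  tdc <- feats[feats$group == "tdc", ]
  clone <- tdc
  clone$group <- "dyslexia"
  clone$subject <- paste0("D_", clone$subject)
  rep_out <- group_report(rbind(tdc, clone))
  tests <- rep_out$tests
  expect_true(all(abs(tests$t) < 1e-10))
  expect_true(all(tests$p > 0.999))
})

test_that("the type-I error rate of the group test is nominal", {
  presets <- list(dyslexia = group_preset("tdc"), tdc = group_preset("tdc"))
  pvals <- unlist(lapply(1:50, function(s) {
    recs <- make_dataset(5, default_texts(1, word_count = 24),
                         group_presets = presets, seed = 7000 + s)
    feats <- quiet_features(recs)
    tests <- group_report(feats)$tests
    tests$p[tests$unit == "subject"]
  }))
  fp_rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(fp_rate, 0.01)
  expect_lte(fp_rate, 0.12)
})

test_that("single-subject groups are flagged rather than tested", {
  recs <- make_dataset(2, default_texts(1, word_count = 30), seed = 29)
  feats <- quiet_features(recs)
  feats <- feats[feats$subject != "T02", ]  # one control left
  tests <- group_report(feats)$tests
  sub <- tests[tests$unit == "subject", ]
  expect_true(all(sub$flag == "insufficient subjects"))
  expect_true(all(is.na(sub$p)))
})
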