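test_that("band-pass passes in-band tones and removes drift and mains", {
  fs <- 100
  t <- seq(0, 100, by = 1 / fs)
  expect_equal(eog_bandpass(numeric(1000), fs), numeric(1000))

  # 2 Hz tone is in-band: amplitude within 5% after the transient
  y <- eog_bandpass(sin(2 * pi * 2 * t), fs)
  mid <- y[2000:8000]
  expect_lt(abs(max(abs(mid)) - 1), 0.05)
  # dual route: time-domain gain agrees with the transfer function evaluated
  # on the unit circle (zero-phase application squares the magnitude)
  bf <- signal::butter(4, c(0.1, 10) / (fs / 2), type = "pass")
  gain <- function(flt, f_hz, fs) {
    w <- 2 * pi * f_hz / fs
    Mod(sum(flt$b * exp(-1i * w * (seq_along(flt$b) - 1))) /
          sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1))))
  }
  expect_equal(max(abs(mid)), gain(bf, 2, fs)^2, tolerance = 0.02)

  # 0.01 Hz drift of amplitude 10 is suppressed below 1
  yd <- eog_bandpass(10 * sin(2 * pi * 0.01 * t), fs)
  expect_lt(max(abs(yd[2000:8000])), 1)
  expect_lt(10 * gain(bf, 0.01, fs)^2, 0.1)

  # 50 Hz mains (below Nyquist at fs = 256) attenuated by >= 40 dB
  fs2 <- 256
  t2 <- seq(0, 30, by = 1 / fs2)
  y50 <- eog_bandpass(sin(2 * pi * 50 * t2), fs2)
  expect_lt(max(abs(y50[2000:5000])), 10^(-40 / 20))
})

test_that("band-pass rejects too-short signals and bad sampling rates", {
  expect_error(eog_bandpass(numeric(10), 100), "too short")
  expect_error(eog_bandpass(numeric(1000), 15), "fs")
  expect_error(eog_bandpass(c(1, NA, 3, rep(0, 100)), 100), "non-finite")
})

test_that("notch removes its centre frequency and spares the passband", {
  fs <- 256
  t <- seq(0, 20, by = 1 / fs)
  expect_equal(eog_notch(numeric(1000), fs), numeric(1000))
  rms <- function(x) sqrt(mean(x^2))
  y2 <- eog_notch(sin(2 * pi * 2 * t), fs)
  expect_lt(abs(rms(y2[1000:4000]) / sqrt(0.5) - 1), 0.02)
  y50 <- eog_notch(sin(2 * pi * 50 * t), fs)
  expect_lt(rms(y50[1000:4000]) / sqrt(0.5), 0.10)
  expect_error(eog_notch(numeric(1000), 100), "Nyquist")
})

test_that("baseline correction zeroes the median and is shift-invariant", {
  expect_equal(baseline_correct(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(baseline_correct(rep(4.2, 10)), rep(0, 10))
  x <- sin(seq(0, 10, by = 0.01)) + rnorm(1001)
  expect_equal(baseline_correct(x + 7.5), baseline_correct(x))
  expect_equal(median(baseline_correct(x)), 0)
})

test_that("framing tiles the signal and drops the remainder", {
  p <- group_preset("tdc", seed = 2)
  rec <- simulate_recording(p, text_spec(1, "Arial", 16, 200, 2))
  n <- length(rec$horizontal)

  fr <- segment_frames(rec, "horizontal", frame_len = 1000)
  expect_equal(nrow(fr), n %/% 1000)
  expect_true(all(lengths(fr$samples) == 1000))
  expect_equal(fr$frame_index, seq_len(nrow(fr)) - 1L)
  expect_equal(unique(fr$label), "tdc")
  # partition: concatenated frames reproduce the leading samples exactly
  expect_identical(unlist(fr$samples), rec$horizontal[seq_len(nrow(fr) * 1000)])

  short <- rec
  short$horizontal <- short$horizontal[1:1234]
  short$vertical <- short$vertical[1:1234]
  short$markers <- c(0L, 1234L)
  fr1 <- segment_frames(short, "horizontal", frame_len = 1000)
  expect_equal(nrow(fr1), 1)
  expect_identical(fr1$samples[[1]], short$horizontal[1:1000])

  tiny <- short
  tiny$horizontal <- tiny$horizontal[1:999]
  tiny$vertical <- tiny$vertical[1:999]
  tiny$markers <- c(0L, 999L)
  expect_warning(fr0 <- segment_frames(tiny, "horizontal", frame_len = 1000),
                 "shorter")
  expect_equal(nrow(fr0), 0)
})

test_that("filtering is idempotent in the passband sense", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  y1 <- eog_bandpass(x, fs)
  y2 <- eog_bandpass(y1, fs)
  rms <- function(v) sqrt(mean(v[1000:5000]^2))
  expect_lt(abs(rms(y2) / rms(y1) - 1), 0.05)
})

test_that("preprocess_recording skips the notch at fs = 100 with a warning", {
  rec <- simulate_recording(group_preset("tdc", seed = 3),
                            text_spec(1, "Arial", 16, 24, 2))
  expect_warning(out <- preprocess_recording(rec), "Nyquist")
  expect_true(out$preprocessed)
  expect_equal(length(out$horizontal), length(rec$horizontal))
  expect_equal(median(out$vertical), 0)
})
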