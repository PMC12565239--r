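#' Blink-detector configuration
#'
#' The detector accepts a peak as a blink when the latency from the
#' threshold up-crossing to the crest lies in `[min_rise, max_rise]`
#' (defaults 50--400 ms; the broader 100--800 ms blink-duration range quoted
#' in the eye-movement literature can be configured instead) and the peak
#' exceeds a per-signal amplitude threshold
#' `T = median(x) + threshold_k * mad(x)` -- a robust scale that resists the
#' blink outliers themselves.
#'
#' @param min_rise,max_rise Up-crossing-to-peak window in seconds.
#' @param threshold_k Multiplier on the per-signal MAD (default 4).
#' @return A `blink_config` object.
#' @export
blink_config <- function(min_rise = 0.05, max_rise = 0.40, threshold_k = 4) {
  if (!(0 < min_rise && min_rise < max_rise)) abort("need 0 < min_rise < max_rise")
  if (threshold_k <= 0) abort("`threshold_k` must be > 0")
  structure(list(min_rise = min_rise, max_rise = max_rise,
                 threshold_k = threshold_k), class = "blink_config")
}

empty_events <- function() {
  tibble(kind = character(), onset = numeric(), peak = numeric(),
         amplitude = numeric())
}

#' Reading time from start/end markers
#'
#' Reading time for a text is the time difference between its start and end
#' markers (0-based sample offsets), in seconds.
#'
#' @param rec An `eog_recording` with an even, sorted marker vector.
#' @param text_index Which start/end pair to use (default 1).
#' @return Reading time in seconds (strictly positive).
#' @export
#' @examples
#' rec <- simulate_recording(group_preset("tdc", seed = 1),
#'                           text_spec(1, "Arial", 16, 24, 2))
#' reading_time(rec)
reading_time <- function(rec, text_index = 1) {
  stopifnot(inherits(rec, "eog_recording"))
  m <- rec$markers
  if (length(m) < 2 * text_index) {
    abort(sprintf("no marker pair for text index %d (text id %s)",
                  text_index, rec$text_meta$text_id))
  }
  start <- m[2 * text_index - 1]
  end <- m[2 * text_index]
  if (end <= start) {
    abort(sprintf("markers for text id %s give non-positive duration",
                  rec$text_meta$text_id))
  }
  (end - start) / rec$sampling_rate
}

#' Detect blinks on the vertical channel
#'
#' Expects a notch-filtered, baseline-corrected vertical EOG signal. Regions
#' above the per-signal threshold are candidate blink excursions; the crest
#' of each region is accepted as a blink when the latency from the region's
#' threshold up-crossing to the crest lies within the configured window.
#' Peaks below threshold are never returned.
#'
#' @param x Vertical-channel signal vector.
#' @param fs Sampling rate in Hz (> 0).
#' @param cfg A [blink_config()].
#' @return Tibble of events (`kind = "blink"`, `onset` = up-crossing time,
#'   `peak` = crest time, `amplitude` = crest value), sorted by peak time.
#' @export
detect_blinks <- function(x, fs, cfg = blink_config()) {
  assert_numeric_signal(x)
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be > 0")
  thr <- stats::median(x) + cfg$threshold_k * stats::mad(x)
  above <- x > thr
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  out <- lapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    ipk <- seg[which.max(x[seg])]
    latency <- (ipk - starts[i]) / fs
    if (latency < cfg$min_rise || latency > cfg$max_rise) return(NULL)
    tibble(kind = "blink", onset = (starts[i] - 1) / fs,
           peak = (ipk - 1) / fs, amplitude = x[ipk])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty_events() else dplyr::arrange(out, .data$peak)
}

# Median forward word-step amplitude estimated from fast positive excursions
# of the windowed first difference.
estimate_word_step <- function(d) {
  mx <- max(d)
  if (!is.finite(mx) || mx <= 0) return(NA_real_)
  thr <- 0.3 * mx
  is_pk <- d > thr &
    d >= c(-Inf, d[-length(d)]) &
    d >= c(d[-1], Inf)
  stats::median(d[is_pk])
}

#' Detect regressive saccades on the horizontal channel
#'
#' A regression is a sudden negative amplitude change: the windowed first
#' difference (default 50 ms window) drops by at least `min_drop`. Line
#' return sweeps -- the much larger leftward movement at the end of each text
#' line -- are excluded by bounding the event's full local amplitude drop at
#' `line_exclusion_frac` times the signal's amplitude range (1st--99th
#' percentile). Consecutive events must be separated by `min_separation`.
#'
#' @param x Band-passed horizontal-channel signal.
#' @param fs Sampling rate in Hz.
#' @param min_drop Minimum drop in signal units; `NULL` (default) uses 0.6
#'   times the median forward word-step estimated from the signal itself.
#' @param min_separation Minimum time between events in seconds.
#' @param window First-difference window in seconds.
#' @param line_exclusion_frac Upper bound on event drop as a fraction of the
#'   per-line amplitude range (default 0.5).
#' @return Tibble of events (`kind = "regression"`, `onset`, `peak` = time of
#'   steepest drop, `amplitude` = signed full drop), sorted by time.
#' @export
detect_regressions <- function(x, fs, min_drop = NULL, min_separation = 0.15,
                               window = 0.05, line_exclusion_frac = 0.5) {
  assert_numeric_signal(x)
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be > 0")
  w <- max(1L, round(window * fs))
  n <- length(x)
  if (n <= 3 * w) return(empty_events())
  d <- x[(1 + w):n] - x[1:(n - w)]  # d[i] = x[i + w] - x[i]
  if (is.null(min_drop)) {
    step <- estimate_word_step(d)
    if (!is.finite(step) || step <= 0) return(empty_events())
    min_drop <- 0.6 * step
  }
  rng <- diff(stats::quantile(x, c(0.01, 0.99), names = FALSE))
  max_drop <- line_exclusion_frac * rng
  cand <- d <= -min_drop
  if (!any(cand)) return(empty_events())
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  events <- lapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    imin <- seg[which.min(d[seg])]  # steepest drop, index into d (= index into x)
    # a drop whose evaluation window is cut off by the signal boundary cannot
    # be sized (and the boundary carries zero-phase filter transients): skip
    if (imin <= 2L * w || imin + 3L * w > n) return(NULL)
    pre <- (imin - 2L * w):imin
    post <- imin:(imin + 3L * w)
    full_drop <- max(x[pre]) - min(x[post])
    if (full_drop > max_drop) return(NULL)  # line-return sweep
    tibble(kind = "regression", onset = (starts[i] - 1) / fs,
           peak = (imin - 1) / fs, amplitude = -full_drop)
  })
  events <- dplyr::bind_rows(events)
  if (nrow(events) == 0) return(empty_events())
  events <- dplyr::arrange(events, .data$peak)
  keep <- rep(TRUE, nrow(events))
  last <- events$peak[1]
  if (nrow(events) > 1) {
    for (i in 2:nrow(events)) {
      if (events$peak[i] - last < min_separation) keep[i] <- FALSE else last <- events$peak[i]
    }
  }
  events[keep, ]
}

#' Discrete signal energy
#'
#' `sum(x^2)` with the unit-sample-spacing convention (signal-units squared
#' times samples). Non-negative and additive over disjoint segments;
#' invariant under sample reversal and sign flip.
#'
#' @param x Numeric signal vector with finite samples.
#' @return A single non-negative number.
#' @export
#' @examples
#' signal_energy(c(1, 2, 3))  # 14
signal_energy <- function(x) {
  assert_numeric_signal(x)
  sum(x^2)
}

#' Extract the oculomotor feature set
#'
#' Computes, per recording: reading time (s), blink count and blink rate
#' (blinks per minute of reading time), regression count and regression rate
#' (regressions per word), and horizontal-channel signal energy. Recordings
#' that have not been preprocessed are passed through
#' [preprocess_recording()] first.
#'
#' @param recordings An `eog_recording` or a list of them.
#' @param blink_cfg A [blink_config()].
#' @param reg_min_drop,reg_min_separation Regression-detector settings, see
#'   [detect_regressions()].
#' @return A tibble with one row per recording: identifiers
#'   (`subject`, `group`, `grade`, `text_id`, `typeface`, `font_size`,
#'   `word_count`) and features (`reading_time`, `n_blinks`, `blink_rate`,
#'   `n_regressions`, `regression_rate`, `energy`).
#' @export
#' @examples
#' recs <- make_dataset(1, default_texts(1, word_count = 24), seed = 1)
#' extract_features(recs)
extract_features <- function(recordings, blink_cfg = blink_config(),
                             reg_min_drop = NULL, reg_min_separation = 0.15) {
  if (inherits(recordings, "eog_recording")) recordings <- list(recordings)
  purrr::map_dfr(recordings, function(rec) {
    if (!isTRUE(rec$preprocessed)) rec <- preprocess_recording(rec)
    rt <- reading_time(rec)
    blinks <- detect_blinks(rec$vertical, rec$sampling_rate, blink_cfg)
    regs <- detect_regressions(rec$horizontal, rec$sampling_rate,
                               min_drop = reg_min_drop,
                               min_separation = reg_min_separation)
    wc <- rec$text_meta$word_count
    tibble(
      subject = rec$subject_id, group = rec$group_label, grade = rec$grade,
      text_id = rec$text_meta$text_id, typeface = rec$text_meta$typeface,
      font_size = rec$text_meta$font_size, word_count = wc,
      reading_time = rt,
      n_blinks = nrow(blinks), blink_rate = nrow(blinks) / (rt / 60),
      n_regressions = nrow(regs), regression_rate = nrow(regs) / wc,
      energy = signal_energy(rec$horizontal)
    )
  })
}

feature_names <- c("reading_time", "blink_rate", "regression_rate", "energy")

#' Group comparison report
#'
#' Summarises a feature table by text (per-text group means) and tests the
#' group contrast per grade and feature with an independent two-sample
#' t-test (equal variances). Because the unit of analysis for such tests is
#' ambiguous in practice, both are computed and labelled: `"subject"`
#' (per-subject means within grade, the conservative unit) and
#' `"observation"` (all subject-by-text rows pooled). Significance stars:
#' `****` for p < 1e-4, `*` for p < 0.05, `ns` otherwise. A grade with fewer
#' than two subjects in either group is flagged and left untested.
#'
#' @param features Tibble from [extract_features()].
#' @return An `eog_group_report`: list with tibbles `text_means` (per text
#'   and group) and `tests` (per grade, feature and unit). `tidy()` returns
#'   the test table.
#' @export
group_report <- function(features) {
  stopifnot(all(c("group", "grade", "subject", "text_id") %in% names(features)))
  long <- tidyr::pivot_longer(features, dplyr::all_of(feature_names),
                              names_to = "feature", values_to = "value")
  text_means <- long |>
    dplyr::group_by(.data$grade, .data$text_id, .data$typeface,
                    .data$font_size, .data$feature, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")

  run_tests <- function(dat, unit) {
    dat |>
      dplyr::group_by(.data$grade, .data$feature) |>
      dplyr::group_modify(function(g, key) {
        x <- g$value[g$group == "dyslexia"]
        y <- g$value[g$group == "tdc"]
        if (length(x) < 2 || length(y) < 2) {
          return(tibble(unit = unit, n_dyslexia = length(x), n_tdc = length(y),
                        mean_dyslexia = mean(x), mean_tdc = mean(y),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        stars = NA_character_, flag = "insufficient subjects"))
        }
        tt <- stats::t.test(x, y, var.equal = TRUE)
        tibble(unit = unit, n_dyslexia = length(x), n_tdc = length(y),
               mean_dyslexia = mean(x), mean_tdc = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               stars = if (tt$p.value < 1e-4) "****"
                       else if (tt$p.value < 0.05) "*" else "ns",
               flag = NA_character_)
      }) |>
      dplyr::ungroup()
  }

  by_subject <- long |>
    dplyr::group_by(.data$grade, .data$feature, .data$group, .data$subject) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  tests <- dplyr::bind_rows(
    run_tests(by_subject, "subject"),
    run_tests(long, "observation")
  )
  structure(list(text_means = text_means, tests = tests),
            class = "eog_group_report")
}

#' @export
print.eog_group_report <- function(x, ...) {
  cat("<eog_group_report>\n")
  cat("Per-grade group tests (independent two-sample t-test):\n")
  print(as.data.frame(x$tests[x$tests$unit == "subject", ]), digits = 4)
  invisible(x)
}

#' @rdname group_report
#' @param x An `eog_group_report`.
#' @param ... Unused.
#' @export
tidy.eog_group_report <- function(x, ...) x$tests
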