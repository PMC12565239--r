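#' Simulate one reading-EOG recording
#'
#' Generates a two-channel EOG recording of one subject reading one text.
#' The horizontal channel is a per-line staircase of forward word saccades
#' (linear 30 ms ramps between fixation plateaus) with occasional sudden
#' negative regression steps and a large negative line-return sweep at each
#' line end. The vertical channel carries Poisson-arriving biphasic
#' raised-cosine blink pulses. White Gaussian noise and an optional 50 Hz
#' sinusoid are added to both channels. Every injected blink and regression
#' is recorded in the returned ground truth, which makes the downstream
#' detectors testable.
#'
#' Randomness is consumed in a documented order so that parts of the draw can
#' be replayed independently: (1) one uniform draw per word for the
#' regression Bernoulli sequence (a word is regression-eligible if it is not
#' the first word of its line), (2) fixation durations, (3) blink count and
#' blink onset times, (4) channel noise. With a fixed `params$seed` the
#' output is bit-identical across calls.
#'
#' @param params A [sim_params()] object.
#' @param text A [text_spec()] object; `text$word_count` must be at least
#'   `params$words_per_line`.
#' @param subject_id Subject identifier string.
#' @return An object of class `eog_recording` with fields `subject_id`,
#'   `group_label`, `grade`, `text_meta`, `horizontal`, `vertical`,
#'   `sampling_rate`, `markers` (0-based start/end sample offsets) and
#'   `ground_truth` (`blink_times`, `regression_times`, `reading_time`,
#'   `word_count`, all times in seconds).
#' @export
#' @examples
#' rec <- simulate_recording(group_preset("tdc", seed = 1),
#'                           text_spec(1, "Arial", 16, 24, 2))
#' rec$ground_truth$reading_time
simulate_recording <- function(params, text, subject_id = "S01") {
  validate_sim_params(params)
  if (!inherits(text, "eog_text_spec")) abort("`text` must be a `text_spec()` object")
  if (text$word_count < params$words_per_line) {
    abort("`text$word_count` must be at least `params$words_per_line`")
  }
  maybe_with_seed(params$seed, simulate_recording_impl(params, text, subject_id))
}

simulate_recording_impl <- function(params, text, subject_id) {
  fs <- params$sampling_rate
  wc <- text$word_count
  wpl <- params$words_per_line
  n_lines <- as.integer(ceiling(wc / wpl))
  line_sizes <- rep(wpl, n_lines)
  line_sizes[n_lines] <- wc - wpl * (n_lines - 1L)

  ## (1) regression Bernoulli sequence, one draw per word
  reg_draw <- stats::runif(wc)
  word_in_line <- sequence(line_sizes)
  is_reg <- reg_draw < params$regression_prob & word_in_line >= 2L

  amp <- params$saccade_amplitude
  n_sacc <- max(1L, round(params$saccade_duration * fs))
  n_ret <- max(1L, round(0.1 * fs))

  segs <- vector("list", 4L * wc + 2L * n_lines)
  n_seg <- 0L
  n_acc <- 0L
  add <- function(v) {
    n_seg <<- n_seg + 1L
    segs[[n_seg]] <<- v
    n_acc <<- n_acc + length(v)
  }
  draw_fix <- function() {
    max(8L, round(stats::rnorm(1, params$fixation_duration_mean,
                               params$fixation_duration_sd) * fs))
  }

  ## (2) horizontal staircase (consumes fixation-duration draws)
  reg_times <- numeric(0)
  widx <- 0L
  for (li in seq_len(n_lines)) {
    level <- 0
    for (wi in seq_len(line_sizes[li])) {
      widx <- widx + 1L
      if (wi > 1L) {
        add(ramp_to(level, level + amp, n_sacc))
        level <- level + amp
      }
      add(rep(level, draw_fix()))
      if (is_reg[widx]) {
        reg_amp <- params$regression_amplitude_frac * amp
        reg_times <- c(reg_times, n_acc / fs)
        add(ramp_to(level, level - reg_amp, n_sacc))
        add(rep(level - reg_amp, draw_fix()))
        add(ramp_to(level - reg_amp, level, n_sacc))
      }
    }
    ret_amp <- params$line_return_amplitude %||% level
    add(ramp_to(level, level - ret_amp, n_ret))
  }
  horizontal <- unlist(segs[seq_len(n_seg)], use.names = FALSE)
  n <- length(horizontal)
  dur_s <- n / fs

  ## (3) blinks: Poisson count over the realised duration, uniform onsets;
  ## arrivals whose pulse would overrun the recording, or closer than one
  ## pulse width to the previous arrival, are thinned to keep pulses
  ## non-overlapping.
  rise <- params$blink_rise_time
  pulse_dur <- 3 * rise
  n_blinks_drawn <- stats::rpois(1, params$blink_rate * dur_s / 60)
  blink_on <- if (n_blinks_drawn > 0) sort(stats::runif(n_blinks_drawn, 0, dur_s)) else numeric(0)
  blink_on <- blink_on[blink_on + pulse_dur < dur_s]
  if (length(blink_on) > 1) {
    keep <- c(TRUE, diff(blink_on) > pulse_dur)
    blink_on <- blink_on[keep]
  }

  vertical <- numeric(n)
  n_pulse <- max(3L, round(pulse_dur * fs))
  tt <- seq_len(n_pulse) / fs
  A <- params$blink_peak_amplitude
  shape <- ifelse(
    tt < rise, 0.5 * A * (1 - cos(pi * tt / rise)),
    ifelse(tt < 2 * rise,
           -0.2 * A + 1.2 * A * 0.5 * (1 + cos(pi * (tt - rise) / rise)),
           -0.2 * A * 0.5 * (1 + cos(pi * (tt - 2 * rise) / rise))))
  for (s0 in blink_on) {
    i0 <- floor(s0 * fs)
    idx <- i0 + seq_len(n_pulse)
    idx <- idx[idx <= n]
    vertical[idx] <- vertical[idx] + shape[seq_along(idx)]
  }
  blink_times <- blink_on + rise  # ground truth records pulse peak times

  ## (4) additive noise and optional powerline interference
  tvec <- (seq_len(n) - 1) / fs
  if (params$powerline_amp > 0) {
    horizontal <- horizontal + params$powerline_amp * sin(2 * pi * 50 * tvec)
    vertical <- vertical + params$powerline_amp * sin(2 * pi * 50 * tvec + 1)
  }
  if (params$noise_sd > 0) {
    horizontal <- horizontal + stats::rnorm(n, 0, params$noise_sd)
    vertical <- vertical + stats::rnorm(n, 0, params$noise_sd)
  }

  gt <- list(blink_times = blink_times, regression_times = reg_times,
             reading_time = dur_s, word_count = wc)
  new_eog_recording(
    subject_id = subject_id, group_label = params$group_label,
    grade = text$grade, text_meta = text,
    horizontal = horizontal, vertical = vertical,
    sampling_rate = fs, markers = c(0L, n), ground_truth = gt
  )
}

new_eog_recording <- function(subject_id, group_label, grade, text_meta,
                              horizontal, vertical, sampling_rate, markers,
                              ground_truth = NULL, preprocessed = FALSE) {
  if (length(horizontal) != length(vertical)) {
    abort("horizontal and vertical channels must have the same length")
  }
  if (length(markers) %% 2L != 0L || is.unsorted(markers) ||
      any(markers < 0) || any(markers > length(horizontal))) {
    abort("markers must be sorted start/end pairs within signal bounds")
  }
  structure(
    list(subject_id = subject_id, group_label = group_label, grade = grade,
         text_meta = text_meta, horizontal = horizontal, vertical = vertical,
         sampling_rate = sampling_rate, markers = markers,
         ground_truth = ground_truth, preprocessed = preprocessed),
    class = "eog_recording"
  )
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf(
    "<eog_recording> subject %s (%s, grade %d), text %d [%s %gpt, %d words]\n",
    x$subject_id, x$group_label, x$grade, x$text_meta$text_id,
    x$text_meta$typeface, x$text_meta$font_size, x$text_meta$word_count))
  cat(sprintf("  %d samples @ %g Hz (%.1f s)%s\n", length(x$horizontal),
              x$sampling_rate, length(x$horizontal) / x$sampling_rate,
              if (isTRUE(x$preprocessed)) ", preprocessed" else ""))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: %d blinks, %d regressions\n",
                length(x$ground_truth$blink_times),
                length(x$ground_truth$regression_times)))
  }
  invisible(x)
}

recording_id <- function(rec) {
  sprintf("%s_text%02d", rec$subject_id, rec$text_meta$text_id)
}

#' Simulate a subject-by-text dataset
#'
#' Generates one recording per subject and text for two groups. Each subject
#' gets mild lognormal jitter (about 8--15 % coefficient of variation) around
#' the group preset's fixation duration, regression probability and blink
#' rate, so that subjects within a group differ while group-level contrasts
#' are preserved. Deterministic under `seed`.
#'
#' @param n_subjects_per_group Number of subjects per group (>= 1).
#' @param texts List of [text_spec()] objects (non-empty).
#' @param group_presets Named list with elements `dyslexia` and `tdc`, each a
#'   [sim_params()] object.
#' @param seed Integer seed.
#' @return A list of `eog_recording` objects of length
#'   `2 * n_subjects_per_group * length(texts)`.
#' @export
#' @examples
#' recs <- make_dataset(1, default_texts(2, word_count = 16), seed = 1)
#' length(recs)
make_dataset <- function(n_subjects_per_group, texts,
                         group_presets = list(dyslexia = group_preset("dyslexia"),
                                              tdc = group_preset("tdc")),
                         seed = 1L) {
  if (n_subjects_per_group < 1) abort("`n_subjects_per_group` must be >= 1")
  if (length(texts) == 0) abort("`texts` must be a non-empty list")
  if (!all(c("dyslexia", "tdc") %in% names(group_presets))) {
    abort("`group_presets` must contain elements `dyslexia` and `tdc`")
  }
  maybe_with_seed(as.integer(seed), {
    recs <- list()
    for (g in c("dyslexia", "tdc")) {
      for (s in seq_len(n_subjects_per_group)) {
        p <- group_presets[[g]]
        p$group_label <- g  # group identity follows the preset slot
        p$fixation_duration_mean <- p$fixation_duration_mean * exp(stats::rnorm(1, 0, 0.08))
        p$regression_prob <- min(1, p$regression_prob * exp(stats::rnorm(1, 0, 0.15)))
        p$blink_rate <- p$blink_rate * exp(stats::rnorm(1, 0, 0.15))
        sid <- sprintf("%s%02d", if (g == "dyslexia") "D" else "T", s)
        for (tx in texts) {
          p$seed <- sample.int(.Machine$integer.max, 1)
          recs[[length(recs) + 1L]] <- simulate_recording(p, tx, subject_id = sid)
        }
      }
    }
    recs
  })
}
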