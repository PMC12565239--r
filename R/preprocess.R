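#' Filter specification
#'
#' Describes either the Butterworth band-pass used on raw EOG (default
#' 4th order, 0.1--10 Hz) or the notch (band-stop) used to remove 50 Hz
#' mains interference before blink detection.
#'
#' @param kind `"bandpass_butterworth"` or `"notch"`.
#' @param order Filter order (>= 1).
#' @param low_hz,high_hz Band edges in Hz for the band-pass.
#' @param notch_hz Notch centre frequency in Hz.
#' @param quality Notch quality factor Q (= centre / bandwidth); the default
#'   30 keeps the stop band narrow so the 0.1--10 Hz analysis band is
#'   untouched.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(kind = c("bandpass_butterworth", "notch"),
                        order = 4, low_hz = 0.1, high_hz = 10,
                        notch_hz = 50, quality = 30) {
  kind <- match.arg(kind)
  if (order < 1) abort("`order` must be >= 1")
  if (kind == "bandpass_butterworth") {
    if (!(0 < low_hz && low_hz < high_hz)) abort("need 0 < low_hz < high_hz")
  } else {
    if (notch_hz <= 0 || quality <= 0) abort("`notch_hz` and `quality` must be > 0")
  }
  structure(list(kind = kind, order = order, low_hz = low_hz, high_hz = high_hz,
                 notch_hz = notch_hz, quality = quality),
            class = "filter_spec")
}

filtfilt_checked <- function(bf, x, fs) {
  # forward-backward (zero-phase) application; event-timing rules downstream
  # depend on undistorted latencies
  pad <- 3 * (max(length(bf$b), length(bf$a)) - 1)
  if (length(x) <= pad) {
    abort(sprintf("signal too short for zero-phase filtering (need > %d samples)", pad))
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Band-pass filter an EOG channel
#'
#' Zero-phase (forward-backward) Butterworth band-pass. With the default
#' 4th-order 0.1--10 Hz design the attenuation at 50 Hz exceeds 40 dB
#' (when 50 Hz is below Nyquist) while in-band tones pass essentially
#' unchanged.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz; must exceed `2 * high_hz`.
#' @param spec A [filter_spec()] of kind `"bandpass_butterworth"`.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' y <- eog_bandpass(sin(2 * pi * 2 * t), fs = 100)
eog_bandpass <- function(x, fs, spec = filter_spec()) {
  assert_numeric_signal(x)
  if (spec$kind != "bandpass_butterworth") abort("`spec` must be a band-pass specification")
  if (fs <= 2 * spec$high_hz) abort("`fs` must exceed twice the upper band edge")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  filtfilt_checked(bf, x, fs)
}

#' Notch-filter an EOG channel
#'
#' Zero-phase second-order Butterworth band-stop centred on `notch_hz`
#' (default 50 Hz mains). Errors when the notch frequency is at or above
#' Nyquist -- in that case mains interference is already outside the
#' representable band and the notch should simply be skipped (as
#' [preprocess_recording()] does, with a warning).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param notch_hz Notch centre in Hz (must be `< fs/2`).
#' @param quality Quality factor Q; stop-band width is `notch_hz / quality`.
#' @return Filtered signal, same length as `x`.
#' @export
eog_notch <- function(x, fs, notch_hz = 50, quality = 30) {
  assert_numeric_signal(x)
  if (notch_hz >= fs / 2) {
    abort(sprintf(
      "notch at %g Hz is at or above Nyquist (%g Hz); skip the notch stage at this sampling rate",
      notch_hz, fs / 2))
  }
  bw <- notch_hz / quality
  bf <- signal::butter(2, c(notch_hz - bw / 2, notch_hz + bw / 2) / (fs / 2),
                       type = "stop")
  filtfilt_checked(bf, x, fs)
}

#' Baseline-correct a signal
#'
#' Subtracts the signal median (default) or mean so the corrected baseline
#' sits at zero; the median is robust to blink-induced outliers.
#'
#' @param x Numeric signal vector (non-empty).
#' @param method `"median"` or `"mean"`.
#' @return Corrected signal, same length.
#' @export
#' @examples
#' baseline_correct(c(1, 2, 3))
baseline_correct <- function(x, method = c("median", "mean")) {
  assert_numeric_signal(x)
  method <- match.arg(method)
  x - switch(method, median = stats::median(x), mean = mean(x))
}

#' Preprocess a recording in place
#'
#' Applies the standard chain to both channels: band-pass on horizontal and
#' vertical, then (vertical only, for the blink path) a 50 Hz notch when the
#' sampling rate allows it, and baseline correction. At `fs <= 2 * notch_hz`
#' the notch is skipped with a warning because the mains frequency sits at or
#' above Nyquist.
#'
#' @param rec An `eog_recording`.
#' @param spec Band-pass [filter_spec()].
#' @param notch Apply the vertical-channel notch? (logical)
#' @param notch_hz,quality Notch parameters, see [eog_notch()].
#' @return The recording with filtered channels and `preprocessed = TRUE`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(), notch = TRUE,
                                 notch_hz = 50, quality = 30) {
  stopifnot(inherits(rec, "eog_recording"))
  fs <- rec$sampling_rate
  rec$horizontal <- eog_bandpass(rec$horizontal, fs, spec)
  v <- eog_bandpass(rec$vertical, fs, spec)
  if (notch) {
    if (notch_hz < fs / 2) {
      v <- eog_notch(v, fs, notch_hz, quality)
    } else {
      warn(sprintf("skipping %g Hz notch: at or above Nyquist for fs = %g Hz",
                   notch_hz, fs))
    }
  }
  rec$vertical <- baseline_correct(v)
  rec$preprocessed <- TRUE
  rec
}

#' Segment a recording channel into fixed-length frames
#'
#' Tiles the chosen channel into half-open windows
#' `[i * frame_len, (i + 1) * frame_len)` (0-based frame index `i`); the
#' trailing remainder is dropped rather than padded, so no fabricated signal
#' content reaches the scalogram stage. A signal shorter than one frame
#' yields zero frames with a warning.
#'
#' @param rec An `eog_recording`.
#' @param channel `"horizontal"` or `"vertical"`.
#' @param frame_len Frame length in samples (default 1000).
#' @return A tibble with columns `recording`, `subject`, `label`, `grade`,
#'   `channel`, `frame_index` (0-based) and list-column `samples` (each of
#'   length `frame_len`).
#' @export
#' @examples
#' rec <- simulate_recording(group_preset("tdc", seed = 1),
#'                           text_spec(1, "Arial", 16, 40, 2))
#' nrow(segment_frames(rec, "horizontal", frame_len = 500))
segment_frames <- function(rec, channel = c("horizontal", "vertical"),
                           frame_len = 1000) {
  stopifnot(inherits(rec, "eog_recording"))
  channel <- match.arg(channel)
  if (frame_len < 1) abort("`frame_len` must be >= 1")
  x <- rec[[channel]]
  n_frames <- length(x) %/% frame_len
  if (n_frames == 0L) {
    warn(sprintf("signal of %d samples is shorter than one %d-sample frame; no frames produced",
                 length(x), frame_len))
    return(tibble(recording = character(), subject = character(),
                  label = character(), grade = integer(), channel = character(),
                  frame_index = integer(), samples = list()))
  }
  frames <- lapply(seq_len(n_frames) - 1L, function(i) {
    x[(i * frame_len + 1L):((i + 1L) * frame_len)]
  })
  tibble(
    recording = recording_id(rec), subject = rec$subject_id,
    label = rec$group_label, grade = rec$grade, channel = channel,
    frame_index = seq_len(n_frames) - 1L, samples = frames
  )
}
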