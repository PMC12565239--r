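#' Wavelet specification for scalogram computation
#'
#' The analytic Morlet wavelet (centre frequency `omega0 = 6` rad/s in
#' dimensionless time) with a geometric scale ladder of
#' `voices_per_octave` scales per octave spanning `freq_range`. The default
#' range is the 0.1--10 Hz EOG analysis band.
#'
#' @param family Currently `"morlet"` (analytic Morlet).
#' @param voices_per_octave Scales per octave (>= 4, default 12).
#' @param freq_range Length-2 Hz vector, low and high frequency.
#' @param omega0 Morlet centre frequency (dimensionless, default 6).
#' @return A `wavelet_spec` object.
#' @export
wavelet_spec <- function(family = "morlet", voices_per_octave = 12,
                         freq_range = c(0.1, 10), omega0 = 6) {
  family <- match.arg(family)
  if (voices_per_octave < 4) abort("`voices_per_octave` must be >= 4")
  if (length(freq_range) != 2 || freq_range[1] <= 0 ||
      freq_range[1] >= freq_range[2]) {
    abort("`freq_range` must be an increasing positive Hz pair")
  }
  structure(list(family = family, voices_per_octave = voices_per_octave,
                 freq_range = freq_range, omega0 = omega0),
            class = "wavelet_spec")
}

#' Continuous wavelet transform energy scalogram
#'
#' Computes `|CWT(a, b)|^2` of a signal frame with the analytic Morlet
#' wavelet via the FFT method: at scale `a` the transform is the inverse FFT
#' of `x_hat(w) * sqrt(2 * pi * a * fs) * psi_hat(a * w)` where
#' `psi_hat(w) = pi^(-1/4) exp(-(w - omega0)^2 / 2)` for `w > 0` and zero
#' otherwise. Rows are ordered coarse (low frequency) to fine (high
#' frequency); the frequency attached to each scale is the wavelet's centre
#' frequency `omega0 / (2 * pi * a)` (Fourier-factor convention).
#'
#' @param frame Numeric frame vector, or one row of [segment_frames()]
#'   output (a list-column element).
#' @param fs Sampling rate in Hz.
#' @param spec A [wavelet_spec()].
#' @param frame_ref Optional identifier carried on the result.
#' @return An `eog_scalogram`: list with `power` (`n_scales x n_samples`,
#'   non-negative), `scales` (seconds), `frequencies` (Hz, increasing),
#'   `fs`, and `frame_ref`.
#' @export
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 9.99, by = 0.01))
#' sc <- eog_cwt(x, fs = 100)
#' sc$frequencies[which.max(rowMeans(sc$power))]
eog_cwt <- function(frame, fs, spec = wavelet_spec(), frame_ref = NULL) {
  assert_numeric_signal(frame, "frame")
  if (length(frame) < 2) abort("`frame` must contain at least 2 samples")
  if (fs <= 0) abort("`fs` must be > 0")
  fmax <- min(spec$freq_range[2], fs / 2)
  fmin <- spec$freq_range[1]
  v <- spec$voices_per_octave
  n_scales <- floor(log2(fmax / fmin) * v) + 1L
  freqs <- fmax * 2^(-(seq_len(n_scales) - 1L) / v)  # fine -> coarse
  w0 <- spec$omega0
  scales <- w0 / (2 * pi * freqs)  # seconds

  n <- length(frame)
  xh <- stats::fft(frame)
  k <- 0:(n - 1)
  omega <- 2 * pi * ifelse(k <= n / 2, k, k - n) * fs / n  # rad/s
  pos <- omega > 0
  power <- matrix(0, n_scales, n)
  for (j in seq_len(n_scales)) {
    a <- scales[j]
    psi <- numeric(n)
    psi[pos] <- pi^(-0.25) * exp(-(a * omega[pos] - w0)^2 / 2)
    norm <- sqrt(2 * pi * a * fs)
    W <- stats::fft(xh * norm * psi, inverse = TRUE) / n
    power[j, ] <- Mod(W)^2
  }
  # rows coarse -> fine frequency
  ord <- order(freqs)
  structure(
    list(power = power[ord, , drop = FALSE], scales = scales[ord],
         frequencies = freqs[ord], fs = fs, frame_ref = frame_ref),
    class = "eog_scalogram"
  )
}

#' @export
print.eog_scalogram <- function(x, ...) {
  cat(sprintf("<eog_scalogram> %d scales x %d samples, %.3g-%.3g Hz\n",
              nrow(x$power), ncol(x$power), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

# 256-entry jet-like RGB lookup table (values 0..255)
jet_lut <- function() {
  ramp <- grDevices::colorRamp(
    c("#00007F", "#0000FF", "#00FFFF", "#FFFF00", "#FF0000", "#7F0000"),
    space = "rgb")
  round(ramp(seq(0, 1, length.out = 256)))
}

# bilinear resize of a matrix to (h_out, w_out), pixel-centre convention
resize_bilinear <- function(m, h_out, w_out) {
  h <- nrow(m); w <- ncol(m)
  ry <- pmin(pmax((seq_len(h_out) - 0.5) * h / h_out - 0.5, 0), h - 1)
  rx <- pmin(pmax((seq_len(w_out) - 0.5) * w / w_out - 0.5, 0), w - 1)
  y0 <- pmin(floor(ry), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(rx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ry - y0; fx <- rx - x0
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- m[y1 + 1, x0 + 1, drop = FALSE]; m11 <- m[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, h_out, w_out); wx <- matrix(fx, h_out, w_out, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Deterministic numeric rendering: log-power is min--max normalised per
#' image, mapped through a jet-like colour lookup table to RGB, and
#' bilinearly resized to the target size. Because of the per-image min--max
#' normalisation, scaling the scalogram by any positive constant leaves the
#' image unchanged; a constant (e.g. all-zero) scalogram maps to the
#' mid-scale colour rather than erroring.
#'
#' @param scal An `eog_scalogram`.
#' @param size Output size: single integer or `(H, W)` pair. 28 for the
#'   compact CNN in this package; 227 for AlexNet-shaped models.
#' @param colormap `"jet"` (default) or a 256 x 3 matrix of 0--255 values.
#' @return An `eog_scalogram_image`: list with `pixels`
#'   (`H x W x 3` integer array, values 0--255), `size`, `colormap_name`.
#' @export
render_scalogram <- function(scal, size = 28, colormap = "jet") {
  stopifnot(inherits(scal, "eog_scalogram"))
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 1)) abort("`size` must be positive")
  if (is.character(colormap)) {
    cname <- colormap
    lut <- switch(colormap, jet = jet_lut(),
                  abort(sprintf("unknown colormap '%s'", colormap)))
  } else {
    cname <- "custom"
    lut <- colormap
    if (!is.matrix(lut) || ncol(lut) != 3) abort("custom colormap must be an n x 3 matrix")
  }
  p <- log10(scal$power + 1e-12)
  rngp <- range(p)
  z <- if (diff(rngp) == 0) {
    matrix(0.5, nrow(p), ncol(p))
  } else {
    (p - rngp[1]) / diff(rngp)
  }
  # display orientation: high frequency at the top row
  z <- z[rev(seq_len(nrow(z))), , drop = FALSE]
  idx <- matrix(pmin(nrow(lut), pmax(1, round(z * (nrow(lut) - 1)) + 1)),
                nrow(z), ncol(z))
  pixels <- array(0L, c(size[1], size[2], 3L))
  for (ch in 1:3) {
    chan <- matrix(lut[idx, ch], nrow(z), ncol(z))
    pixels[, , ch] <- as.integer(pmin(255, pmax(0, round(
      resize_bilinear(chan, size[1], size[2])))))
  }
  structure(list(pixels = pixels, size = size, colormap_name = cname),
            class = "eog_scalogram_image")
}

#' @export
print.eog_scalogram_image <- function(x, ...) {
  cat(sprintf("<eog_scalogram_image> %d x %d x 3 (%s colormap)\n",
              x$size[1], x$size[2], x$colormap_name))
  invisible(x)
}

#' Build a labelled scalogram-image dataset
#'
#' Runs the frame-to-image path over a list of recordings for one channel:
#' preprocess (unless already done), segment into `frame_len`-sample frames,
#' CWT each frame, render each scalogram. Provenance (recording, subject,
#' frame index, channel) is retained per image so that cross-validation can
#' split at frame, recording or subject level. When `limit_per_class` is set
#' the first `limit_per_class` images of each class (in recording order) are
#' kept, giving balanced counts.
#'
#' @param recordings List of `eog_recording` objects.
#' @param channel `"horizontal"` or `"vertical"`.
#' @param spec A [wavelet_spec()].
#' @param size Image size (see [render_scalogram()]).
#' @param frame_len Frame length in samples (default 1000).
#' @param limit_per_class Optional images per class; errors if a class
#'   cannot supply that many frames.
#' @param preprocess Apply [preprocess_recording()] first (default TRUE).
#' @return A tibble with columns `label`, `subject`, `recording`, `grade`,
#'   `channel`, `frame_index`, and list-column `image`
#'   (`eog_scalogram_image` objects).
#' @export
build_image_dataset <- function(recordings, channel = c("horizontal", "vertical"),
                                spec = wavelet_spec(), size = 28,
                                frame_len = 1000, limit_per_class = NULL,
                                preprocess = TRUE) {
  channel <- match.arg(channel)
  if (length(recordings) == 0) abort("`recordings` is empty")
  frames <- purrr::map_dfr(recordings, function(rec) {
    if (preprocess && !isTRUE(rec$preprocessed)) rec <- preprocess_recording(rec)
    segment_frames(rec, channel, frame_len)
  })
  if (nrow(frames) == 0) abort("no frames: recordings shorter than one frame")
  classes <- unique(frames$label)
  if (length(classes) < 2) abort("need frames from at least two classes")
  if (!is.null(limit_per_class)) {
    counts <- table(frames$label)
    if (any(counts < limit_per_class)) {
      abort(sprintf("class '%s' has only %d frames (< limit_per_class = %d)",
                    names(counts)[which.min(counts)], min(counts),
                    limit_per_class))
    }
    frames <- frames |>
      dplyr::group_by(.data$label) |>
      dplyr::slice_head(n = limit_per_class) |>
      dplyr::ungroup()
  }
  fs <- recordings[[1]]$sampling_rate
  frames$image <- purrr::map2(frames$samples, seq_len(nrow(frames)), function(x, i) {
    render_scalogram(eog_cwt(x, fs, spec,
                             frame_ref = paste0(frames$recording[i], "#",
                                                frames$frame_index[i])),
                     size = size)
  })
  frames[, c("label", "subject", "recording", "grade", "channel",
             "frame_index", "image")]
}
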