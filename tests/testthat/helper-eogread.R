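# Greedy matching of detected event times to ground-truth times within a
# tolerance; each truth event can absorb at most one detection.
match_events <- function(detected, truth, tol = 0.15) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    d <- abs(truth - t)
    d[used] <- Inf
    if (length(d) > 0 && min(d) <= tol) {
      tp <- tp + 1L
      used[which.min(d)] <- TRUE
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

precision_recall <- function(counts) {
  c(precision = unname(counts["tp"] / (counts["tp"] + counts["fp"])),
    recall = unname(counts["tp"] / (counts["tp"] + counts["fn"])))
}

# Two synthetic image classes whose frames live in disjoint frequency bands;
# trivially separable by construction, used for learnability checks.
make_tone_image_dataset <- function(n_per_class, freqs = c(1, 5), noise_sd = 0.5,
                                    seed = 1, size = 28) {
  withr::with_seed(seed, {
    one_class <- function(freq, lab) {
      tibble::tibble(
        label = lab,
        subject = paste0(lab, "_", seq_len(n_per_class)),
        recording = paste0(lab, "_", seq_len(n_per_class)),
        grade = 2L,
        channel = "synthetic",
        frame_index = 0L,
        image = lapply(seq_len(n_per_class), function(i) {
          x <- sin(2 * pi * freq * seq(0, 9.99, by = 0.01) +
                     stats::runif(1, 0, 2 * pi)) +
            stats::rnorm(1000, 0, noise_sd)
          render_scalogram(eog_cwt(x, 100), size)
        })
      )
    }
    rbind(one_class(freqs[1], "slow"), one_class(freqs[2], "fast"))
  })
}

quiet_preprocess <- function(rec, ...) suppressWarnings(preprocess_recording(rec, ...))
quiet_features <- function(recs, ...) suppressWarnings(extract_features(recs, ...))
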