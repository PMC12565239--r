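# eogread

Reading electrooculography (EOG) analysis in R: from simulated two-channel
reading recordings with ground-truth ocular events, through oculomotor
feature extraction and group statistics, to wavelet-scalogram imaging and a
compact convolutional network with k-fold cross-validated evaluation.

## Who this is for

Children with dyslexia read more slowly, blink more, and return to
previously read words (regressive saccades) more often than typically
developing controls (TDC). These behaviours leave clear signatures in
two-channel EOG recorded during reading: the horizontal channel traces the
left-to-right fixation/saccade staircase of each text line (with sudden
negative steps at regressions and a large leftward sweep at each line
return), while the vertical channel carries the large transients of blinks.
`eogread` packages the complete analysis chain for such recordings —
detection of those events, the derived reading-performance features, and a
scalogram-based deep-learning classifier — together with a simulator that
generates realistic reading EOG with known event ground truth, so every
stage is testable without access to clinical recordings.

## The methods in brief

* **Preprocessing.** 4th-order Butterworth band-pass (0.1–10 Hz), applied
  forward–backward (zero phase) so event latencies are undistorted; 50 Hz
  notch (Q = 30) and median baseline correction on the vertical channel
  before blink detection; fixed-length 1000-sample framing for imaging.
* **Features.** Reading time from start/end markers; blinks as
  above-threshold crests whose up-crossing-to-crest latency lies in
  50–400 ms, with the per-signal threshold `median + 4·MAD`; regressions as
  sudden negative amplitude changes of the horizontal channel (windowed
  first difference), with line-return sweeps excluded by an amplitude
  bound; signal energy `E = Σ x[n]²`. Rates follow the usual conventions:
  blinks per minute of reading time, regressions per word.
* **Statistics.** Per-text group means and per-grade independent two-sample
  t-tests for each feature, at both subject and observation level.
* **Imaging.** Analytic Morlet CWT (12 voices/octave, 0.1–10 Hz),
  energy scalogram `|CWT(a,b)|²`, rendered to fixed-size RGB images
  (log-power, per-image min–max normalisation, jet-like colormap, bilinear
  resize).
* **Classifier.** A compact CNN for 28×28×3 scalogram images: four 4×4
  convolution blocks (16/32/64/64 filters, stride 1, same padding) each
  with batch normalisation and ReLU, max pooling after the first two blocks
  (28→7→3), 50 % dropout, a 2-unit fully connected layer and softmax —
  108,946 learnables in total. Trained with Adam and evaluated by
  stratified 5-fold cross-validation with accuracy, sensitivity,
  specificity and F1 from the fold confusion matrices, reported as
  mean ± sd plus the overlapped (summed) confusion matrix.

## Worked example

```r
library(eogread)

# simulate 4 subjects per group reading 2 texts, extract features
recs  <- make_dataset(4, default_texts(2, word_count = 60), seed = 1)
feats <- extract_features(recs)
dplyr::summarise(dplyr::group_by(feats, group),
                 reading_time = mean(reading_time),
                 blink_rate = mean(blink_rate),
                 regression_rate = mean(regression_rate))
#> # A tibble: 2 x 4
#>   group    reading_time blink_rate regression_rate
#>   <chr>           <dbl>      <dbl>           <dbl>
#> 1 dyslexia         37.5      16.5           0.196
#> 2 tdc              22.3       9.09          0.0609
```

The dyslexia group reads the same texts more slowly (37.5 s vs 22.3 s on
average), blinks almost twice as often per minute, and regresses at about
three times the per-word rate — the directions expected for dyslexic
readers, recovered here entirely from the signals by the detectors (the
simulator's ground truth is never consulted).

Continuing to images and classification:

```r
ds <- build_image_dataset(recs, "horizontal", frame_len = 1000, size = 28)
cv <- run_cv(ds, cv_config(k = 5, seed = 1, epochs = 8, batch_size = 32))
glance(cv)   # one-row mean/sd summary across folds
tidy(cv)     # per-fold accuracy, sensitivity, specificity, F1
```

A single-call pipeline (`run_pipeline(validate_config("config.yaml"))`)
executes simulate → preprocess → features → scalogram → train and writes
CSV/PNG/JSON artifacts plus a reproducibility manifest; a thin command-line
wrapper is provided at `inst/cli/eogread.R`.

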