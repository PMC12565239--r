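#' Confusion matrix for a two-class outcome
#'
#' @param truth,pred Factors (or characters) of true and predicted labels.
#' @param positive Label treated as positive; defaults to `"dyslexia"` when
#'   present, otherwise the first level of `truth`.
#' @return An `eog_cm` with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) abort("`truth` and `pred` lengths differ")
  positive <- positive %||% if ("dyslexia" %in% truth) "dyslexia" else truth[1]
  new_cm(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive),
    positive = positive
  )
}

#' @rdname confusion_matrix
#' @param tp,tn,fp,fn Non-negative outcome counts.
#' @export
new_cm <- function(tp, tn, fp, fn, positive = "positive") {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) abort("confusion-matrix counts must be non-negative")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, positive = positive),
            class = "eog_cm")
}

#' @export
print.eog_cm <- function(x, ...) {
  cat(sprintf("<eog_cm> positive = %s\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"), pred = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/(tp+tn+fp+fn)`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and F1 `2tp/(2tp+fp+fn)`, each expressed as a percentage.
#' A metric with a zero denominator is reported as `NaN` and named in the
#' `undefined` list-column -- never silently set to 0.
#'
#' @param cm An `eog_cm` (see [confusion_matrix()] / [new_cm()]).
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `f1` (percent) and list-column `undefined`.
#' @export
#' @examples
#' cm_metrics(new_cm(tp = 1601, tn = 1600, fp = 1400, fn = 1399))$accuracy
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "eog_cm"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) abort("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  vals <- c(
    accuracy = safe_div(cm$tp + cm$tn, total),
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    f1 = safe_div(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  ) * 100
  tibble(accuracy = vals[["accuracy"]], sensitivity = vals[["sensitivity"]],
         specificity = vals[["specificity"]], f1 = vals[["f1"]],
         undefined = list(names(vals)[is.nan(vals)]))
}

#' Aggregate per-fold metric values
#'
#' Arithmetic mean and sample standard deviation of fold-level percentages,
#' the convention used when summarising k-fold results as "mean +/- sd". A
#' singleton input is flagged and given sd 0 by convention.
#'
#' @param fold_values Numeric vector of per-fold values (non-empty).
#' @return One-row tibble with `mean`, `sd`, `n`, `flag`.
#' @export
#' @examples
#' aggregate_folds(c(77.08, 72.92, 70.33, 76.75, 71.58))$mean  # 73.732
aggregate_folds <- function(fold_values) {
  if (length(fold_values) == 0) abort("`fold_values` is empty")
  tibble(
    mean = mean(fold_values),
    sd = if (length(fold_values) == 1) 0 else stats::sd(fold_values),
    n = length(fold_values),
    flag = if (length(fold_values) == 1) "singleton" else NA_character_
  )
}

#' Cross-validation configuration
#'
#' @param k Number of folds (>= 2, default 5).
#' @param split_unit Unit kept intact across folds: `"frame"` (default,
#'   mirrors frame-level protocols but lets frames of one recording fall in
#'   both train and test -- see the leakage note in the vignette),
#'   `"recording"` or `"subject"` (recommended against leakage).
#' @param seed Integer seed controlling folds, initialisation and shuffling.
#' @param epochs,batch_size,learning_rate,optimizer_name Training settings;
#'   only Adam is implemented.
#' @return A `cv_config` object.
#' @export
cv_config <- function(k = 5, split_unit = c("frame", "recording", "subject"),
                      seed = 1, epochs = 20, batch_size = 64,
                      learning_rate = 1e-3, optimizer_name = "adam") {
  if (k < 2) abort("`k` must be >= 2")
  split_unit <- match.arg(split_unit)
  if (optimizer_name != "adam") abort("only the Adam optimiser is implemented")
  structure(list(k = as.integer(k), split_unit = split_unit,
                 seed = as.integer(seed), epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 optimizer_name = optimizer_name),
            class = "cv_config")
}

make_folds <- function(data, k, split_unit, seed) {
  maybe_with_seed(seed, {
    fold <- integer(nrow(data))
    if (split_unit == "frame") {
      for (cl in unique(data$label)) {
        idx <- sample(which(data$label == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      gcol <- if (split_unit == "subject") data$subject else data$recording
      if (is.null(gcol)) abort(sprintf("data lacks a `%s` column", split_unit))
      gl <- unique(data.frame(g = gcol, label = data$label))
      gl <- gl[!duplicated(gl$g), ]
      gfold <- integer(nrow(gl))
      for (cl in unique(gl$label)) {
        idx <- sample(which(gl$label == cl))
        gfold[idx] <- rep_len(seq_len(k), length(idx))
      }
      fold <- gfold[match(gcol, gl$g)]
    }
    fold
  })
}

#' k-fold cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation of the compact CNN on a labelled
#' scalogram-image dataset. Folds are stratified by class at the chosen
#' split unit; each fold trains a fresh model on the remaining folds and is
#' evaluated on the held-out fold. Fold assignment, weight initialisation
#' and shuffling are all deterministic under `cfg$seed`.
#'
#' @param data Dataset tibble from [build_image_dataset()] (columns `image`,
#'   `label`, optionally `subject` / `recording`).
#' @param cfg A [cv_config()].
#' @param spec A [dyslexianet_spec()]; its input shape must match the
#'   images.
#' @param positive Positive class label (default `"dyslexia"` when present).
#' @param verbose Print per-fold progress?
#' @return An `eog_cv` report: per-fold metrics and confusion matrices,
#'   mean +/- sd per metric, and the overlapped (element-wise summed)
#'   confusion matrix. Use `tidy()` for per-fold rows and `glance()` for the
#'   one-row summary.
#' @export
run_cv <- function(data, cfg = cv_config(), spec = dyslexianet_spec(),
                   positive = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(data), all(c("image", "label") %in% names(data)))
  data$label <- factor(data$label)
  if (nlevels(data$label) != spec$n_classes) {
    abort(sprintf("expected %d classes, found %d", spec$n_classes,
                  nlevels(data$label)))
  }
  if (min(table(data$label)) < cfg$k) {
    abort("each class needs at least k samples")
  }
  x <- images_to_matrix(data$image)
  if (ncol(x) != prod(spec$input_shape)) {
    abort(sprintf("images have %d values but the model expects %d",
                  ncol(x), prod(spec$input_shape)))
  }
  fold <- make_folds(data, cfg$k, cfg$split_unit, cfg$seed)
  for (f in seq_len(cfg$k)) {
    if (length(unique(data$label[fold == f])) < spec$n_classes ||
        length(unique(data$label[fold != f])) < spec$n_classes) {
      abort(sprintf("fold %d is missing a class; use more data or fewer folds", f))
    }
  }
  fold_metrics <- list()
  fold_cms <- list()
  for (f in seq_len(cfg$k)) {
    tr <- fold != f
    model <- build_model(spec, seed = cfg$seed * 1000L + f)
    model <- train_dyslexianet(model, x[tr, , drop = FALSE], data$label[tr],
                               epochs = cfg$epochs, batch_size = cfg$batch_size,
                               learning_rate = cfg$learning_rate,
                               seed = cfg$seed * 1000L + 500L + f)
    pred <- predict(model, x[!tr, , drop = FALSE], type = "class")
    cm <- confusion_matrix(data$label[!tr], pred, positive = positive)
    met <- cm_metrics(cm)
    met$fold <- f
    met$n_test <- sum(!tr)
    fold_metrics[[f]] <- met
    fold_cms[[f]] <- cm
    if (verbose) {
      message(sprintf("fold %d/%d accuracy %.2f%%", f, cfg$k, met$accuracy))
    }
  }
  fm <- dplyr::bind_rows(fold_metrics)[, c("fold", "n_test", "accuracy",
                                           "sensitivity", "specificity", "f1")]
  summary <- purrr::map_dfr(c("accuracy", "sensitivity", "specificity", "f1"),
                            function(mname) {
                              out <- aggregate_folds(fm[[mname]])
                              out$metric <- mname
                              out[, c("metric", "mean", "sd", "n", "flag")]
                            })
  overlapped <- new_cm(
    tp = sum(vapply(fold_cms, `[[`, numeric(1), "tp")),
    tn = sum(vapply(fold_cms, `[[`, numeric(1), "tn")),
    fp = sum(vapply(fold_cms, `[[`, numeric(1), "fp")),
    fn = sum(vapply(fold_cms, `[[`, numeric(1), "fn")),
    positive = fold_cms[[1]]$positive
  )
  structure(list(fold_metrics = fm, fold_cms = fold_cms, summary = summary,
                 overlapped = overlapped, config = cfg, fold = fold),
            class = "eog_cv")
}

#' @export
print.eog_cv <- function(x, ...) {
  cat(sprintf("<eog_cv> %d-fold, split by %s\n", x$config$k,
              x$config$split_unit))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @rdname run_cv
#' @param x An `eog_cv` report.
#' @param ... Unused.
#' @export
tidy.eog_cv <- function(x, ...) x$fold_metrics

#' @rdname run_cv
#' @export
glance.eog_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), paste0(x$summary$metric, "_mean"))
  wide_sd <- stats::setNames(as.list(x$summary$sd), paste0(x$summary$metric, "_sd"))
  tibble::as_tibble(c(wide, wide_sd, list(k = x$config$k)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
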