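test_that("the architecture exposes the expected layer shapes", {
  spec <- dyslexianet_spec()
  expect_equal(spec$fc_in, 576)
  m <- build_model(spec, seed = 1)
  shape_of <- function(nm) m$layers[[nm]]$out_shape
  expect_equal(shape_of("conv_1"), c(28, 28, 16))
  expect_equal(shape_of("maxpool_1"), c(7, 7, 16))
  expect_equal(shape_of("conv_2"), c(7, 7, 32))
  expect_equal(shape_of("maxpool_2"), c(3, 3, 32))
  expect_equal(shape_of("conv_3"), c(3, 3, 64))
  expect_equal(shape_of("conv_4"), c(3, 3, 64))
  expect_equal(shape_of("fc"), c(1, 1, 2))
})

test_that("per-layer learnable counts match the layer ledger", {
  m <- build_model(dyslexianet_spec(), seed = 1)
  expect_equal(count_learnables(m, "conv_1"), 784)
  expect_equal(count_learnables(m, "batchnorm_1"), 32)
  expect_equal(count_learnables(m, "Conv_2"), 8224)  # case-insensitive lookup
  expect_equal(count_learnables(m, "batchnorm_2"), 64)
  expect_equal(count_learnables(m, "conv_3"), 32832)
  expect_equal(count_learnables(m, "batchnorm_3"), 128)
  expect_equal(count_learnables(m, "conv_4"), 65600)
  expect_equal(count_learnables(m, "batchnorm_4"), 128)
  expect_equal(count_learnables(m, "fc"), 1154)
  expect_equal(count_learnables(m, "relu_1"), 0)
  expect_equal(count_learnables(m, "maxpool_1"), 0)
  expect_equal(count_learnables(m, "dropout"), 0)
  expect_equal(count_learnables(m, "softmax"), 0)
  expect_error(count_learnables(m, "conv_9"), "unknown layer")
})

test_that("an inconsistent architecture is rejected at the offending layer", {
  spec <- dyslexianet_spec()
  bad <- spec
  fc_pos <- which(vapply(bad$layers, `[[`, character(1), "name") == "fc")
  bad$layers[[fc_pos]]$in_features <- 1024L
  expect_error(build_model(bad), "fc")
  bad2 <- spec
  bn_pos <- which(vapply(bad2$layers, `[[`, character(1), "name") == "batchnorm_2")
  bad2$layers[[bn_pos]]$channels <- 8L
  expect_error(build_model(bad2), "batchnorm_2")
})

test_that("an untrained model emits normalised class probabilities", {
  m <- build_model(dyslexianet_spec(), seed = 2)
  x <- matrix(runif(3 * 28 * 28 * 3), 3)
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("metrics match their definitions computed from raw labels", {
  # worked example: 3201 correct of 6000
  cm <- new_cm(tp = 1601, tn = 1600, fp = 1400, fn = 1399)
  expect_equal(cm_metrics(cm)$accuracy, 53.35, tolerance = 0.005)

  expect_equal(unlist(cm_metrics(new_cm(10, 10, 0, 0))[, 1:4]),
               c(accuracy = 100, sensitivity = 100, specificity = 100, f1 = 100))

  expect_equal(cm_metrics(new_cm(tp = 50, tn = 0, fp = 10, fn = 30))$f1,
               2 * 50 / (2 * 50 + 10 + 30) * 100, tolerance = 1e-10)

  # dual route: metrics from a confusion matrix versus direct evaluation on
  # the label vectors the matrix was built from
  set.seed(9)
  truth <- sample(c("dyslexia", "tdc"), 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.3, sample(c("dyslexia", "tdc"), 500, TRUE), truth)
  cm <- confusion_matrix(truth, pred)
  met <- cm_metrics(cm)
  expect_equal(met$accuracy, 100 * mean(pred == truth))
  expect_equal(met$sensitivity,
               100 * mean(pred[truth == "dyslexia"] == "dyslexia"))
  expect_equal(met$specificity, 100 * mean(pred[truth == "tdc"] == "tdc"))
  prec <- mean(truth[pred == "dyslexia"] == "dyslexia")
  rec <- mean(pred[truth == "dyslexia"] == "dyslexia")
  expect_equal(met$f1, 100 * 2 * prec * rec / (prec + rec))
})

test_that("undefined metrics surface as NaN with a flag, never as zero", {
  met <- cm_metrics(new_cm(tp = 0, tn = 5, fp = 3, fn = 0))
  expect_true(is.nan(met$sensitivity))
  expect_true("sensitivity" %in% met$undefined[[1]])
  expect_false(identical(met$sensitivity, 0))
  expect_error(new_cm(-1, 2, 3, 4), "non-negative")
})

test_that("accuracy decomposes into prevalence-weighted sensitivity/specificity", {
  set.seed(11)
  for (i in 1:20) {
    cnt <- rpois(4, 40) + 1
    cm <- new_cm(cnt[1], cnt[2], cnt[3], cnt[4])
    met <- cm_metrics(cm)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(met$accuracy,
                 (met$sensitivity * P + met$specificity * N) / (P + N))
  }
})

test_that("fold aggregation is the arithmetic mean with sample sd", {
  agg <- aggregate_folds(c(77.08, 72.92, 70.33, 76.75, 71.58))
  expect_equal(agg$mean, 73.732)
  expect_equal(agg$sd, sd(c(77.08, 72.92, 70.33, 76.75, 71.58)))
  expect_equal(aggregate_folds(c(99.92, 100, 100, 99.92, 100))$mean, 99.968)
  single <- aggregate_folds(42)
  expect_equal(single$mean, 42)
  expect_equal(single$sd, 0)
  expect_equal(single$flag, "singleton")
  expect_error(aggregate_folds(numeric(0)), "empty")
})

test_that("cross-validation partitions the data and sums fold matrices", {
  ds <- make_tone_image_dataset(12, seed = 3)
  cfg <- cv_config(k = 3, seed = 5, epochs = 1, batch_size = 8)
  cv <- run_cv(ds, cfg)
  # folds: disjoint, exhaustive, stratified
  expect_equal(sort(unique(cv$fold)), 1:3)
  expect_equal(length(cv$fold), nrow(ds))
  for (f in 1:3) {
    expect_equal(sum(cv$fold == f), 8)
    expect_equal(unname(table(ds$label[cv$fold == f])), c(4L, 4L),
                 ignore_attr = TRUE)
  }
  # overlapped confusion matrix is the element-wise fold sum
  for (fld in c("tp", "tn", "fp", "fn")) {
    expect_equal(cv$overlapped[[fld]],
                 sum(vapply(cv$fold_cms, `[[`, numeric(1), fld)))
  }
  expect_equal(cv$overlapped$tp + cv$overlapped$tn + cv$overlapped$fp +
                 cv$overlapped$fn, nrow(ds))
  # summary equals aggregate_folds applied per metric
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(cv$fold_metrics$accuracy))
  # deterministic under the config seed
  cv2 <- run_cv(ds, cfg)
  expect_identical(cv$fold_metrics, cv2$fold_metrics)
  # broom-style accessors
  expect_equal(nrow(tidy(cv)), 3)
  expect_equal(glance(cv)$k, 3L)
})

test_that("subject-level splitting keeps a subject's frames in one fold", {
  ds <- make_tone_image_dataset(6, seed = 13)
  ds$subject <- rep(rep(paste0("S", 1:3), each = 2), 2)
  ds$subject <- paste0(ds$label, "_", ds$subject)
  cv <- run_cv(ds, cv_config(k = 3, split_unit = "subject", seed = 2,
                             epochs = 1, batch_size = 8))
  for (s in unique(ds$subject)) {
    expect_equal(length(unique(cv$fold[ds$subject == s])), 1)
  }
})
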