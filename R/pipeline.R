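pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "eogread-run",
    verbosity = 1L,
    simulate = list(
      n_subjects_per_group = 2L,
      n_texts = 4L,
      word_count = 48L,
      presets = list(dyslexia = list(), tdc = list())
    ),
    preprocess = list(order = 4, low_hz = 0.1, high_hz = 10, notch = TRUE,
                      notch_hz = 50, quality = 30),
    features = list(min_rise = 0.05, max_rise = 0.40, threshold_k = 4,
                    reg_min_separation = 0.15),
    scalogram = list(channel = "horizontal", frame_len = 1000L, size = 28L,
                     voices_per_octave = 12L, freq_low = 0.1, freq_high = 10,
                     limit_per_class = NULL),
    train = list(k = 5L, split_unit = "frame", epochs = 20L, batch_size = 64L,
                 learning_rate = 1e-3)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      abort(sprintf("unknown configuration key `%s`",
                    paste(c(path, nm), collapse = ".")))
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "presets") {
      if (!is.list(user[[nm]])) {
        abort(sprintf("configuration key `%s` must be a mapping",
                      paste(c(path, nm), collapse = ".")))
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, injects defaults for every missing
#' key, rejects unknown keys with their key path, and checks cross-field
#' invariants (blink window ordering, positive frame length, fold count).
#' An empty file yields the all-defaults configuration.
#'
#' @param config Path to a YAML/JSON file, or a named list, or `NULL` for
#'   defaults.
#' @return A validated `pipeline_config` list.
#' @export
#' @examples
#' cfg <- validate_config(list(train = list(k = 2)))
#' cfg$train$k
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  if (!is.list(config)) abort("configuration must be a mapping")
  cfg <- merge_config(pipeline_defaults(), config)
  if (cfg$features$min_rise >= cfg$features$max_rise) {
    abort("features.min_rise must be smaller than features.max_rise")
  }
  if (cfg$scalogram$frame_len < 1) abort("scalogram.frame_len must be >= 1")
  if (!cfg$scalogram$channel %in% c("horizontal", "vertical", "both")) {
    abort("scalogram.channel must be horizontal, vertical or both")
  }
  if (cfg$train$k < 2) abort("train.k must be >= 2")
  if (cfg$simulate$n_subjects_per_group < 1) {
    abort("simulate.n_subjects_per_group must be >= 1")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_wrap <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> features -> scalogram -> train and
#' writes all artifacts plus a reproducibility manifest (package version,
#' seed, per-stage timings, md5 hashes of the numeric outputs) under
#' `config$out_dir`. Re-running with the same configuration and seed
#' reproduces the numeric outputs bit-identically; CNN training is also
#' seeded and deterministic here because all of its stochastic components
#' (folds, initialisation, shuffling, dropout) derive from the seed.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "eogread",
                   version = as.character(utils::packageVersion("eogread")),
                   seed = cfg$seed, config = unclass(cfg), stages = list())
  say <- function(...) if (cfg$verbosity > 0) message(sprintf(...))
  tic <- function() Sys.time()
  stage_done <- function(name, t0, ...) {
    manifest$stages[[name]] <<- c(list(elapsed_s = as.numeric(Sys.time() - t0, units = "secs")),
                                  list(...))
  }

  # simulate
  t0 <- tic()
  recs <- stage_wrap("simulate", {
    presets <- list(
      dyslexia = do.call(group_preset, c(list(group = "dyslexia"),
                                         cfg$simulate$presets$dyslexia)),
      tdc = do.call(group_preset, c(list(group = "tdc"),
                                    cfg$simulate$presets$tdc))
    )
    make_dataset(cfg$simulate$n_subjects_per_group,
                 default_texts(cfg$simulate$n_texts, cfg$simulate$word_count),
                 presets, seed = cfg$seed)
  })
  rec_dir <- file.path(cfg$out_dir, "recordings")
  for (r in recs) write_recording(r, rec_dir)
  stage_done("simulate", t0, n_recordings = length(recs))
  say("simulate: %d recordings", length(recs))

  # preprocess
  t0 <- tic()
  recs <- stage_wrap("preprocess", {
    spec <- filter_spec(order = cfg$preprocess$order,
                        low_hz = cfg$preprocess$low_hz,
                        high_hz = cfg$preprocess$high_hz)
    lapply(recs, preprocess_recording, spec = spec,
           notch = cfg$preprocess$notch, notch_hz = cfg$preprocess$notch_hz,
           quality = cfg$preprocess$quality)
  })
  stage_done("preprocess", t0)
  say("preprocess: done")

  # features
  t0 <- tic()
  feats <- stage_wrap("features", {
    extract_features(recs,
                     blink_cfg = blink_config(cfg$features$min_rise,
                                              cfg$features$max_rise,
                                              cfg$features$threshold_k),
                     reg_min_separation = cfg$features$reg_min_separation)
  })
  feat_path <- file.path(cfg$out_dir, "features.csv")
  utils::write.csv(feats, feat_path, row.names = FALSE)
  report <- group_report(feats)
  jsonlite::write_json(list(tests = report$tests),
                       file.path(cfg$out_dir, "group_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  stage_done("features", t0, features_md5 = unname(tools::md5sum(feat_path)))
  say("features: %d rows", nrow(feats))

  # scalogram
  t0 <- tic()
  channels <- if (cfg$scalogram$channel == "both") c("horizontal", "vertical") else cfg$scalogram$channel
  wspec <- wavelet_spec(voices_per_octave = cfg$scalogram$voices_per_octave,
                        freq_range = c(cfg$scalogram$freq_low,
                                       cfg$scalogram$freq_high))
  datasets <- stage_wrap("scalogram", {
    lapply(stats::setNames(channels, channels), function(ch) {
      ds <- build_image_dataset(recs, ch, wspec, size = cfg$scalogram$size,
                                frame_len = cfg$scalogram$frame_len,
                                limit_per_class = cfg$scalogram$limit_per_class)
      write_image_dataset(ds, file.path(cfg$out_dir, paste0("images_", ch)))
      ds
    })
  })
  stage_done("scalogram", t0,
             n_images = vapply(datasets, nrow, integer(1)))
  say("scalogram: %s images", paste(vapply(datasets, nrow, integer(1)), collapse = "+"))

  # train
  t0 <- tic()
  cvs <- stage_wrap("train", {
    lapply(datasets, function(ds) {
      run_cv(ds, cv_config(k = cfg$train$k, split_unit = cfg$train$split_unit,
                           seed = cfg$seed, epochs = cfg$train$epochs,
                           batch_size = cfg$train$batch_size,
                           learning_rate = cfg$train$learning_rate),
             spec = dyslexianet_spec(input_shape = c(cfg$scalogram$size,
                                                     cfg$scalogram$size, 3)))
    })
  })
  cv_json <- lapply(cvs, function(cv) {
    list(summary = cv$summary, fold_metrics = cv$fold_metrics,
         overlapped = cv$overlapped[c("tp", "tn", "fp", "fn")])
  })
  jsonlite::write_json(cv_json, file.path(cfg$out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_done("train", t0,
             mean_accuracy = vapply(cvs, function(cv) {
               cv$summary$mean[cv$summary$metric == "accuracy"]
             }, numeric(1)))
  say("train: done")

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  say("manifest: %s (%d stages)", manifest_path, length(manifest$stages))
  invisible(manifest)
}
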