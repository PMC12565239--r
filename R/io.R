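#' Write / read a recording as CSV plus JSON sidecar
#'
#' The signal goes to `<id>.csv` (columns `horizontal`, `vertical`); markers,
#' metadata and ground truth go to `<id>.json`. The pair round-trips through
#' [read_recording()].
#'
#' @param rec An `eog_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "eog_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- recording_id(rec)
  csv <- file.path(dir, paste0(id, ".csv"))
  utils::write.csv(
    data.frame(horizontal = rec$horizontal, vertical = rec$vertical),
    csv, row.names = FALSE)
  meta <- list(
    subject_id = rec$subject_id, group_label = rec$group_label,
    grade = rec$grade, sampling_rate = rec$sampling_rate,
    markers = rec$markers, preprocessed = rec$preprocessed,
    text_meta = unclass(rec$text_meta), ground_truth = rec$ground_truth
  )
  jsonlite::write_json(meta, file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv)
}

#' @rdname write_recording
#' @param csv_path Path to a recording CSV written by [write_recording()]
#'   (the JSON sidecar is located next to it).
#' @export
read_recording <- function(csv_path) {
  sig <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  gt <- meta$ground_truth
  if (!is.null(gt)) {
    gt$blink_times <- as.numeric(gt$blink_times)
    gt$regression_times <- as.numeric(gt$regression_times)
  }
  new_eog_recording(
    subject_id = meta$subject_id, group_label = meta$group_label,
    grade = meta$grade,
    text_meta = do.call(text_spec, meta$text_meta[c("text_id", "typeface",
                                                    "font_size", "word_count",
                                                    "grade")]),
    horizontal = sig$horizontal, vertical = sig$vertical,
    sampling_rate = meta$sampling_rate, markers = meta$markers,
    ground_truth = gt, preprocessed = isTRUE(meta$preprocessed)
  )
}

#' Write a scalogram-image dataset to PNG files with a JSON manifest
#'
#' @param dataset Tibble from [build_image_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    f <- sprintf("%s_%s_f%04d.png", dataset$label[i], dataset$recording[i],
                 dataset$frame_index[i])
    png::writePNG(dataset$image[[i]]$pixels / 255, file.path(dir, f))
    files[i] <- f
  }
  manifest <- dataset[, setdiff(names(dataset), "image")]
  manifest$file <- files
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
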