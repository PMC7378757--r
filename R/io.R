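#' Write one annotated recording as a delimited text file pair
#'
#' The recording goes to `<prefix>_recording.csv` with columns `time_s,
#' ax_g, ay_g, az_g` and the annotations to `<prefix>_annotations.csv` with
#' columns `label, time_s`. Numeric values are written with 9 significant
#' digits.
#'
#' @param annotated An `annotated_recording`.
#' @param prefix File path prefix (directory must exist).
#' @return Invisibly, the two file paths written.
#' @export
write_recording <- function(annotated, prefix) {
  stopifnot(inherits(annotated, "annotated_recording"))
  rec <- annotated$recording
  n <- nrow(rec$data)
  num <- function(x) formatC(x, digits = 9, format = "g")
  rec_file <- paste0(prefix, "_recording.csv")
  ann_file <- paste0(prefix, "_annotations.csv")
  utils::write.csv(data.frame(time_s = num((seq_len(n) - 1) / rec$fs),
                              ax_g = num(rec$data[, 1]),
                              ay_g = num(rec$data[, 2]),
                              az_g = num(rec$data[, 3])),
                   rec_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(label = annotated$annotations$label,
                              time_s = num(annotated$annotations$time_s)),
                   ann_file, row.names = FALSE, quote = 1)  # quote labels only
  invisible(c(rec_file, ann_file))
}

#' Write every recording of a study
#'
#' One `subjectNN_recording.csv` / `subjectNN_annotations.csv` pair per
#' subject under `dir`.
#'
#' @param recordings List of `annotated_recording`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file prefixes.
#' @export
write_study <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefixes <- file.path(dir, sprintf("subject%02d", seq_along(recordings)))
  for (i in seq_along(recordings)) write_recording(recordings[[i]], prefixes[i])
  invisible(prefixes)
}

#' Read one annotated recording from a text file pair
#'
#' Inverse of [write_recording()]. The sampling rate is inferred from the
#' `time_s` column unless supplied.
#'
#' @param prefix File path prefix used when writing.
#' @param subject_id Subject identifier to attach; default the prefix
#'   basename.
#' @param fs Sampling rate in Hz; `NULL` infers it from the time column.
#' @param label_map Optional named character vector mapping file labels
#'   onto the seven class labels (e.g. `c("fall front hard" = "Fall")`).
#'   Unmapped labels must already be valid classes.
#' @return An `annotated_recording`.
#' @export
read_recording <- function(prefix, subject_id = basename(prefix), fs = NULL,
                           label_map = NULL) {
  rec_file <- paste0(prefix, "_recording.csv")
  ann_file <- paste0(prefix, "_annotations.csv")
  for (f in c(rec_file, ann_file))
    if (!file.exists(f)) stop("missing input file: ", f)
  rec <- utils::read.csv(rec_file)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(rec)))
    stop(rec_file, ": expected columns ", paste(need, collapse = ", "))
  lens <- vapply(rec[need[-1]], function(col) sum(!is.na(col)), 0L)
  if (length(unique(c(nrow(rec), lens))) != 1)
    stop(rec_file, ": channel lengths differ (",
         paste(lens, collapse = ", "), ")")
  if (is.null(fs)) {
    dt <- diff(rec$time_s)
    if (!length(dt) || any(dt <= 0))
      stop(rec_file, ": cannot infer sampling rate from time_s")
    fs <- 1 / stats::median(dt)
  }
  ann <- utils::read.csv(ann_file, colClasses = c("character", "numeric"))
  if (!all(c("label", "time_s") %in% names(ann)) || !nrow(ann))
    stop(ann_file, ": expected non-empty columns label, time_s")
  if (!is.null(label_map)) {
    hit <- ann$label %in% names(label_map)
    ann$label[hit] <- unname(label_map[ann$label[hit]])
  }
  bad <- which(!ann$label %in% activity_classes())
  if (length(bad))
    stop(ann_file, ": unknown label '", ann$label[bad[1]], "' at row ",
         bad[1], " (provide a label_map)")
  data <- as.matrix(rec[, need[-1]])
  structure(list(recording = new_triaxial_recording(subject_id, fs, data),
                 annotations = ann[, c("label", "time_s")]),
            class = "annotated_recording")
}

#' Load externally supplied recordings from a directory
#'
#' Reads every `*_recording.csv` / `*_annotations.csv` pair under `path`
#' (the package's documented text format), validates channel lengths and
#' annotation labels, and maps labels onto the seven classes through a
#' user-editable label map.
#'
#' @param path Directory containing the file pairs.
#' @param fs Sampling rate, Hz; `NULL` infers it per file.
#' @param label_map Optional named character vector, see
#'   [read_recording()].
#' @return List of `annotated_recording`, sorted by file name.
#' @export
load_external_recordings <- function(path, fs = NULL, label_map = NULL) {
  files <- sort(list.files(path, pattern = "_recording\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no *_recording.csv files found under ", path)
  prefixes <- sub("_recording\\.csv$", "", files)
  lapply(prefixes, function(p)
    read_recording(p, subject_id = basename(p), fs = fs,
                   label_map = label_map))
}

#' Write / read a per-event feature table
#'
#' Tab-separated text with a header row: `subject`, `label`, then one
#' column per feature; values with 9 significant digits.
#'
#' @param features data.frame from [extract_study_features()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, TRUE) & names(out) != "subject"
  out[num] <- lapply(out[num], formatC, digits = 9, format = "g")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

config_defaults <- function() {
  list(simulation = list(n_subjects = 35, rest_gap = c(5, 6),
                         sampling_rate = 50, noise_sd = 0.03,
                         subject_variability = 0.1, fall_scale = 1,
                         seed = 20200706),
       segmentation = list(search_halfwidth_s = 2.5),
       features = list(type = "full"),
       model = list(family = "linear_svm", k = 5, cost = 1),
       evaluation = list(task = "binary", threshold = 0.0002))
}

#' Read / write a pipeline configuration
#'
#' YAML configuration with sections `simulation`, `segmentation`,
#' `features`, `model` and `evaluation`. Missing fields take the documented
#' defaults (the emulated study settings: 50 Hz, 2 s segments, 0.5-5 /
#' 5-10 / 10-20 Hz bands, selection threshold 0.0002); unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- config_defaults()
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    badkey <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(badkey))
      stop("unknown key(s) in section '", sec, "': ",
           paste(badkey, collapse = ", "))
    defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  defaults
}

#' @rdname read_pipeline_config
#' @param config Configuration list to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_to_simulation <- function(cfg) {
  s <- cfg$simulation
  simulation_config(n_subjects = s$n_subjects,
                    events = default_templates(fall_scale = s$fall_scale),
                    rest_gap = unlist(s$rest_gap),
                    sampling_rate = s$sampling_rate, noise_sd = s$noise_sd,
                    subject_variability = s$subject_variability,
                    seed = s$seed)
}
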