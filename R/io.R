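# CSV readers/writers for the pipeline schemas, run configuration and the
# end-to-end driver.

RECORDING_COLUMNS <- c("time", "acc_x", "acc_y", "acc_z",
                       "gyr_x", "gyr_y", "gyr_z",
                       "mag_x", "mag_y", "mag_z",
                       "label", "marker", "qw", "qx", "qy", "qz")

#' Write / read a labeled recording as CSV
#'
#' Column schema:
#' `time,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z,mag_x,mag_y,mag_z,label,marker,qw,qx,qy,qz`
#' (seconds, m/s^2, rad/s, normalized field units; comma-delimited, `.`
#' decimal).  Numeric values round-trip at 15 significant digits.
#'
#' @param rec A `labeled_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `labeled_recording` (subject/location/sample_rate restored
#'   from the data and an optional sidecar written next to the CSV).
#' @export
write_recording <- function(rec, path) {
  stopifnot(all(RECORDING_COLUMNS %in% names(rec)))
  df <- as.data.frame(rec)[, RECORDING_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(subject = attr(rec, "subject"),
               location = attr(rec, "location"),
               sample_rate = attr(rec, "sample_rate"))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, fill = FALSE, check.names = FALSE)
  missing <- setdiff(RECORDING_COLUMNS, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column '", missing[1L], "'")
  df <- df[, RECORDING_COLUMNS]
  df$marker <- as.logical(df$marker)
  metapath <- paste0(path, ".meta.yaml")
  if (file.exists(metapath)) {
    meta <- yaml::read_yaml(metapath)
    attr(df, "subject") <- meta$subject
    attr(df, "location") <- meta$location
    attr(df, "sample_rate") <- meta$sample_rate
  } else if (nrow(df) > 1L) {
    attr(df, "sample_rate") <- 1 / (df$time[2L] - df$time[1L])
  }
  class(df) <- c("labeled_recording", "data.frame")
  df
}

#' Write / read a feature table as CSV with a sidecar tag file
#'
#' @param ft A `feature_table`.
#' @param path CSV path; the feature-set tag goes to `<path>.meta.yaml`.
#' @return `write_features` returns `path` invisibly; `read_features` the
#'   `feature_table`.
#' @export
write_features <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(ft$x, label = ft$label, subject = ft$subject,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(tag = ft$tag, features = colnames(ft$x)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, fill = FALSE, check.names = FALSE)
  for (col in c("label", "subject"))
    if (!col %in% names(df))
      stop("schema error in ", path, ": missing column '", col, "'")
  metapath <- paste0(path, ".meta.yaml")
  tag <- if (file.exists(metapath)) yaml::read_yaml(metapath)$tag
         else NA_character_
  fcols <- setdiff(names(df), c("label", "subject"))
  structure(list(x = as.matrix(df[, fcols, drop = FALSE]),
                 label = as.character(df$label),
                 subject = as.integer(df$subject), tag = tag),
            class = "feature_table")
}

#' Write / read a confusion matrix (CSV counts, JSON metrics)
#'
#' @param cm A `confusion_matrix`.
#' @param path CSV path for the count table (rows = predicted class); the
#'   metric summary goes to `<path>.metrics.json`.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` the
#'   `confusion_matrix`.
#' @export
write_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  df <- data.frame(predicted = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  met <- class_metrics(cm)
  jsonlite::write_json(
    list(overall_accuracy = met$overall, total = met$total,
         per_class = met$per_class[, c("class", "ppv", "fdr",
                                       "recall", "fnr")]),
    paste0(path, ".metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, fill = FALSE, check.names = FALSE)
  if (!"predicted" %in% names(df))
    stop("schema error in ", path, ": missing column 'predicted'")
  m <- as.matrix(df[, setdiff(names(df), "predicted"), drop = FALSE])
  rownames(m) <- df$predicted
  names(dimnames(m)) <- c("predicted", "truth")
  as_confusion(m)
}

#' Run configuration
#'
#' Every parameter of the pipeline with a default, optionally overridden
#' from a YAML file and/or named arguments; a fully default configuration
#' runs end-to-end.
#'
#' @param path Optional YAML file whose keys override the defaults.
#' @param ... Named overrides applied after the file.
#' @return Object of class `har_config` (a named list).
#' @export
har_config <- function(path = NULL, ...) {
  cfg <- list(
    protocol = "full", loops = 5, time_scale = 1,
    subjects = 8, location = "LB",
    acc_noise_std = 0.05, gyr_noise_std = 0.005, mag_noise_std = 0.01,
    gyr_bias = 0.01, sample_rate = 50,
    beta = 0.1, q_init_mode = "algebraic", use_mag = TRUE, zeta = 0,
    tags = c("raw6", "quat4"),
    classifier = "subspace", k = 5, L = 30, n_l = NULL, d_l = NULL,
    seed = 1, out_dir = ".", verbose = FALSE)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    over <- yaml::read_yaml(path)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$subjects >= 1, cfg$beta >= 0, cfg$k >= 1, cfg$L >= 1,
            cfg$sample_rate > 0, cfg$time_scale > 0)
  structure(cfg, class = "har_config")
}

#' Run the recognition pipeline end-to-end
#'
#' Simulate protocol recordings for the configured subjects, estimate
#' attitude on the continuous streams where needed, extract each configured
#' feature set with marker samples dropped, and evaluate with
#' leave-one-subject-out cross-validation.
#'
#' @param config A [har_config()].
#' @return The [compare_feature_sets()] result, with the recordings attached
#'   as attribute `recordings`.
#' @export
run_har_experiment <- function(config = har_config()) {
  stopifnot(inherits(config, "har_config"))
  noise <- sensor_noise_model(config$acc_noise_std, config$gyr_noise_std,
                              config$mag_noise_std, config$gyr_bias,
                              config$sample_rate)
  script <- har_protocol(config$protocol, loops = config$loops,
                         time_scale = config$time_scale)
  if (config$verbose)
    message("simulating ", config$subjects, " subject(s), ",
            nrow(script), " segments, location ", config$location)
  recs <- generate_protocol_dataset(script, subjects = config$subjects,
                                    location = config$location,
                                    noise = noise, seed = config$seed)
  cmp <- compare_feature_sets(recs, tags = config$tags, beta = config$beta,
                              classifier = config$classifier, k = config$k,
                              L = config$L, n_l = config$n_l,
                              d_l = config$d_l, seed = config$seed,
                              verbose = config$verbose)
  attr(cmp, "recordings") <- recs
  cmp
}
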