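# Per-sample feature tables.
#
# Classification is per 50 Hz tick: one row per sample, no windowing, no
# scaling or filtering.  Five feature sets are compared: raw three-axis
# accelerometer (acc3), raw six-axis accelerometer + gyroscope (raw6), the
# two sensor norms (norm), and the attitude features Euler angles (euler3)
# and quaternion (quat4).

FEATURE_TAGS <- c("acc3", "raw6", "norm", "euler3", "quat4")

#' Build a per-sample feature table from a recording
#'
#' @param rec A `labeled_recording`.
#' @param attitude Attitude stream from [estimate_attitude()] (required for
#'   tags `euler3` and `quat4`); must be row-aligned with `rec`.
#' @param tag Feature set: `"acc3"` (acc_x,acc_y,acc_z), `"raw6"` (acc3 +
#'   gyr_x,gyr_y,gyr_z), `"norm"` (|acc|, |gyr|), `"euler3"`
#'   (roll,pitch,yaw) or `"quat4"` (qw,qx,qy,qz).
#' @param drop_marker Drop marker-flagged samples from the returned table.
#'   Attitude must be estimated on the continuous recording *before*
#'   stripping (a gap in the stream has no gyroscope signature, so a filter
#'   run across it starts every segment in a recovery transient); this
#'   argument removes the marker rows after row-aligned feature extraction.
#' @return Object of class `feature_table`: list with `x` (numeric matrix,
#'   one row per sample, named columns), `label` (factor), `subject`
#'   (integer vector) and `tag`.
#' @export
extract_features <- function(rec, attitude = NULL,
                             tag = c("raw6", "acc3", "norm", "euler3", "quat4"),
                             drop_marker = FALSE) {
  tag <- match.arg(tag)
  n <- nrow(rec)
  if (tag %in% c("euler3", "quat4")) {
    if (is.null(attitude))
      stop("feature set '", tag, "' requires an attitude stream")
    if (nrow(attitude) != n)
      stop("attitude stream and recording differ in length")
  }
  x <- switch(tag,
    acc3 = as.matrix(rec[, c("acc_x", "acc_y", "acc_z")]),
    raw6 = as.matrix(rec[, c("acc_x", "acc_y", "acc_z",
                             "gyr_x", "gyr_y", "gyr_z")]),
    norm = {
      a <- sqrt(rec$acc_x^2 + rec$acc_y^2 + rec$acc_z^2)
      g <- sqrt(rec$gyr_x^2 + rec$gyr_y^2 + rec$gyr_z^2)
      cbind(acc_norm = a, gyr_norm = g)
    },
    euler3 = as.matrix(attitude[, c("roll", "pitch", "yaw")]),
    quat4 = as.matrix(attitude[, c("qw", "qx", "qy", "qz")])
  )
  rownames(x) <- NULL
  subject <- attr(rec, "subject")
  if (is.null(subject)) subject <- NA_integer_
  label <- as.character(rec$label)
  keep <- if (drop_marker && !is.null(rec$marker)) !rec$marker
          else rep(TRUE, n)
  structure(list(x = x[keep, , drop = FALSE],
                 label = label[keep],
                 subject = rep(as.integer(subject), sum(keep)),
                 tag = tag),
            class = "feature_table")
}

#' Stack feature tables from several recordings
#'
#' @param tables List of `feature_table` objects sharing the same tag.
#' @return One combined `feature_table`.
#' @export
feature_table_bind <- function(tables) {
  stopifnot(length(tables) >= 1L)
  tags <- unique(vapply(tables, `[[`, "", "tag"))
  if (length(tags) != 1L)
    stop("cannot bind feature tables with different tags: ",
         paste(tags, collapse = ", "))
  structure(list(x = do.call(rbind, lapply(tables, `[[`, "x")),
                 label = unlist(lapply(tables, `[[`, "label")),
                 subject = unlist(lapply(tables, `[[`, "subject")),
                 tag = tags),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> tag=", x$tag, ": ", nrow(x$x), " samples x ",
      ncol(x$x), " features, ", length(unique(x$label)), " classes, ",
      length(unique(x$subject)), " subject(s)\n", sep = "")
  invisible(x)
}
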