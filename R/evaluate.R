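# Confusion-matrix metrics, leave-one-subject-out cross-validation and the
# feature-set comparison experiments.
#
# Metric conventions: rows of the confusion matrix are the predicted class
# ("output class"), columns are the true class ("target class").  Per class,
# the positive predictive value (share of that class's predictions that are
# correct, diag/row-sum) pairs with the false discovery rate, and the recall
# (true positive rate, diag/column-sum) pairs with the false negative rate;
# each pair sums to 100%.  Overall accuracy is trace/total.  Reported
# percentages are rounded half-up to one decimal; raw fractions are kept.

# round half-up to `digits` decimals (round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a confusion matrix
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class name list; defaults to the sorted union of observed
#'   labels.  Labels outside `classes` are an error.
#' @return Object of class `confusion_matrix`: an integer matrix with rows =
#'   predicted class, columns = true class.
#' @export
build_confusion <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("labels outside the class list: ",
                        paste(bad, collapse = ", "))
  cm <- table(predicted = factor(predicted, levels = classes),
              truth = factor(truth, levels = classes))
  cm <- unclass(cm)
  structure(cm, class = "confusion_matrix")
}

#' Wrap a count table as a confusion matrix
#'
#' @param counts Square numeric matrix, rows = predicted class, columns =
#'   true class; dimnames give the classes.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(predicted = seq_len(nrow(counts)),
                             truth = seq_len(ncol(counts)))
  structure(counts, class = "confusion_matrix")
}

#' Per-class and overall confusion-matrix metrics
#'
#' @param cm A `confusion_matrix` (rows = predicted, columns = true).
#' @return Object of class `class_metrics`: list with `per_class` (data
#'   frame with columns `class`, `ppv`, `fdr`, `recall`, `fnr`, in percent
#'   rounded half-up to one decimal, plus `.raw` fractions), `overall`
#'   (percent), `overall_raw` and `total`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  d <- diag(m)
  rs <- rowSums(m); cs <- colSums(m)
  ppv <- ifelse(rs > 0, d / rs, NA_real_)
  rec <- ifelse(cs > 0, d / cs, NA_real_)
  per <- data.frame(class = rownames(m),
                    ppv = round_half_up(100 * ppv),
                    fdr = round_half_up(100 * (1 - ppv)),
                    recall = round_half_up(100 * rec),
                    fnr = round_half_up(100 * (1 - rec)),
                    ppv_raw = ppv, recall_raw = rec,
                    row.names = NULL)
  structure(list(per_class = per,
                 overall = round_half_up(100 * sum(d) / total),
                 overall_raw = sum(d) / total,
                 total = total),
            class = "class_metrics")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = predicted, columns = true\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.class_metrics <- function(x, ...) {
  print(x$per_class[, c("class", "ppv", "fdr", "recall", "fnr")])
  cat(sprintf("overall accuracy: %.1f%% of %d samples\n", x$overall, x$total))
  invisible(x)
}

#' The published three-posture confusion-matrix example
#'
#' The standing/sitting/laying matrix whose printed cells (45,664 standing
#' and 11,046 laying correct; 670 standing-as-sitting; 1,561
#' laying-as-standing; 46,352 standing cases; 50,288 standing predictions;
#' 74,728 samples) anchor the metric definitions.  The cells not printed in
#' the source are chosen consistent with the printed row/column totals and
#' the 91.2% overall accuracy, and are marked here as synthetic fill.
#'
#' @return A 3x3 `confusion_matrix`.
#' @export
worked_example_confusion <- function() {
  cls <- c("standing", "sitting", "laying")
  m <- matrix(c(45664, 3063, 1561,    # predicted standing
                670,   11442, 632,    # predicted sitting
                18,    632,   11046), # predicted laying
              nrow = 3L, byrow = TRUE,
              dimnames = list(predicted = cls, truth = cls))
  as_confusion(m)
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject serves exactly once as the held-out test set; the classifier
#' is trained on all remaining subjects.  Fold confusion matrices are pooled
#' cellwise.
#'
#' @param features A combined `feature_table` covering at least two
#'   subjects (see [feature_table_bind()]).
#' @param classifier `"subspace"` (default) or `"knn"`.
#' @param k,L,n_l,d_l Classifier parameters (see [subspace_train()]); `n_l`
#'   and `d_l` default per fold to the fold's training size and
#'   `ceiling(D/2)`.
#' @param seed Integer seed for the ensemble draws (per-fold substreams).
#' @param verbose Log per-fold accuracy with `message()`.
#' @return Object of class `cv_report`: list with `folds` (per-subject list
#'   of `subject`, `confusion`, `metrics`, `seconds`), `pooled` confusion
#'   matrix, `metrics` on the pooled matrix, `subjects`, and `classifier`
#'   settings.
#' @export
loso_cv <- function(features, classifier = c("subspace", "knn"), k = 5,
                    L = 30, n_l = NULL, d_l = NULL, seed = 1,
                    verbose = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "feature_table"))
  subjects <- sort(unique(features$subject))
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least two subjects")
  classes <- sort(unique(features$label))
  folds <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    test <- features$subject == s
    xtr <- features$x[!test, , drop = FALSE]
    ytr <- features$label[!test]
    xte <- features$x[test, , drop = FALSE]
    yte <- features$label[test]
    t0 <- proc.time()[["elapsed"]]
    pred <- if (classifier == "subspace") {
      ens <- subspace_train(xtr, y = ytr, L = L, n_l = min(n_l %||% nrow(xtr), nrow(xtr)),
                            d_l = d_l %||% ceiling(ncol(xtr) / 2), k = k,
                            seed = .substream_seed(seed, "fold", i))
      subspace_predict(ens, xte)
    } else {
      knn_predict(knn_model(xtr, ytr, k = k), xte)$label
    }
    el <- proc.time()[["elapsed"]] - t0
    cm <- build_confusion(yte, pred, classes)
    if (verbose)
      message(sprintf("fold %d (subject %s): accuracy %.1f%% [%d samples, %.1fs]",
                      i, s, class_metrics(cm)$overall, sum(cm), el))
    list(subject = s, confusion = cm, metrics = class_metrics(cm),
         seconds = el)
  })
  pooled <- as_confusion(Reduce(`+`, lapply(folds, function(f)
    unclass(f$confusion))))
  structure(list(folds = folds, pooled = pooled,
                 metrics = class_metrics(pooled), subjects = subjects,
                 classifier = list(type = classifier, k = k, L = L,
                                   n_l = n_l, d_l = d_l, seed = seed)),
            class = "cv_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", length(x$folds), " leave-one-subject-out folds\n",
      sep = "")
  acc <- vapply(x$folds, function(f) f$metrics$overall, 0)
  cat("fold accuracies (%):", paste(sprintf("%.1f", acc), collapse = " "),
      "\n")
  cat(sprintf("pooled overall accuracy: %.1f%%\n", x$metrics$overall))
  invisible(x)
}

#' Compare feature sets under an identical LOSO pipeline
#'
#' Runs the same leave-one-subject-out evaluation on the same recordings for
#' each requested feature set, extracting attitude features once per
#' recording when needed.  Compute time is informational only.
#'
#' @param recordings List of `labeled_recording`s (one per subject), with
#'   marker segments still present: attitude is estimated on the continuous
#'   stream, and marker samples are dropped afterwards at the feature level.
#' @param tags Feature-set tags to compare (see [extract_features()]).
#' @param beta Fusion gain for attitude estimation.
#' @param ... Passed to [loso_cv()] (classifier, k, L, n_l, d_l, seed).
#' @return Object of class `feature_comparison`: list with `table` (data
#'   frame: tag, n_features, accuracy, per-stair-class recall, seconds) and
#'   `reports` (named list of `cv_report`s).
#' @export
compare_feature_sets <- function(recordings, tags = c("raw6", "quat4"),
                                 beta = 0.1, ...) {
  stopifnot(all(tags %in% FEATURE_TAGS))
  need_att <- any(tags %in% c("euler3", "quat4"))
  att <- if (need_att) lapply(recordings, estimate_attitude, beta = beta)
         else vector("list", length(recordings))
  reports <- list()
  rows <- list()
  for (tg in tags) {
    ft <- feature_table_bind(lapply(seq_along(recordings), function(i)
      extract_features(recordings[[i]], attitude = att[[i]], tag = tg,
                       drop_marker = TRUE)))
    t0 <- proc.time()[["elapsed"]]
    rep <- loso_cv(ft, ...)
    secs <- proc.time()[["elapsed"]] - t0
    pm <- rep$metrics$per_class
    rec_of <- function(cl) if (cl %in% pm$class)
      pm$recall_raw[pm$class == cl] * 100 else NA_real_
    rows[[tg]] <- data.frame(tag = tg, n_features = ncol(ft$x),
                             accuracy = rep$metrics$overall,
                             recall_upstairs = rec_of("upstairs"),
                             recall_downstairs = rec_of("downstairs"),
                             seconds = secs)
    reports[[tg]] <- rep
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reports = reports),
            class = "feature_comparison")
}

#' @export
print.feature_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}
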