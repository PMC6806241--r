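# K-nearest-neighbors and the random-subspace KNN ensemble.
#
# KNN is instance-based: the "model" stores the training rows and defers all
# computation to prediction time.  The ensemble trains L KNN learners, each
# on d_l feature indices drawn with replacement (and optionally n_l training
# rows drawn with replacement), and combines their votes by simple majority.
# The reference prediction path is an exhaustive distance scan; every
# tie-break is deterministic so predictions are replayable bit-for-bit.

#' Euclidean distance between two feature vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("feature vectors differ in dimension: ", length(x), " vs ", length(y))
  sqrt(sum((x - y)^2))
}

#' Store a KNN model
#'
#' @param x Training feature matrix (rows = samples).
#' @param y Training labels (coerced to character).
#' @param k Number of neighbors (default 5); must not exceed the number of
#'   training rows.
#' @return Object of class `knn_model`.
#' @export
knn_model <- function(x, y, k = 5) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) == 0L) stop("empty training set")
  if (nrow(x) != length(y)) stop("x and y differ in length")
  if (k < 1L || k > nrow(x))
    stop("k must be in [1, number of training rows]")
  structure(list(x = x, y = y, k = as.integer(k),
                 classes = sort(unique(y))),
            class = "knn_model")
}

# squared distances from all training rows to a block of query rows;
# computed term-by-term per coordinate to match the definition exactly
.dist2_block <- function(train, query) {
  n <- nrow(train); m <- nrow(query)
  d2 <- matrix(0, n, m)
  for (j in seq_len(ncol(train)))
    d2 <- d2 + (matrix(train[, j], n, m) -
                matrix(query[, j], n, m, byrow = TRUE))^2
  d2
}

#' Predict with a KNN model
#'
#' For each query, the K nearest training rows (ties at the K-th distance
#' resolved toward the smallest training index) vote with equal weight; the
#' class probability is the vote share and the predicted class is the one
#' with the largest probability.  A probability tie goes to the class of the
#' nearest neighbor among the tied classes.
#'
#' @param model A [knn_model()].
#' @param newdata Query feature matrix (or a single feature vector).
#' @param details Also return `nn1`, the label of the single nearest
#'   neighbor per query (used by the ensemble tie-break).
#' @return List with `label` (character vector), `prob` (matrix, one row per
#'   query, one column per training class), and optionally `nn1`.
#' @export
knn_predict <- function(model, newdata, details = FALSE) {
  stopifnot(inherits(model, "knn_model"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(model$x))
    stop("query has ", ncol(newdata), " features; model expects ",
         ncol(model$x))
  m <- nrow(newdata)
  k <- model$k
  cls <- model$classes
  labels <- character(m)
  prob <- matrix(0, m, length(cls), dimnames = list(NULL, cls))
  nn1 <- character(m)
  chunk <- max(1L, floor(4e6 / nrow(model$x)))
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(m, start + chunk - 1L)
    d2 <- .dist2_block(model$x, newdata[idx, , drop = FALSE])
    for (jj in seq_along(idx)) {
      ord <- order(d2[, jj])           # stable: equal distances by index
      nb <- ord[seq_len(k)]
      lab <- model$y[nb]
      counts <- table(factor(lab, levels = cls))
      p <- as.numeric(counts) / k
      prob[idx[jj], ] <- p
      top <- cls[p == max(p)]
      labels[idx[jj]] <- if (length(top) == 1L) top else
        lab[match(TRUE, lab %in% top)]   # nearest neighbor among tied classes
      nn1[idx[jj]] <- lab[1L]
    }
  }
  out <- list(label = labels, prob = prob)
  if (details) out$nn1 <- nn1
  out
}

#' Train a random-subspace KNN ensemble
#'
#' With N training rows and D features, each of the L learners draws `d_l`
#' feature indices uniformly with replacement (duplicates kept as-is) and
#' `n_l` training rows (with replacement by default), then stores a KNN
#' model on that projection.  All draws derive from `seed`, and the
#' per-learner index lists are kept so predictions are replayable.
#'
#' @param features A `feature_table` (or a feature matrix, with `y` given).
#' @param L Number of learners (default 30).
#' @param n_l Training rows per learner (default all N).
#' @param d_l Features drawn per learner (default `ceiling(D / 2)`).
#' @param k Neighbors per learner (default 5).
#' @param seed Integer seed for the index draws.
#' @param replace_rows Draw rows with replacement (default `TRUE`).
#' @param y Training labels when `features` is a plain matrix.
#' @return Object of class `subspace_knn`.
#' @export
subspace_train <- function(features, L = 30, n_l = NULL, d_l = NULL, k = 5,
                           seed = 1, replace_rows = TRUE, y = NULL) {
  if (inherits(features, "feature_table")) {
    x <- features$x; y <- features$label
  } else {
    x <- as.matrix(features)
    if (is.null(y)) stop("labels y required with a plain feature matrix")
  }
  N <- nrow(x); D <- ncol(x)
  if (N == 0L) stop("empty training set")
  if (is.null(n_l)) n_l <- N
  if (is.null(d_l)) d_l <- ceiling(D / 2)
  stopifnot(L >= 1, d_l >= 1, n_l >= 1, n_l <= N)
  set.seed(seed)
  learners <- lapply(seq_len(L), function(l) {
    fidx <- sample.int(D, d_l, replace = TRUE)
    ridx <- if (n_l == N && !replace_rows) seq_len(N)
            else sample.int(N, n_l, replace = replace_rows)
    list(feat_idx = fidx, row_idx = ridx,
         model = knn_model(x[ridx, fidx, drop = FALSE], y[ridx], k = k))
  })
  structure(list(learners = learners, L = L, n_l = n_l, d_l = d_l, k = k,
                 D = D, seed = seed, classes = sort(unique(as.character(y)))),
            class = "subspace_knn")
}

#' Predict with a random-subspace KNN ensemble
#'
#' Each learner projects the query onto its own feature indices and votes
#' its KNN label; the ensemble returns the class chosen the most.  A vote
#' tie goes to the class, among the tied ones, of the first learner's
#' nearest neighbor (falling back to its neighbor ordering, then to the
#' alphabetically first tied class).
#'
#' @param ens A [subspace_train()] ensemble.
#' @param newdata Query matrix with all D original features (or one vector).
#' @return Character vector of predicted labels.
#' @export
subspace_predict <- function(ens, newdata) {
  stopifnot(inherits(ens, "subspace_knn"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ens$D)
    stop("query has ", ncol(newdata), " features; ensemble expects ", ens$D)
  m <- nrow(newdata)
  votes <- matrix(NA_character_, m, ens$L)
  first <- NULL
  for (l in seq_len(ens$L)) {
    lr <- ens$learners[[l]]
    pr <- knn_predict(lr$model, newdata[, lr$feat_idx, drop = FALSE],
                      details = (l == 1L))
    votes[, l] <- pr$label
    if (l == 1L) first <- pr
  }
  cls <- ens$classes
  vapply(seq_len(m), function(i) {
    counts <- table(factor(votes[i, ], levels = cls))
    top <- cls[counts == max(counts)]
    if (length(top) == 1L) return(top)
    if (first$nn1[i] %in% top) return(first$nn1[i])
    top[1L]
  }, character(1L))
}
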