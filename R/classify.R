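#' Pairwise distances between feature rows
#'
#' Euclidean, or the chi-square histogram distance
#' `sum((x - y)^2 / (x + y + eps))` with a small guard in the denominator
#' (histogram features are non-negative, so `x + y = 0` only for empty
#' bins, which then contribute 0).
#'
#' @param features numeric matrix, rows = samples.
#' @param metric `"euclidean"` or `"chi2"`.
#' @param eps denominator guard for chi2.
#' @return symmetric distance matrix with zero diagonal.
#' @export
feature_distances <- function(features, metric = c("euclidean", "chi2"),
                              eps = 1e-10) {
  metric <- match.arg(metric)
  n <- nrow(features)
  if (metric == "euclidean") {
    return(as.matrix(stats::dist(features)))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- features[i, ]
    for (j in (i + 1L):n) {
      xj <- features[j, ]
      v <- sum((xi - xj)^2 / (xi + xj + eps))
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  rownames(d) <- colnames(d) <- rownames(features)
  d
}

pairwise_distance <- function(x, y, metric = c("euclidean", "chi2"),
                              eps = 1e-10) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("feature dimension mismatch")
  if (metric == "euclidean") sqrt(sum((x - y)^2))
  else sum((x - y)^2 / (x + y + eps))
}

#' Leave-one-sample-out KNN evaluation
#'
#' Each sample in turn is held out and classified by majority vote of its
#' `k` nearest remaining samples. Vote ties fall back to the label of the
#' single nearest neighbor; neighbor-distance ties are broken by sample
#' index, so the evaluation is fully deterministic.
#'
#' @param data list with `features` (matrix) and `labels`
#'   (vector, one per row) as returned by [dataset_features()].
#' @param k neighbor count (default 1).
#' @param metric distance passed to [feature_distances()].
#' @return object of class `lddscp_eval`: `accuracy` (fraction of correct
#'   folds), `confusion` (true x predicted count table), and `predictions`
#'   (data.frame with per-fold truth and prediction).
#' @examples
#' f <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
#' ev <- loso_knn_evaluate(list(features = f,
#'                              labels = rep(c("a", "b"), each = 10)))
#' ev$accuracy   # 1 for well-separated clusters
#' @export
loso_knn_evaluate <- function(data, k = 1L, metric = c("euclidean", "chi2")) {
  metric <- match.arg(metric)
  features <- data$features
  labels <- as.character(data$labels)
  n <- nrow(features)
  if (length(labels) != n) stop("labels must match feature rows")
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the sample count")
  d <- feature_distances(features, metric)
  pred <- character(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others], others)]
    nn <- ord[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else labels[ord[1L]]
  }
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, classes), factor(pred, classes),
                     dnn = c("true", "predicted"))
  structure(list(
    accuracy = mean(pred == labels),
    confusion = confusion,
    predictions = data.frame(id = rownames(features) %||% seq_len(n),
                             true = labels, predicted = pred,
                             correct = pred == labels,
                             stringsAsFactors = FALSE),
    k = k, metric = metric), class = "lddscp_eval")
}

#' @export
print.lddscp_eval <- function(x, ...) {
  cat(sprintf("LOSO %d-NN (%s): accuracy %.4f over %d folds\n",
              x$k, x$metric, x$accuracy, nrow(x$predictions)))
  print(x$confusion)
  invisible(x)
}

#' Per-class center features
#'
#' The center sample of a class is its arithmetic mean feature vector
#' (default) or its medoid — the member minimizing the summed distance to
#' the rest of its class.
#'
#' @inheritParams loso_knn_evaluate
#' @param type `"mean"` or `"medoid"`.
#' @return matrix, one row per class (sorted class names as rownames).
#' @export
class_centers <- function(data, type = c("mean", "medoid"),
                          metric = c("euclidean", "chi2")) {
  type <- match.arg(type)
  metric <- match.arg(metric)
  labels <- as.character(data$labels)
  classes <- sort(unique(labels))
  if (any(!nzchar(classes))) stop("empty class label")
  centers <- t(vapply(classes, function(cl) {
    rows <- data$features[labels == cl, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty class: ", cl)
    if (type == "mean") {
      colMeans(rows)
    } else {
      d <- feature_distances(rows, metric)
      rows[which.min(rowSums(d)), ]
    }
  }, numeric(ncol(data$features))))
  rownames(centers) <- classes
  centers
}

#' Class-membership component profile of a sample
#'
#' Inverse-square-distance weights to the class centers, normalized to sum
#' to one: `Ra_i = (1/d_i^2) / sum_j (1/d_j^2)`, where `d_i` is the distance
#' from the sample to class i's center. A sample at distance zero from one
#' or more centers receives all mass there, split equally (the formula's
#' limit convention).
#'
#' @param sample numeric feature vector.
#' @param centers matrix from [class_centers()].
#' @param metric distance name.
#' @return named numeric vector of components, summing to 1.
#' @examples
#' ctr <- rbind(a = c(0, 0), b = c(3, 0))
#' expression_components(c(1, 0), ctr)   # d = (1, 2) -> (0.8, 0.2)
#' @export
expression_components <- function(sample, centers,
                                  metric = c("euclidean", "chi2")) {
  metric <- match.arg(metric)
  if (length(sample) != ncol(centers)) {
    stop("sample/center dimension mismatch")
  }
  d <- apply(centers, 1L, pairwise_distance, y = sample, metric = metric)
  if (any(d == 0)) {
    ra <- as.numeric(d == 0) / sum(d == 0)
  } else {
    w <- 1 / d^2
    ra <- w / sum(w)
  }
  names(ra) <- rownames(centers)
  ra
}
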