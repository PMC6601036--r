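# k-nearest-neighbour classifier (Euclidean metric on standardized
# features). Distance ties are broken by lower training index; vote ties by
# the class of the nearest neighbour.

#' Train a k-NN classifier
#'
#' Stores the (already standardized) training matrix; see
#' [standardize_features()].
#'
#' @param train a `labeled_dataset`.
#' @param k number of neighbours (default 6).
#' @return object of class `knn_model`.
#' @export
train_knn <- function(train, k = 6L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(train$x)) stop("k exceeds training-set size")
  structure(list(x = train$x, y = train$y, k = k,
                 feature_names = colnames(train$x)),
            class = "knn_model")
}

#' Predict with k-NN
#'
#' Majority vote of the k nearest training compounds; the score is the
#' fraction of actives among the k neighbours. Predicted label is +1 when
#' the score exceeds 0.5; an exact vote tie is resolved to the class of the
#' nearest neighbour.
#'
#' @param object a `knn_model`.
#' @param newdata feature matrix or `labeled_dataset` (standardized with the
#'   training parameters).
#' @param ... unused.
#' @return data.frame with columns `id`, `label`, `score`.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  x <- .model_matrix(object, newdata)
  n <- nrow(x); k <- object$k
  label <- integer(n); score <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(object$x) - x[i, ])^2)
    nb <- order(d2)[seq_len(k)]   # stable order: distance then training index
    pos <- sum(object$y[nb] == 1L)
    score[i] <- pos / k
    label[i] <- if (pos * 2L == k) object$y[nb[1]] else if (pos * 2L > k) 1L else -1L
  }
  data.frame(id = if (inherits(newdata, "labeled_dataset")) newdata$ids
                  else rownames(x) %||% paste0("row", seq_len(n)),
             label = label, score = score, stringsAsFactors = FALSE)
}

#' @rdname predict.knn_model
#' @param model a `knn_model`.
#' @export
knn_predict <- function(model, newdata) predict(model, newdata)
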