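# C4.5-style decision tree: binary threshold splits on continuous features
# chosen by gain ratio, with pessimistic (confidence-bound) error pruning.

.entropy <- function(pos, n) {
  if (n == 0L || pos == 0L || pos == n) return(0)
  p <- pos / n
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# best gain-ratio split over all features/thresholds; NULL if no split with
# positive information gain exists
.c45_best_split <- function(X, y01, idx) {
  n <- length(idx); pos <- sum(y01[idx])
  parent <- .entropy(pos, n)
  best <- NULL; best_ratio <- 1e-12
  for (f in seq_len(ncol(X))) {
    xs <- X[idx, f]; o <- order(xs); sx <- xs[o]
    cut_ok <- sx[-n] < sx[-1]
    if (!any(cut_ok)) next
    cpos <- cumsum(y01[idx][o])[-n]
    nl <- seq_len(n - 1); nr <- n - nl
    gain <- parent - vapply(which(cut_ok), function(k)
      (nl[k] * .entropy(cpos[k], nl[k]) + nr[k] * .entropy(pos - cpos[k], nr[k])) / n,
      numeric(1))
    ks <- which(cut_ok)
    split_info <- -(nl[ks] / n) * log2(nl[ks] / n) - (nr[ks] / n) * log2(nr[ks] / n)
    ratio <- ifelse(gain > 1e-12, gain / split_info, -Inf)
    j <- which.max(ratio)
    if (ratio[j] > best_ratio) {
      best_ratio <- ratio[j]
      k <- ks[j]
      best <- list(f = f, thr = (sx[k] + sx[k + 1]) / 2)
    }
  }
  best
}

# Clopper-Pearson-style upper confidence limit on the error rate of a leaf
# with E errors out of N, at confidence CF (C4.5's pessimistic estimate)
.ucf <- function(E, N, CF) {
  if (N == 0L) return(1)
  stats::qbeta(1 - CF, E + 1, N - E)
}

.c45_grow <- function(X, y01, idx) {
  n <- length(idx); pos <- sum(y01[idx])
  leaf <- function() list(leaf = TRUE, n = n, pos = pos,
                          class = if (pos * 2L > n) 1L else -1L)
  if (pos == 0L || pos == n || n < 2L) return(leaf())
  sp <- .c45_best_split(X, y01, idx)
  if (is.null(sp)) return(leaf())
  gl <- X[idx, sp$f] <= sp$thr
  list(leaf = FALSE, f = sp$f, thr = sp$thr, n = n, pos = pos,
       class = if (pos * 2L > n) 1L else -1L,
       left = .c45_grow(X, y01, idx[gl]), right = .c45_grow(X, y01, idx[!gl]))
}

# pessimistic-error subtree replacement
.c45_prune <- function(node, CF) {
  if (node$leaf) return(node)
  node$left <- .c45_prune(node$left, CF)
  node$right <- .c45_prune(node$right, CF)
  est <- function(nd) {
    if (nd$leaf) {
      E <- if (nd$class == 1L) nd$n - nd$pos else nd$pos
      nd$n * .ucf(E, nd$n, CF)
    } else est(nd$left) + est(nd$right)
  }
  E_here <- if (node$class == 1L) node$n - node$pos else node$pos
  if (node$n * .ucf(E_here, node$n, CF) <= est(node) + 1e-9)
    return(list(leaf = TRUE, n = node$n, pos = node$pos, class = node$class))
  node
}

#' Train a C4.5-style decision tree
#'
#' @param train a `labeled_dataset` with both classes present.
#' @param pruning_confidence confidence level CF of the pessimistic pruning
#'   step (C4.5's default 0.25); smaller values prune harder.
#' @return object of class `c45_model`.
#' @export
train_c45 <- function(train, pruning_confidence = 0.25) {
  if (length(unique(train$y)) < 2L) stop("C4.5 training needs both classes")
  y01 <- train$y == 1L
  root <- .c45_grow(train$x, y01, seq_len(nrow(train$x)))
  root <- .c45_prune(root, pruning_confidence)
  structure(list(root = root, pruning_confidence = pruning_confidence,
                 feature_names = colnames(train$x)),
            class = "c45_model")
}

#' Predict with a C4.5-style tree
#'
#' Walks each compound from the root to a leaf; the score is the
#' Laplace-smoothed fraction of actives in the leaf, the label the leaf
#' class (+1 only when actives form a strict majority).
#'
#' @param object a `c45_model`.
#' @param newdata feature matrix or `labeled_dataset`.
#' @param ... unused.
#' @return data.frame with columns `id`, `label`, `score`.
#' @export
predict.c45_model <- function(object, newdata, ...) {
  x <- .model_matrix(object, newdata)
  one <- function(v) {
    nd <- object$root
    while (!nd$leaf) nd <- if (v[nd$f] <= nd$thr) nd$left else nd$right
    c(nd$class, (nd$pos + 1) / (nd$n + 2))
  }
  res <- t(apply(x, 1, one))
  data.frame(id = if (inherits(newdata, "labeled_dataset")) newdata$ids
                  else rownames(x) %||% paste0("row", seq_len(nrow(x))),
             label = as.integer(res[, 1]), score = res[, 2],
             stringsAsFactors = FALSE)
}

#' @rdname predict.c45_model
#' @param model a `c45_model`.
#' @export
c45_predict <- function(model, newdata) predict(model, newdata)
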