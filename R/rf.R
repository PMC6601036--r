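# Random forest, written out in full: bootstrap-sampled unpruned CART trees
# with Gini splits over M_try randomly preselected features per node,
# consensus voting, out-of-bag (OOB) error bookkeeping, the two-stage
# M_try/N_tree tuning scan, and OOB permutation importance.
#
# Determinism: every tree draws its bootstrap sample and per-node feature
# subsets from a private RNG stream seeded as a fixed function of
# (forest seed, tree index), so a forest with N trees is the exact prefix
# of a forest with N' > N trees at the same seed -- which the N_tree tuning
# scan exploits.

.tree_seed <- function(seed, t) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(t) * 12345) %% 2147483629)
}

# Gini-best split of rows `idx` over candidate features `feats`.
# Ties: first feature in the (already randomised) candidate order wins,
# then the lowest threshold.
.best_split <- function(X, y01, idx, feats) {
  n <- length(idx)
  pos <- sum(y01[idx])
  parent <- 1 - (pos / n)^2 - ((n - pos) / n)^2
  best <- NULL; best_gain <- 1e-12
  for (f in feats) {
    xs <- X[idx, f]
    o <- order(xs)
    sx <- xs[o]
    cut_ok <- sx[-n] < sx[-1]
    if (!any(cut_ok)) next
    cpos <- cumsum(y01[idx][o])[-n]
    nl <- seq_len(n - 1)
    gl <- 1 - (cpos / nl)^2 - ((nl - cpos) / nl)^2
    nr <- n - nl
    rpos <- pos - cpos
    gr <- 1 - (rpos / nr)^2 - ((nr - rpos) / nr)^2
    gain <- parent - (nl * gl + nr * gr) / n
    gain[!cut_ok] <- -Inf
    k <- which.max(gain)
    if (gain[k] > best_gain) {
      best_gain <- gain[k]
      best <- list(f = f, thr = (sx[k] + sx[k + 1]) / 2)
    }
  }
  best
}

# grow one unpruned CART tree to purity (minimum node size 1)
.grow_cart <- function(X, y, idx, M_try) {
  y01 <- y == 1L
  p <- ncol(X)
  var <- integer(0); thr <- numeric(0); left <- integer(0)
  right <- integer(0); pred <- integer(0)
  new_node <- function() {
    var[length(var) + 1L] <<- NA_integer_; thr[length(thr) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_; right[length(right) + 1L] <<- NA_integer_
    pred[length(pred) + 1L] <<- NA_integer_
    length(var)
  }
  root <- new_node()
  stack <- list(list(node = root, idx = idx))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    ni <- top$idx
    pos <- sum(y01[ni]); n <- length(ni)
    sp <- if (pos == 0L || pos == n) NULL else
      .best_split(X, y01, ni, sample.int(p, min(M_try, p)))
    if (is.null(sp)) {
      # leaf: majority class, exact tie -> -1 (predict inactive)
      pred[top$node] <- if (pos * 2L > n) 1L else -1L
      next
    }
    var[top$node] <- sp$f; thr[top$node] <- sp$thr
    go_left <- X[ni, sp$f] <= sp$thr
    l <- new_node(); r <- new_node()
    left[top$node] <- l; right[top$node] <- r
    stack[[length(stack) + 1L]] <- list(node = l, idx = ni[go_left])
    stack[[length(stack) + 1L]] <- list(node = r, idx = ni[!go_left])
  }
  list(var = var, thr = thr, left = left, right = right, pred = pred)
}

# class predictions (+1/-1) of one tree for all rows of X
.tree_predict <- function(tree, X) {
  out <- integer(nrow(X))
  stack <- list(list(node = 1L, rows = seq_len(nrow(X))))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nd <- top$node; rows <- top$rows
    if (!length(rows)) next
    if (!is.na(tree$pred[nd])) { out[rows] <- tree$pred[nd]; next }
    gl <- X[rows, tree$var[nd]] <= tree$thr[nd]
    stack[[length(stack) + 1L]] <- list(node = tree$left[nd], rows = rows[gl])
    stack[[length(stack) + 1L]] <- list(node = tree$right[nd], rows = rows[!gl])
  }
  out
}

#' Train a random forest
#'
#' Grows `N_tree` unpruned CART trees on bootstrap samples of the training
#' data; each node split considers `M_try` uniformly sampled features and
#' uses the Gini criterion. Out-of-bag vote tallies are accumulated during
#' training. A single-class training set yields a trivial constant model
#' with a warning.
#'
#' @param train a `labeled_dataset` (no missing values; see
#'   [impute_missing()]).
#' @param M_try features sampled per split; default `floor(sqrt(p))`.
#' @param N_tree number of trees.
#' @param seed integer seed; fixes the forest bit-for-bit.
#' @return object of class `rf_model`.
#' @export
train_random_forest <- function(train, M_try = NULL, N_tree = 500L, seed = 1L) {
  X <- train$x; y <- train$y
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X)) stop("training matrix contains missing values; impute first")
  if (is.null(M_try)) M_try <- max(1L, floor(sqrt(p)))
  stopifnot(M_try >= 1L, M_try <= p, N_tree >= 1L)
  constant <- length(unique(y)) == 1L
  if (constant) warning("single-class training set: returning constant model")
  trees <- vector("list", N_tree)
  inbag <- vector("list", N_tree)
  oob_pos <- integer(n); oob_tot <- integer(n)
  for (t in seq_len(N_tree)) {
    set.seed(.tree_seed(seed, t))
    bag <- sample.int(n, n, replace = TRUE)
    inbag[[t]] <- bag
    tree <- if (constant)
      list(var = NA_integer_, thr = NA_real_, left = NA_integer_,
           right = NA_integer_, pred = y[1])
    else .grow_cart(X, y, bag, M_try)
    trees[[t]] <- tree
    oob <- setdiff(seq_len(n), bag)
    if (length(oob)) {
      pr <- .tree_predict(tree, X[oob, , drop = FALSE])
      oob_pos[oob] <- oob_pos[oob] + (pr == 1L)
      oob_tot[oob] <- oob_tot[oob] + 1L
    }
  }
  structure(list(trees = trees, inbag = inbag, M_try = M_try, N_tree = N_tree,
                 seed = seed, feature_names = colnames(X),
                 oob_pos = oob_pos, oob_tot = oob_tot, y_train = y,
                 n_train = n),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model: %d trees, M_try = %d, %d training samples, OOB error %.4f>\n",
              x$N_tree, x$M_try, x$n_train, rf_oob_error(x)))
  invisible(x)
}

# align a feature matrix (or labeled_dataset) with the model's columns
.model_matrix <- function(model, newdata) {
  x <- if (inherits(newdata, "labeled_dataset")) newdata$x else as.matrix(newdata)
  if (!is.null(model$feature_names) && !is.null(colnames(x)))
    x <- x[, model$feature_names, drop = FALSE]
  x
}

#' Predict with a random forest
#'
#' Consensus vote over all trees. The relative probability score is the
#' fraction of trees voting active (+1); the label is the majority vote,
#' with exact ties (even forests) resolved to -1, the conservative
#' screening default.
#'
#' @param object an `rf_model`.
#' @param newdata feature matrix or `labeled_dataset`.
#' @param ... unused.
#' @return data.frame with columns `id`, `label`, `score`.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  x <- .model_matrix(object, newdata)
  votes <- integer(nrow(x))
  for (tree in object$trees) votes <- votes + (.tree_predict(tree, x) == 1L)
  score <- votes / object$N_tree
  data.frame(id = if (inherits(newdata, "labeled_dataset")) newdata$ids
                  else rownames(x) %||% paste0("row", seq_len(nrow(x))),
             label = ifelse(score > 0.5, 1L, -1L),
             score = score, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname predict.rf_model
#' @param model an `rf_model`.
#' @export
rf_predict <- function(model, newdata) predict(model, newdata)

#' Out-of-bag prediction error rate
#'
#' Misclassification rate over training samples using only the votes of
#' trees whose bootstrap bag excluded the sample; samples that were never
#' out of bag are excluded from the denominator.
#'
#' @param model an `rf_model`.
#' @param train ignored (tallies are stored in the model); accepted for
#'   call-site symmetry with [test_per()].
#' @return error rate in `[0, 1]`.
#' @export
rf_oob_error <- function(model, train = NULL) {
  cov <- model$oob_tot > 0L
  if (!any(cov)) stop("no training sample has OOB coverage; increase N_tree")
  score <- model$oob_pos[cov] / model$oob_tot[cov]
  pred <- ifelse(score > 0.5, 1L, -1L)
  mean(pred != model$y_train[cov])
}

#' Test-set prediction error rate
#'
#' Fraction of test compounds misclassified by the full-forest vote.
#'
#' @param model a trained classifier with a `predict` method.
#' @param test a `labeled_dataset`.
#' @return error rate in `[0, 1]`.
#' @export
test_per <- function(model, test) {
  stopifnot(nrow(test$x) > 0L)
  mean(predict(model, test)$label != test$y)
}

#' Winner of a tuning scan under the documented tie-break rules
#'
#' Selects the row minimising the test-set error rate; ties are broken by
#' lower training-set OOB error, then by the smaller parameter value
#' (larger forests only cost computation).
#'
#' @param scan data.frame with a parameter column plus `test_per` and
#'   `train_oob_per`.
#' @param param name of the parameter column being scanned.
#' @return the winning parameter value.
#' @export
select_tuning_winner <- function(scan, param = "N_tree") {
  stopifnot(nrow(scan) > 0L, param %in% names(scan))
  scan[[param]][order(scan$test_per, scan$train_oob_per, scan[[param]])][1]
}

#' Two-stage OOB-driven tuning of M_try and N_tree
#'
#' Stage 1 scans `M_try_grid` at a fixed reference forest size
#' (`N_tree_ref`), minimising the test-set prediction error rate. Stage 2
#' fixes the winning M_try and scans `N_tree_grid` (evaluated as nested
#' prefixes of one large forest, which the per-tree seeding makes exact).
#' Ties are broken by lower training-set OOB error, then by the smaller
#' parameter value (smaller forests are cheaper).
#'
#' @param train,test `labeled_dataset`s.
#' @param M_try_grid,N_tree_grid integer grids (non-empty).
#' @param seed forest seed.
#' @param N_tree_ref reference forest size for stage 1.
#' @return list `M_try`, `N_tree`, `scan` (one row per grid point with test
#'   and training-OOB error rates, for histogram-style inspection).
#' @export
tune_rf <- function(train, test, M_try_grid, N_tree_grid, seed = 1L,
                    N_tree_ref = 500L) {
  if (!length(M_try_grid) || !length(N_tree_grid)) stop("empty tuning grid")
  M_try_grid <- sort(unique(as.integer(M_try_grid)))
  N_tree_grid <- sort(unique(as.integer(N_tree_grid)))
  scan <- NULL
  s1 <- data.frame(M_try = M_try_grid, N_tree = N_tree_ref,
                   test_per = NA_real_, train_oob_per = NA_real_)
  for (i in seq_along(M_try_grid)) {
    m <- train_random_forest(train, M_try = M_try_grid[i],
                             N_tree = N_tree_ref, seed = seed)
    s1$test_per[i] <- test_per(m, test)
    s1$train_oob_per[i] <- rf_oob_error(m)
  }
  best_M <- select_tuning_winner(s1, "M_try")

  # stage 2: one forest of max(N_tree_grid) trees, prefix evaluation
  N_max <- max(N_tree_grid)
  model <- train_random_forest(train, M_try = best_M, N_tree = N_max, seed = seed)
  n_te <- nrow(test$x); n_tr <- nrow(train$x)
  te_votes <- integer(n_te)
  oob_pos <- integer(n_tr); oob_tot <- integer(n_tr)
  s2 <- data.frame(M_try = best_M, N_tree = N_tree_grid,
                   test_per = NA_real_, train_oob_per = NA_real_)
  gi <- 1L
  Xte <- .model_matrix(model, test)
  for (t in seq_len(N_max)) {
    te_votes <- te_votes + (.tree_predict(model$trees[[t]], Xte) == 1L)
    oob <- setdiff(seq_len(n_tr), model$inbag[[t]])
    if (length(oob)) {
      pr <- .tree_predict(model$trees[[t]], train$x[oob, , drop = FALSE])
      oob_pos[oob] <- oob_pos[oob] + (pr == 1L)
      oob_tot[oob] <- oob_tot[oob] + 1L
    }
    while (gi <= length(N_tree_grid) && N_tree_grid[gi] == t) {
      lab_te <- ifelse(te_votes / t > 0.5, 1L, -1L)
      s2$test_per[gi] <- mean(lab_te != test$y)
      cov <- oob_tot > 0L
      lab_tr <- ifelse(oob_pos[cov] / oob_tot[cov] > 0.5, 1L, -1L)
      s2$train_oob_per[gi] <- mean(lab_tr != train$y[cov])
      gi <- gi + 1L
    }
  }
  best_N <- select_tuning_winner(s2, "N_tree")
  scan <- rbind(cbind(stage = 1L, s1), cbind(stage = 2L, s2))
  list(M_try = best_M, N_tree = best_N, scan = scan)
}

#' OOB permutation importance
#'
#' For every feature and tree, permutes the feature's values among that
#' tree's out-of-bag samples and records the drop in OOB accuracy; the
#' importance is the mean drop over trees (optionally averaged over
#' repeated permutations).
#'
#' @param model an `rf_model`.
#' @param train the `labeled_dataset` the model was trained on.
#' @param seed RNG seed for the permutations.
#' @param n_repeats permutations averaged per tree/feature.
#' @return data.frame `feature`, `importance`, sorted descending.
#' @export
rf_feature_importance <- function(model, train, seed = 1L, n_repeats = 1L) {
  X <- .model_matrix(model, train); y <- train$y
  p <- ncol(X)
  drops <- matrix(0, model$N_tree, p)
  set.seed(.tree_seed(seed, 982451653))
  for (t in seq_len(model$N_tree)) {
    oob <- setdiff(seq_len(nrow(X)), model$inbag[[t]])
    if (length(oob) < 2L) next
    Xo <- X[oob, , drop = FALSE]
    base_acc <- mean(.tree_predict(model$trees[[t]], Xo) == y[oob])
    for (f in seq_len(p)) {
      acc <- 0
      for (r in seq_len(n_repeats)) {
        Xp <- Xo
        Xp[, f] <- Xp[sample.int(length(oob)), f]
        acc <- acc + mean(.tree_predict(model$trees[[t]], Xp) == y[oob])
      }
      drops[t, f] <- base_acc - acc / n_repeats
    }
  }
  imp <- colMeans(drops)
  out <- data.frame(feature = colnames(X) %||% paste0("V", seq_len(p)),
                    importance = imp, stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Top-n features from an importance ranking
#'
#' @param importance data.frame from [rf_feature_importance()].
#' @param n number of features to keep.
#' @return character vector of feature names.
#' @export
select_top <- function(importance, n = 10L) {
  utils::head(importance$feature, n)
}
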