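# Labeled datasets: feature matrix in registry column order, class labels
# in {+1 = active, -1 = inactive}, compound ids. Imputation and z-scoring
# always derive their parameters from the training portion only.

#' Construct a labeled dataset
#'
#' @param x numeric matrix or data.frame of features (rows = compounds).
#' @param labels integer vector in `{+1, -1}`.
#' @param ids optional compound identifiers.
#' @return object of class `labeled_dataset` with fields `x`, `y`, `ids`.
#' @export
labeled_dataset <- function(x, labels, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  if (nrow(x) != length(labels)) stop("feature rows and labels differ in length")
  if (is.null(ids)) ids <- paste0("cmpd", seq_len(nrow(x)))
  structure(list(x = x, y = labels, ids = as.character(ids)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d compounds x %d features; %d active / %d inactive>\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == -1L)))
  invisible(x)
}

#' Join a descriptor table with an activity table
#'
#' @param tab descriptor data.frame (`id` column plus features), as from
#'   [compute_descriptors()] or [read_descriptor_table()].
#' @param activity data.frame with columns `id` and `label` (+1/-1).
#' @return a `labeled_dataset` over the ids present in both tables.
#' @export
dataset_from_table <- function(tab, activity) {
  keep <- intersect(tab$id, activity$id)
  if (!length(keep)) stop("no overlapping ids between descriptors and activity table")
  t2 <- tab[match(keep, tab$id), , drop = FALSE]
  a2 <- activity[match(keep, activity$id), , drop = FALSE]
  labeled_dataset(t2[, setdiff(names(t2), "id"), drop = FALSE], a2$label, keep)
}

.subset_dataset <- function(d, idx) {
  out <- labeled_dataset(d$x[idx, , drop = FALSE], d$y[idx], d$ids[idx])
  out
}

#' Stratified train/test split
#'
#' Randomly splits a dataset, stratified by class: each class contributes
#' `round(train_fraction * n_class)` compounds to the training set.
#' Reproducible for a fixed seed; the two parts are disjoint and their union
#' is the input.
#'
#' @param d a `labeled_dataset`.
#' @param train_fraction fraction assigned to training (default 2/3).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(d, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (any(table(d$y) < 2L)) stop("each class needs at least 2 members to split")
  set.seed(seed)
  tr <- integer(0)
  for (cl in sort(unique(d$y))) {
    idx <- which(d$y == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    tr <- c(tr, sample(idx, n_tr))
  }
  tr <- sort(tr)
  list(train = .subset_dataset(d, tr),
       test = .subset_dataset(d, setdiff(seq_len(nrow(d$x)), tr)))
}

#' Impute masked feature values with training-set medians
#'
#' Columns that are entirely missing in the training set cannot be imputed
#' and are dropped from both sets.
#'
#' @param train training `labeled_dataset`.
#' @param test optional second dataset imputed with the training medians.
#' @return list `train`, `test` (NULL if absent), `medians`.
#' @export
impute_missing <- function(train, test = NULL) {
  med <- apply(train$x, 2, stats::median, na.rm = TRUE)
  keep <- !is.na(med)
  fill <- function(d) {
    x <- d$x[, keep, drop = FALSE]
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- med[keep][j]
    }
    labeled_dataset(x, d$y, d$ids)
  }
  list(train = fill(train), test = if (!is.null(test)) fill(test),
       medians = med[keep])
}

#' Z-score features using training statistics
#'
#' Centres and scales both sets with the training mean and standard
#' deviation; zero-variance training columns are dropped from both sets.
#'
#' @param train training `labeled_dataset`.
#' @param test optional dataset transformed with the training parameters.
#' @return list `train`, `test` (NULL if absent), `params` (mean, sd, kept
#'   column names).
#' @export
standardize_features <- function(train, test = NULL) {
  mu <- colMeans(train$x)
  sdv <- apply(train$x, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  tf <- function(d) {
    x <- sweep(sweep(d$x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
    labeled_dataset(x, d$y, d$ids)
  }
  params <- list(mean = mu[keep], sd = sdv[keep], columns = colnames(train$x)[keep])
  list(train = tf(train), test = if (!is.null(test)) tf(test), params = params)
}

# apply stored standardization parameters to a raw feature matrix
.apply_scaling <- function(x, params) {
  x <- x[, params$columns, drop = FALSE]
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}
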