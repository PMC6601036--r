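# Soft-margin SVM with Gaussian RBF kernel, trained by sequential minimal
# optimization (SMO). The kernel is parameterized by its width sigma,
# k(x, y) = exp(-||x - y||^2 / (2 sigma^2)), so k(x, x) = 1. The working
# pair is chosen deterministically (first KKT violator in index order,
# partner maximising |E_i - E_j|), so a fit is reproducible without any RNG.

.rbf_kernel <- function(A, B, sigma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Train an RBF-kernel SVM by SMO
#'
#' Solves the soft-margin dual to the stated KKT tolerance. Inputs are
#' expected to be standardized (see [standardize_features()]).
#'
#' @param train a `labeled_dataset`.
#' @param sigma RBF kernel width (> 0); default 0.2.
#' @param C box constraint (> 0).
#' @param tol KKT violation tolerance.
#' @param max_passes maximum full passes without progress before declaring
#'   convergence; exceeding `max_iter` total passes raises an error.
#' @param max_iter hard cap on passes over the data.
#' @return object of class `svm_model` with support coefficients and bias.
#' @export
train_svm <- function(train, sigma = 0.2, C = 1, tol = 1e-3,
                      max_passes = 2L, max_iter = 2000L) {
  stopifnot(sigma > 0, C > 0)
  X <- train$x; y <- as.numeric(train$y)
  n <- nrow(X)
  K <- .rbf_kernel(X, X, sigma)
  alpha <- numeric(n); b <- 0
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  passes <- 0L; iter <- 0L
  while (passes < max_passes) {
    if (iter >= max_iter)
      stop(sprintf("SMO did not converge within %d passes (sigma=%g, C=%g)",
                   max_iter, sigma, C))
    iter <- iter + 1L
    changed <- 0L
    E <- fcache() - y
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * y) + b - y[i]
      if (!((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)))
        next
      Eall <- as.numeric(K %*% (alpha * y)) + b - y
      # partners in decreasing |E_i - E_j| order; fall through degenerate
      # pairs (eta = 0, e.g. duplicated rows) instead of stalling
      for (j in order(-abs(Ei - Eall), seq_len(n))) {
        if (j == i) next
        Ej <- Eall[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (H - L < 1e-12) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= -1e-12) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] - y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] - y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        changed <- changed + 1L
        break
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  sv <- alpha > 1e-8
  structure(list(sv_x = X[sv, , drop = FALSE], sv_y = y[sv],
                 alpha = alpha[sv], b = b, sigma = sigma, C = C,
                 feature_names = colnames(X), n_sv = sum(sv)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model: RBF sigma = %g, C = %g, %d support vectors>\n",
              x$sigma, x$C, x$n_sv))
  invisible(x)
}

# decision values f(x)
.svm_decision <- function(model, x) {
  if (!model$n_sv) return(rep(model$b, nrow(x)))
  K <- .rbf_kernel(x, model$sv_x, model$sigma)
  as.numeric(K %*% (model$alpha * model$sv_y)) + model$b
}

#' Predict with an SVM
#'
#' Label is the sign of the decision value (0 resolved to -1); the score is
#' a logistic map `1/(1 + exp(-f))` of the margin, used only for ranking.
#'
#' @param object an `svm_model`.
#' @param newdata feature matrix or `labeled_dataset` (standardized with the
#'   training parameters).
#' @param ... unused.
#' @return data.frame with columns `id`, `label`, `score`.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  x <- .model_matrix(object, newdata)
  f <- .svm_decision(object, x)
  data.frame(id = if (inherits(newdata, "labeled_dataset")) newdata$ids
                  else rownames(x) %||% paste0("row", seq_len(nrow(x))),
             label = ifelse(f > 0, 1L, -1L),
             score = 1 / (1 + exp(-f)), stringsAsFactors = FALSE)
}

#' @rdname predict.svm_model
#' @param model an `svm_model`.
#' @export
svm_predict <- function(model, newdata) predict(model, newdata)
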