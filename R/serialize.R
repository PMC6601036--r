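# JSON serialization of trained models (format version 1). Trees are stored
# as flat parallel arrays, SVM coefficients as numeric vectors; everything
# round-trips exactly through jsonlite with digits = NA.

.SERIAL_VERSION <- 1L

#' Save / load a trained model as JSON
#'
#' Supports `rf_model`, `knn_model`, `c45_model` and `svm_model`. The
#' container records a format version and the model class; loading restores
#' an object functionally identical to the saved one.
#'
#' @param model a trained model.
#' @param path JSON path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("rf_model", "knn_model", "c45_model", "svm_model"))
    stop("unsupported model class: ", cls)
  payload <- list(format_version = .SERIAL_VERSION, model_class = cls,
                  model = unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format_version) || payload$format_version > .SERIAL_VERSION)
    stop("unsupported model file format")
  m <- payload$model
  cls <- payload$model_class
  if (cls == "rf_model") {
    m$trees <- lapply(seq_along(m$trees$var), function(i)
      list(var = as.integer(m$trees$var[[i]]), thr = as.numeric(m$trees$thr[[i]]),
           left = as.integer(m$trees$left[[i]]), right = as.integer(m$trees$right[[i]]),
           pred = as.integer(m$trees$pred[[i]])))
    m$inbag <- lapply(m$inbag, as.integer)
    m$y_train <- as.integer(m$y_train)
  }
  if (cls == "knn_model") { m$x <- as.matrix(m$x); m$y <- as.integer(m$y) }
  if (cls == "svm_model") m$sv_x <- as.matrix(m$sv_x)
  if (cls == "c45_model") m$root <- .relist_c45(m$root)
  if (!is.null(m$feature_names)) {
    if (cls == "knn_model") colnames(m$x) <- m$feature_names
    if (cls == "svm_model") colnames(m$sv_x) <- m$feature_names
  }
  structure(m, class = cls)
}

.relist_c45 <- function(nd) {
  nd$leaf <- isTRUE(nd$leaf)
  if (!nd$leaf) {
    nd$left <- .relist_c45(nd$left); nd$right <- .relist_c45(nd$right)
  }
  nd
}
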