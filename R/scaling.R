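#' Column scaling with a reusable transformation record
#'
#' `autoscale()` mean-centres each column and divides by its SD (unit
#' variance); `range_scale()` maps each column to \[0, 1\] via its min and
#' max. Both record the training-set parameters so held-out samples can be
#' transformed identically with [apply_scaling()] — scaling is always fit
#' on training data only. Transformations compose: passing an already
#' scaled `feature_matrix` appends a step to its record (the supervised
#' Kohonen workflow autoscales and then range-scales).
#'
#' Constant columns carry no information and cannot be scaled; they are
#' dropped with a warning (or rejected with `strict = TRUE`).
#'
#' @param x Numeric matrix, or a `feature_matrix` to compose onto.
#' @param strict Error instead of dropping constant columns.
#' @return A `feature_matrix`: list with `X` (scaled matrix) and `scaling`
#'   (list of transformation steps).
#' @export
autoscale <- function(x, strict = FALSE) {
  fm <- as_feature_matrix(x)
  m <- drop_constant(fm$X, strict)
  step <- list(method = "autoscale", center = colMeans(m),
               scale = apply(m, 2, stats::sd))
  fm$X <- sweep(sweep(m, 2, step$center), 2, step$scale, "/")
  fm$scaling <- c(fm$scaling, list(step))
  fm
}

#' @rdname autoscale
#' @export
range_scale <- function(x, strict = FALSE) {
  fm <- as_feature_matrix(x)
  m <- drop_constant(fm$X, strict)
  step <- list(method = "range", min = apply(m, 2, min),
               range = apply(m, 2, max) - apply(m, 2, min))
  fm$X <- sweep(sweep(m, 2, step$min), 2, step$range, "/")
  fm$scaling <- c(fm$scaling, list(step))
  fm
}

#' Apply a recorded scaling to new samples
#'
#' @param scaling Scaling record (`fm$scaling` or a `feature_matrix`).
#' @param newx Matrix (or vector, one sample) on the original scale, with
#'   the training variables (matched by name when available).
#' @return Scaled matrix.
#' @export
apply_scaling <- function(scaling, newx) {
  if (inherits(scaling, "feature_matrix")) scaling <- scaling$scaling
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1,
                                         dimnames = list(NULL, names(newx)))
  for (step in scaling) {
    vars <- names(if (step$method == "autoscale") step$center else step$min)
    if (!is.null(colnames(newx))) {
      miss <- setdiff(vars, colnames(newx))
      if (length(miss) > 0) stop("new samples lack variable(s): ",
                                 paste(miss, collapse = ", "))
      newx <- newx[, vars, drop = FALSE]
    } else if (ncol(newx) != length(vars)) {
      stop("variable count mismatch: expected ", length(vars))
    }
    newx <- switch(step$method,
      autoscale = sweep(sweep(newx, 2, step$center), 2, step$scale, "/"),
      range = sweep(sweep(newx, 2, step$min), 2, step$range, "/"),
      stop("unknown scaling step: ", step$method))
  }
  newx
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) return(x)
  stopifnot(is.matrix(x) || is.data.frame(x))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("feature matrix must be complete (no missing values)")
  structure(list(X = m, scaling = list()), class = "feature_matrix")
}

drop_constant <- function(m, strict) {
  spread <- apply(m, 2, function(col) diff(range(col)))
  if (any(spread == 0)) {
    bad <- colnames(m)[spread == 0]
    if (is.null(bad)) bad <- which(spread == 0)
    if (strict) stop("constant column(s): ", paste(bad, collapse = ", "))
    warning("dropping constant column(s): ", paste(bad, collapse = ", "))
    m <- m[, spread > 0, drop = FALSE]
  }
  m
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d variables; scaling: %s\n",
              nrow(x$X), ncol(x$X),
              if (length(x$scaling) == 0) "none" else
                paste(vapply(x$scaling, `[[`, "", "method"), collapse = " + ")))
  invisible(x)
}
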