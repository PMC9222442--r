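#' Principal component analysis by singular value decomposition
#'
#' Computes PCA of a (typically autoscaled) feature matrix: loadings are
#' the right singular vectors of the column-centred matrix, scores the
#' projections of the samples onto them, and the explained variance per
#' component comes from the squared singular values. Input is expected to
#' be scaled already ([autoscale()]); the matrix is re-centred here, which
#' is a no-op after autoscaling but makes the decomposition well-defined
#' for any input.
#'
#' @param x Matrix or `feature_matrix` (samples x variables).
#' @param n_components Number of components to keep (default: all
#'   `min(n - 1, p)`).
#' @return A `pca_model`: list with `loadings` (p x k, orthonormal
#'   columns), `scores` (n x k), `explained_variance_pct` (length k,
#'   non-increasing), `center` (column means used).
#' @export
pca_fit <- function(x, n_components = NULL) {
  fm <- as_feature_matrix(x)
  m <- fm$X
  if (nrow(m) < 2) stop("PCA needs >= 2 samples")
  kmax <- min(nrow(m) - 1, ncol(m))
  if (is.null(n_components)) n_components <- kmax
  if (n_components < 1 || n_components > kmax) {
    stop("n_components must lie in [1, ", kmax, "]")
  }
  center <- colMeans(m)
  mc <- sweep(m, 2, center)
  sv <- svd(mc)
  ev <- sv$d^2 / sum(sv$d^2) * 100
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", k)
  scores <- mc %*% loadings
  rownames(scores) <- rownames(m)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_pct = ev[k], center = center),
            class = "pca_model")
}

#' Project new samples onto a fitted PCA
#'
#' @param model A `pca_model`.
#' @param newx Matrix on the same (scaled) variable space.
#' @return Scores matrix.
#' @export
pca_project <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != nrow(model$loadings)) {
    stop("variable count mismatch with PCA model")
  }
  sweep(newx, 2, model$center) %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("PCA: %d components; explained variance %%: %s\n", k,
              paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", ")))
  invisible(x)
}
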