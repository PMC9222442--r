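#' Supervised Kohonen self-organising map
#'
#' Trains a supervised Kohonen network (SKN): a self-organising map whose
#' weight columns concatenate an input block (one weight per variable) and
#' a class block (one weight per class, in \[0, 1\]). During training the
#' winning neuron of a sample is the one minimising the Euclidean distance
#' over the concatenated blocks (so class membership helps organise the
#' map); during prediction the distance uses the input block only and the
#' sample inherits the winner's class.
#'
#' The map is a `grid[1] x grid[2]` toroidal array of hexagonally laid-out
#' neurons. Training uses the batch algorithm: each epoch assigns all
#' samples to winners, then every neuron within the neighbourhood radius
#' of a winner moves toward the mean of the samples assigned to that
#' neighbourhood, by a fraction equal to the learning rate. The
#' neighbourhood radius shrinks linearly from the full map (radius 4 on an
#' 8 x 8 torus, so initially every correction reaches the whole network)
#' to 0 (only the winner), and the learning rate decreases linearly from
#' `lr[1]` to `lr[2]` (defaults 0.5 to 0.01) over `epochs` epochs.
#' Neighbourhood rings are Chebyshev distance on the toroidal grid indices
#' (the square-step rings used by batch SOM toolboxes). The default
#' neighbourhood kernel is a Gaussian over that ring distance (with a
#' floor on its width), so every neuron keeps receiving small corrections
#' throughout training; with the discrete `"bubble"` kernel, neurons that
#' never win a sample are left with quasi-random weights from the early
#' epochs, and a prediction landing on such a neuron classifies by
#' initialisation noise. Weights are initialised uniformly on \[0, 1\],
#' seeded.
#'
#' Inputs must be range-scaled to \[0, 1\] (the class block is 0/1 coded,
#' so equal block weighting is only meaningful when the input block lives
#' on the same scale).
#'
#' @param x Matrix or `feature_matrix`, range-scaled to \[0, 1\].
#' @param classes Class labels (no empty class allowed).
#' @param grid `c(rows, cols)` of the map (default 8 x 8).
#' @param epochs Training epochs (default 200).
#' @param lr Learning-rate schedule `c(start, end)`.
#' @param neighbourhood `"gaussian"` (default) or `"bubble"` (discrete
#'   step).
#' @param class_weight Relative weight of the class block in the training
#'   distance (1 = equal blocks).
#' @param seed Integer seed for weight initialisation.
#' @param tol Tolerance for the \[0, 1\] input check.
#' @return An `skn_model`: `input_weights` (neurons x variables),
#'   `class_weights` (neurons x classes, in \[0, 1\]), `neuron_class`
#'   (factor, argmax class per neuron), `grid`, `coords` (neuron grid
#'   positions), and the training log (epochs, radius and learning-rate
#'   schedules).
#' @export
skn_fit <- function(x, classes, grid = c(8, 8), epochs = 200,
                    lr = c(0.5, 0.01), neighbourhood = c("gaussian", "bubble"),
                    class_weight = 1, seed = 1L, tol = 1e-8) {
  neighbourhood <- match.arg(neighbourhood)
  fm <- as_feature_matrix(x)
  m <- fm$X
  if (min(m) < -tol || max(m) > 1 + tol) {
    stop("SKN input must be range-scaled to [0, 1] (see range_scale())")
  }
  grp <- droplevels(factor(classes))
  if (nlevels(grp) < 2) stop("SKN training needs >= 2 non-empty classes")
  Y <- stats::model.matrix(~ grp - 1)
  colnames(Y) <- levels(grp)

  n_neuron <- prod(grid)
  coords <- cbind(row = rep(seq_len(grid[1]), times = grid[2]),
                  col = rep(seq_len(grid[2]), each = grid[1]))
  D <- torus_distances(grid)                  # neuron x neuron ring distance
  r_max <- max(D)

  set.seed(seed)
  Wx <- matrix(stats::runif(n_neuron * ncol(m)), n_neuron,
               dimnames = list(NULL, colnames(m)))
  Wy <- matrix(stats::runif(n_neuron * ncol(Y)), n_neuron,
               dimnames = list(NULL, colnames(Y)))

  radius_log <- lr_log <- numeric(epochs)
  for (e in seq_len(epochs)) {
    frac <- if (epochs == 1) 1 else (e - 1) / (epochs - 1)
    radius <- round(r_max * (1 - frac))
    alpha <- lr[1] + (lr[2] - lr[1]) * frac
    radius_log[e] <- radius; lr_log[e] <- alpha

    win <- skn_winners(m, Wx, Y, Wy, class_weight)
    H <- neighbourhood_kernel(D, win, radius, neighbourhood)  # neuron x n
    mass <- rowSums(H)
    upd <- mass > 0
    targ_x <- (H %*% m)[upd, , drop = FALSE] / mass[upd]
    targ_y <- (H %*% Y)[upd, , drop = FALSE] / mass[upd]
    Wx[upd, ] <- Wx[upd, ] + alpha * (targ_x - Wx[upd, , drop = FALSE])
    Wy[upd, ] <- Wy[upd, ] + alpha * (targ_y - Wy[upd, , drop = FALSE])
    Wy[Wy < 0] <- 0; Wy[Wy > 1] <- 1
  }

  neuron_class <- factor(levels(grp)[max.col(Wy, ties.method = "first")],
                         levels = levels(grp))
  structure(list(input_weights = Wx, class_weights = Wy,
                 neuron_class = neuron_class, grid = grid, coords = coords,
                 classes = levels(grp), class_weight = class_weight,
                 log = list(epochs = epochs, radius = radius_log,
                            lr = lr_log, seed = seed,
                            neighbourhood = neighbourhood)),
            class = "skn_model")
}

# winner per sample over concatenated (input, class) blocks
skn_winners <- function(m, Wx, Y, Wy, class_weight) {
  dx <- dist2(m, Wx)
  dy <- dist2(Y, Wy)
  max.col(-(dx + class_weight * dy), ties.method = "first")
}

# squared Euclidean distances, samples x neurons
dist2 <- function(A, W) {
  outer(rowSums(A^2), rep(1, nrow(W))) - 2 * tcrossprod(A, W) +
    outer(rep(1, nrow(A)), rowSums(W^2))
}

# neuron x sample neighbourhood weights around each sample's winner
neighbourhood_kernel <- function(D, win, radius, kind) {
  Dw <- D[, win, drop = FALSE]
  if (kind == "bubble") {
    (Dw <= radius) * 1
  } else {
    sig <- max(radius, 0.5)
    exp(-Dw^2 / (2 * sig^2))
  }
}

#' Toroidal ring distances between map neurons
#'
#' Chebyshev distance on grid indices with wraparound on both axes, so the
#' distance table is symmetric and translation invariant and every neuron
#' has a full neighbourhood (no edge effects). Maximum ring on an 8 x 8
#' torus: 4.
#'
#' @param grid `c(rows, cols)`.
#' @return `prod(grid)` square matrix of integer ring distances (neurons
#'   in column-major order).
#' @export
torus_distances <- function(grid) {
  rows <- seq_len(grid[1]); cols <- seq_len(grid[2])
  r <- rep(rows, times = grid[2]); c <- rep(cols, each = grid[1])
  dr <- abs(outer(r, r, "-")); dr <- pmin(dr, grid[1] - dr)
  dc <- abs(outer(c, c, "-")); dc <- pmin(dc, grid[2] - dc)
  pmax(dr, dc)
}

#' Predict classes from a trained SKN
#'
#' The winner is computed on the input block only; the sample takes the
#' winner's class (argmax of its class weights).
#'
#' @param model An `skn_model`.
#' @param newx Matrix scaled with the training scaling record. Values may
#'   fall slightly outside \[0, 1\] (held-out samples beyond the training
#'   range); they are used as-is.
#' @return List with `class`, `neuron` (winning neuron index) and
#'   `distance` (Euclidean distance to the winner's input weights).
#' @export
skn_predict <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != ncol(model$input_weights)) {
    stop("variable count mismatch with SKN model")
  }
  d2 <- dist2(newx, model$input_weights)
  win <- max.col(-d2, ties.method = "first")
  list(class = as.character(model$neuron_class[win]), neuron = win,
       distance = sqrt(pmax(d2[cbind(seq_len(nrow(newx)), win)], 0)))
}

#' PCA of the SKN neuron weight map
#'
#' Runs PCA on the neurons x variables input-weight matrix of a trained
#' map. Each neuron score carries the neuron's class assignment, so score
#' plots show how the map organises the classes, and the variable loadings
#' show which variables drive that organisation (the weight-map reading of
#' the trained network).
#'
#' @param model An `skn_model`.
#' @param n_components Components to keep (default all).
#' @return The `pca_model` with an extra element `neuron_class`.
#' @export
som_weight_pca <- function(model, n_components = NULL) {
  if (!inherits(model, "skn_model")) stop("need a trained skn_model")
  p <- pca_fit(model$input_weights, n_components)
  p$neuron_class <- model$neuron_class
  p
}

#' @export
print.skn_model <- function(x, ...) {
  cat(sprintf("Supervised Kohonen map: %d x %d toroidal grid, %d epochs\n",
              x$grid[1], x$grid[2], x$log$epochs))
  cat(sprintf("  neurons per class: %s\n",
              paste(sprintf("%s=%d", levels(x$neuron_class),
                            table(x$neuron_class)), collapse = ", ")))
  invisible(x)
}
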