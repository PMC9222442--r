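#' Partial least squares discriminant analysis
#'
#' PLS-DA regresses a {0, 1} class indicator on latent variables (LVs)
#' extracted from the (autoscaled) feature matrix by NIPALS-style iterative
#' deflation: each LV direction maximises the covariance between the X
#' scores and the indicator, X is deflated by the fitted LV, and the next
#' LV is extracted from the residual. Prediction reconstructs the
#' indicator from the regression coefficients and assigns the class whose
#' indicator value is larger (threshold 0.5 for two classes).
#'
#' With `n_lv = rank(X)` the fit coincides with ordinary least squares on
#' the indicator; small `n_lv` (the emulated study used 2) regularises.
#'
#' @param x Matrix or `feature_matrix` (samples x variables, scaled).
#' @param classes Class labels (2 levels required in training data).
#' @param n_lv Number of latent variables.
#' @param positive_class Label coded 1; default: second factor level.
#' @return A `plsda_model`: weights `W`, x-loadings `P`, y-loadings `q`,
#'   scores `T` (n x n_lv, mutually orthogonal columns), regression
#'   coefficients `coefficients` (per original variable) and `intercept`,
#'   plus the class coding.
#' @export
plsda_fit <- function(x, classes, n_lv = 2, positive_class = NULL) {
  fm <- as_feature_matrix(x)
  m <- fm$X
  grp <- factor(classes)
  grp <- droplevels(grp)
  if (nlevels(grp) != 2) {
    stop("PLS-DA training data must contain exactly 2 classes (got ",
         nlevels(grp), ")")
  }
  if (is.null(positive_class)) positive_class <- levels(grp)[2]
  if (!positive_class %in% levels(grp)) stop("positive_class not in labels")
  y <- as.numeric(grp == positive_class)

  rank_x <- qr(sweep(m, 2, colMeans(m)))$rank
  if (n_lv < 1 || n_lv > rank_x) {
    stop("n_lv must lie in [1, rank(X) = ", rank_x, "]")
  }

  xmean <- colMeans(m)
  ymean <- mean(y)
  E <- sweep(m, 2, xmean)
  f <- y - ymean
  p <- ncol(m)
  W <- P <- matrix(0, p, n_lv, dimnames = list(colnames(m), NULL))
  Tm <- matrix(0, nrow(m), n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q[a] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q[a] * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
  }
  Rstar <- W %*% solve(crossprod(P, W))   # X_c %*% Rstar reproduces scores
  beta <- Rstar %*% q
  structure(list(W = W, P = P, q = q, Rstar = Rstar, scores = Tm,
                 coefficients = drop(beta),
                 intercept = ymean - drop(crossprod(xmean, beta)),
                 n_lv = n_lv,
                 classes = levels(grp), positive_class = positive_class,
                 xmean = xmean, ymean = ymean),
            class = "plsda_model")
}

#' Predict classes from a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param newx Matrix on the training variable space (already scaled with
#'   the training scaling record).
#' @return List with `class` (labels), `indicator` (predicted 0/1-coded
#'   response) and `scores` (projections onto the LVs).
#' @export
plsda_predict <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != length(model$coefficients)) {
    stop("variable count mismatch with PLS-DA model")
  }
  yhat <- drop(newx %*% model$coefficients) + model$intercept
  neg <- setdiff(model$classes, model$positive_class)
  cls <- ifelse(yhat > 0.5, model$positive_class, neg)
  scores <- sweep(newx, 2, model$xmean) %*% model$Rstar
  list(class = cls, indicator = yhat, scores = scores)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA: %d LVs, %d variables; classes %s (positive = %s)\n",
              x$n_lv, length(x$coefficients),
              paste(x$classes, collapse = "/"), x$positive_class))
  invisible(x)
}
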