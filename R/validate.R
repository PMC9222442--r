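#' Model specifications for validation
#'
#' A model spec bundles the scaling pipeline and fit/predict functions a
#' classifier needs, so [cross_validate()] can refit everything — scaling
#' parameters included — inside each training fold (no information from
#' held-out samples leaks into the fit).
#'
#' * `plsda_spec()`: autoscaling + PLS-DA with `n_lv` latent variables.
#' * `skn_spec()`: autoscaling + range scaling + supervised Kohonen map.
#'
#' @param n_lv Latent variables for PLS-DA.
#' @param grid,epochs,lr,neighbourhood,class_weight,seed See [skn_fit()].
#' @return A `model_spec` list with elements `name`, `scale` (function
#'   matrix -> feature_matrix), `fit` (scaled matrix, classes -> model) and
#'   `predict` (model, scaled matrix -> labels).
#' @export
plsda_spec <- function(n_lv = 2) {
  structure(list(
    name = sprintf("PLS-DA (%d LVs)", n_lv),
    scale = function(m) autoscale(m),
    fit = function(m, classes) plsda_fit(m, classes, n_lv = n_lv),
    predict = function(model, m) plsda_predict(model, m)$class
  ), class = "model_spec")
}

#' @rdname plsda_spec
#' @export
skn_spec <- function(grid = c(8, 8), epochs = 200, lr = c(0.5, 0.01),
                     neighbourhood = "gaussian", class_weight = 1, seed = 1L) {
  structure(list(
    name = sprintf("SKN (%dx%d, %d epochs)", grid[1], grid[2], epochs),
    scale = function(m) range_scale(autoscale(m)),
    fit = function(m, classes) skn_fit(m, classes, grid = grid,
                                       epochs = epochs, lr = lr,
                                       neighbourhood = neighbourhood,
                                       class_weight = class_weight,
                                       seed = seed),
    predict = function(model, m) skn_predict(model, m)$class
  ), class = "model_spec")
}

#' Fit a model spec on the full data (fitting performance)
#'
#' @param x Unscaled feature matrix (samples x variables).
#' @param classes Class labels.
#' @param spec A `model_spec`.
#' @return List with `model`, `scaling`, `predicted`, `metrics`
#'   (fitting-set [compute_metrics()]).
#' @export
fit_model <- function(x, classes, spec) {
  fm <- spec$scale(x)
  model <- spec$fit(fm$X, classes)
  pred <- spec$predict(model, fm$X)
  list(model = model, scaling = fm$scaling, predicted = pred,
       metrics = compute_metrics(
         confusion_matrix(classes, pred, classes = sort(unique(classes)))))
}

#' Repeated stratified holdout cross-validation
#'
#' The emulated study's protocol: at each iteration a random 20% of the
#' samples is removed, the model — scaling parameters included — is fit on
#' the remaining 80%, and the removed samples are predicted. Holdout size
#' is `round(holdout_frac * n)` (half away from zero: 20% of 34 samples is
#' 7), allocated over classes proportionally (largest remainder), so no
#' training fold loses a whole class. Predictions are pooled over all
#' iterations before the metrics are computed (per-iteration averaging of
#' NER is available as an option; both are reported by [print()]).
#'
#' With `holdout_frac = 0` the procedure degenerates to fitting metrics.
#'
#' @param x Unscaled feature matrix.
#' @param classes Class labels (>= 2 per class).
#' @param spec A `model_spec`.
#' @param holdout_frac Fraction held out per iteration.
#' @param iterations Number of random holdouts.
#' @param seed Integer seed for the holdout draws.
#' @param stratified Stratify the holdout by class (default) or draw it
#'   simply at random (redrawn if a training class empties).
#' @return A `cv_result`: pooled `metrics`, `ner_pct` /`accuracy_pct`
#'   shortcuts, `per_iteration_ner_pct` (mean of per-iteration NERs),
#'   `misclassification` tibble (per sample: times held out, times wrong),
#'   `n_iterations`, `holdout_size`.
#' @export
cross_validate <- function(x, classes, spec, holdout_frac = 0.2,
                           iterations = 1000, seed = 1L, stratified = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(classes))
  classes <- as.character(classes)
  lev <- sort(unique(classes))
  if (length(lev) < 2) stop("cross-validation needs >= 2 classes")
  if (min(table(classes)) < 2) stop("each class needs >= 2 samples")
  if (holdout_frac < 0 || holdout_frac >= 1) {
    stop("holdout_frac must lie in [0, 1)")
  }
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  m_hold <- floor(holdout_frac * n + 0.5)
  if (m_hold == 0) {
    fit <- fit_model(x, classes, spec)
    return(structure(list(metrics = fit$metrics,
                          ner_pct = fit$metrics$ner_pct,
                          accuracy_pct = fit$metrics$accuracy_pct,
                          per_iteration_ner_pct = fit$metrics$ner_pct,
                          misclassification = tibble::tibble(
                            sample_id = ids, class = classes,
                            n_heldout = 1L,
                            n_wrong = as.integer(fit$predicted != classes)),
                          n_iterations = 0L, holdout_size = 0L,
                          spec_name = spec$name),
                     class = "cv_result"))
  }

  set.seed(seed)
  truth_all <- pred_all <- character(0)
  held <- wrong <- integer(n)
  iter_ner <- numeric(iterations)
  for (it in seq_len(iterations)) {
    hold <- draw_holdout(classes, lev, m_hold, stratified)
    train <- setdiff(seq_len(n), hold)
    fm <- spec$scale(x[train, , drop = FALSE])
    model <- spec$fit(fm$X, classes[train])
    newx <- apply_scaling(fm$scaling, x[hold, , drop = FALSE])
    pred <- spec$predict(model, newx)
    truth_all <- c(truth_all, classes[hold])
    pred_all <- c(pred_all, pred)
    held[hold] <- held[hold] + 1L
    wrong[hold] <- wrong[hold] + as.integer(pred != classes[hold])
    sens <- vapply(lev, function(k) {
      in_k <- classes[hold] == k
      if (!any(in_k)) NA_real_ else mean(pred[in_k] == k) * 100
    }, numeric(1))
    iter_ner[it] <- mean(sens, na.rm = TRUE)
  }
  metrics <- compute_metrics(confusion_matrix(truth_all, pred_all,
                                              classes = lev))
  structure(list(metrics = metrics, ner_pct = metrics$ner_pct,
                 accuracy_pct = metrics$accuracy_pct,
                 per_iteration_ner_pct = mean(iter_ner),
                 misclassification = tibble::tibble(
                   sample_id = ids, class = classes, n_heldout = held,
                   n_wrong = wrong),
                 n_iterations = iterations, holdout_size = m_hold,
                 spec_name = spec$name),
            class = "cv_result")
}

# stratified (largest remainder) or simple holdout; never empties a
# training class
draw_holdout <- function(classes, lev, m_hold, stratified) {
  n <- length(classes)
  if (stratified) {
    quota <- m_hold * table(factor(classes, levels = lev)) / n
    take <- floor(quota)
    rem <- m_hold - sum(take)
    if (rem > 0) {
      order_frac <- order(quota - take, decreasing = TRUE)
      take[order_frac[seq_len(rem)]] <- take[order_frac[seq_len(rem)]] + 1
    }
    take <- pmin(take, table(factor(classes, levels = lev)) - 1)
    unlist(lapply(lev, function(k) {
      sample(which(classes == k), take[k])
    }), use.names = FALSE)
  } else {
    repeat {
      hold <- sample(n, m_hold)
      if (all(lev %in% classes[-hold])) return(hold)
    }
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d iterations, holdout %d\n",
              x$spec_name, x$n_iterations, x$holdout_size))
  cat(sprintf("  pooled NER%% %.2f (per-iteration mean %.2f), accuracy%% %.2f\n",
              x$ner_pct, x$per_iteration_ner_pct, x$accuracy_pct))
  invisible(x)
}

#' External prediction of held-back samples
#'
#' Applies the training scaling record to samples never used in model
#' fitting (in the emulated study, animals given a therapeutic
#' dexamethasone dose) and reports their predicted classes and the
#' fraction falling in an expected class.
#'
#' @param fit Output of [fit_model()] (model + scaling), or a list with
#'   `model` and `scaling`.
#' @param spec The `model_spec` used to build `fit`.
#' @param newx Unscaled matrix of external samples (training variables).
#' @param expected_label Class the externals are expected to resemble.
#' @return Tibble with `sample_id`, `predicted`, plus attribute
#'   `fraction_expected`.
#' @export
external_predict <- function(fit, spec, newx, expected_label = "control") {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  scaled <- apply_scaling(fit$scaling, newx)
  pred <- spec$predict(fit$model, scaled)
  ids <- rownames(newx)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(newx)))
  out <- tibble::tibble(sample_id = ids, predicted = pred,
                        as_expected = pred == expected_label)
  attr(out, "fraction_expected") <- mean(out$as_expected)
  out
}
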