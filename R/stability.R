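#' geNorm reference-gene stability ranking
#'
#' Classic pairwise-variation measure: on the log2-quantity scale (a Cq
#' difference is already a log2 ratio at 100% efficiency), the variation of
#' a gene pair (j, k) is `V_jk = sd over samples of (Cq_j - Cq_k)`, and the
#' stability of gene j is `M_j = mean of V_jk over k != j`. Lower M = more
#' stable. The least stable gene is excluded and M recomputed on the
#' survivors, iterating until two genes remain; those two are the geNorm
#' reference pair.
#'
#' Samples with a missing Cq for any candidate are dropped (pairwise SDs
#' must share a common sample set for the iterative exclusion to be
#' coherent). A per-sample Cq offset common to all genes (dilution, RNA
#' input) cancels in the differences.
#'
#' @param summaries Output of [aggregate_replicates()] (or any tibble with
#'   `sample_id`, `target`, `mean_cq`).
#' @param candidates Character vector of >= 3 candidate gene symbols.
#' @return List with `m_values` (named, initial full-panel M per candidate),
#'   `ranking` (symbols from least to most stable, i.e. exclusion order
#'   first), `selected` (the final pair, alphabetical), and `steps`
#'   (per-iteration M tables).
#' @export
genorm_rank <- function(summaries, candidates) {
  if (length(candidates) < 3) {
    stop("geNorm needs >= 3 candidate genes (M is undefined once a single ",
         "pair would remain after exclusion)")
  }
  m <- candidate_matrix(summaries, candidates)
  if (nrow(m) < 3) stop("geNorm needs >= 3 samples with complete candidates")

  steps <- list()
  active <- candidates
  exclusion <- character(0)
  first_m <- NULL
  while (length(active) > 2) {
    mv <- genorm_m(m[, active, drop = FALSE])
    if (is.null(first_m)) first_m <- mv
    steps[[length(steps) + 1]] <- mv
    worst <- names(mv)[which.max(mv)]
    exclusion <- c(exclusion, worst)
    active <- setdiff(active, worst)
  }
  steps[[length(steps) + 1]] <- genorm_m(m[, active, drop = FALSE])
  list(m_values = first_m,
       ranking = c(exclusion, sort(active)),
       selected = sort(active),
       steps = steps)
}

# mean over partner genes of the pairwise SD of Cq differences
genorm_m <- function(m) {
  k <- ncol(m)
  v <- matrix(0, k, k)
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      v[j, l] <- v[l, j] <- stats::sd(m[, j] - m[, l])
    }
  }
  mv <- rowSums(v) / (k - 1)
  names(mv) <- colnames(m)
  mv
}

#' NormFinder reference-gene stability ranking
#'
#' Model-based stability estimator on the log2-quantity scale. Within each
#' group, the per-sample average over candidates is removed (absorbing
#' sample-specific loading/efficiency), leaving residuals whose group means
#' carry the gene's intergroup bias and whose scatter carries its intragroup
#' variance. The intragroup variance of each gene is estimated with a
#' bias correction for the removed sample average; the intergroup
#' difference is shrunk towards zero in proportion to its sampling variance
#' (an empirical-Bayes step, so noisy bias estimates are not over-trusted).
#' The stability value of a gene averages, over groups,
#' `|shrunk bias| + sqrt(intragroup variance / n_group)`: lower = more
#' stable, combining systematic and random error of a normaliser based on
#' that gene.
#'
#' @param summaries As for [genorm_rank()], plus a `class` column (or pass
#'   `classes`).
#' @param candidates Character vector of >= 3 candidate gene symbols
#'   (the sample-average correction needs several genes).
#' @param classes Optional named vector mapping `sample_id` to group label;
#'   defaults to the `class` column of `summaries`. Exactly the samples
#'   with one of `groups` labels are used.
#' @param groups Group labels to include (default: the two study classes,
#'   control and dex).
#' @param background Genes over which the model is estimated (default: all
#'   targets in `summaries`, the intended use — the removed per-sample
#'   average and the shrinkage pool are then estimated from the whole
#'   assayed panel, whose regulation largely averages out, rather than
#'   from the few candidates themselves). Must contain `candidates`.
#' @return List with `stability` (named, per candidate), `ranking`
#'   (most stable first), `selected` (top pair, alphabetical), and the
#'   per-gene `intergroup` (shrunk bias per group) and `intragroup`
#'   variance estimates.
#' @export
normfinder_rank <- function(summaries, candidates, classes = NULL,
                            groups = c("control", "dex"),
                            background = NULL) {
  if (length(candidates) < 3) stop("NormFinder needs >= 3 candidate genes")
  if (is.null(background)) background <- unique(summaries$target)
  if (!all(candidates %in% background)) {
    stop("background must contain all candidates")
  }
  if (is.null(classes)) {
    if (!"class" %in% names(summaries)) {
      stop("no `classes` given and `summaries` has no class column")
    }
    cls <- dplyr::distinct(summaries, .data$sample_id, .data$class)
    classes <- stats::setNames(cls$class, cls$sample_id)
  }
  m <- candidate_matrix(summaries, background)
  grp <- classes[rownames(m)]
  keep <- grp %in% groups
  m <- m[keep, , drop = FALSE]
  grp <- factor(grp[keep], levels = groups)
  if (nlevels(droplevels(grp)) < 2) {
    stop("NormFinder needs samples from >= 2 groups (intergroup term ",
         "undefined for a single class)")
  }
  if (min(table(grp)) < 2) stop("each group needs >= 2 samples")

  k <- length(background)
  if (k < 3) stop("NormFinder needs >= 3 genes overall")
  y <- -m                                     # log2 quantity scale
  r <- y - rowMeans(y)                        # remove sample average
  G <- nlevels(grp)
  ng <- as.integer(table(grp))

  gmean <- apply(r, 2, function(col) tapply(col, grp, mean))   # G x k
  gvar <- apply(r, 2, function(col) tapply(col, grp, stats::var))
  # bias-correct for the subtracted sample average:
  # E[s2_ig] = sig2_ig (1 - 2/k) + S_g / k^2  with S_g = sum_i sig2_ig
  S_g <- rowSums(gvar) * k / (k - 1)
  sig2 <- pmax((gvar - S_g / k^2) * k / (k - 2), 0)            # G x k

  d <- gmean - matrix(colMeans(gmean), G, k, byrow = TRUE)     # bias per grp
  vd <- sig2 / ng * (1 - 1 / G)^2 +
    (colSums(sig2 / ng)[col(d)] - sig2 / ng) / G^2             # Var(d_ig)
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(vd))
  d_shrunk <- d * gamma2 / (gamma2 + vd)

  stability_all <- colMeans(abs(d_shrunk) + sqrt(sig2 / ng))
  names(stability_all) <- background
  colnames(d_shrunk) <- colnames(sig2) <- background
  stability <- stability_all[candidates]
  ord <- order(stability)
  list(stability = stability,
       ranking = candidates[ord],
       selected = sort(candidates[ord][1:2]),
       stability_all = stability_all,
       intergroup = d_shrunk, intragroup = sig2)
}

#' Select the reference-gene pair
#'
#' Runs geNorm and NormFinder and returns the agreed pair. When the two
#' methods' top pairs differ, geNorm's pair is used (its pair is defined
#' jointly, which is what a two-gene normaliser needs) and the disagreement
#' is recorded.
#'
#' @inheritParams normfinder_rank
#' @return List with `selected`, `genorm`, `normfinder`, `agreement`.
#' @export
select_references <- function(summaries, candidates, classes = NULL,
                              groups = c("control", "dex")) {
  g <- genorm_rank(summaries, candidates)
  n <- normfinder_rank(summaries, candidates, classes, groups)
  agree <- identical(g$selected, n$selected)
  list(selected = g$selected, genorm = g, normfinder = n, agreement = agree)
}

# samples x candidates mean-Cq matrix, complete cases only
candidate_matrix <- function(summaries, candidates) {
  miss <- setdiff(candidates, unique(summaries$target))
  if (length(miss) > 0) {
    stop("candidates absent from Cq summaries: ", paste(miss, collapse = ", "))
  }
  m <- cq_matrix(summaries[summaries$target %in% candidates, , drop = FALSE])
  m <- m[, candidates, drop = FALSE]
  m[stats::complete.cases(m), , drop = FALSE]
}
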