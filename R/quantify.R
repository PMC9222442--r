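#' Reference-gene normalisation (delta-Cq)
#'
#' `dCq(sample, gene) = mean_cq(sample, gene) - mean(mean_cq(sample, refs))`.
#' The arithmetic mean of reference Cq values corresponds to the geometric
#' mean of reference quantities, the standard multi-gene normaliser. The
#' reference genes are removed from the output matrix. Samples missing any
#' reference gene cannot be normalised and are dropped with a warning.
#'
#' Targets missing in a sample (all wells filtered out) are left `NA` here
#' unless `impute = TRUE`, in which case they are imputed at the class-wise
#' observed maximum dCq + 0.5 cycles — a worst-case ("at most this
#' expressed") value, appropriate for targets lost to late Cq. Imputed
#' cells are reported.
#'
#' @param summaries Output of [aggregate_replicates()].
#' @param references Character vector (typically a pair) of reference genes.
#' @param impute Impute missing dCq values (needed before multivariate
#'   modelling, which requires complete matrices).
#' @param classes Named vector `sample_id -> class`; defaults to the
#'   `class` column of `summaries`. Only used for class-wise imputation.
#' @return List with `dcq` (samples x non-reference targets matrix),
#'   `dropped_samples`, and `imputed` (logical matrix like `dcq`).
#' @export
normalize_dcq <- function(summaries, references, impute = TRUE,
                          classes = NULL) {
  stopifnot(length(references) >= 1)
  m <- cq_matrix(summaries)
  miss <- setdiff(references, colnames(m))
  if (length(miss) > 0) {
    stop("reference genes absent from data: ", paste(miss, collapse = ", "))
  }
  refm <- m[, references, drop = FALSE]
  ok <- stats::complete.cases(refm)
  dropped <- rownames(m)[!ok]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped),
            " sample(s) with missing reference gene(s): ",
            paste(dropped, collapse = ", "))
  }
  m <- m[ok, , drop = FALSE]
  norm <- rowMeans(m[, references, drop = FALSE])
  targets <- setdiff(colnames(m), references)
  dcq <- m[, targets, drop = FALSE] - norm
  imputed <- is.na(dcq)

  if (impute && any(imputed)) {
    if (is.null(classes)) {
      if (!"class" %in% names(summaries)) {
        stop("imputation needs class labels (column `class` or `classes`)")
      }
      cls <- dplyr::distinct(summaries, .data$sample_id, .data$class)
      classes <- stats::setNames(cls$class, cls$sample_id)
    }
    grp <- classes[rownames(dcq)]
    for (j in which(colSums(imputed) > 0)) {
      for (g in unique(grp[imputed[, j]])) {
        in_g <- grp == g
        fill <- if (any(!imputed[in_g, j])) {
          max(dcq[in_g, j], na.rm = TRUE) + 0.5
        } else {
          max(dcq[, j], na.rm = TRUE) + 0.5   # class fully missing
        }
        dcq[in_g & imputed[, j], j] <- fill
      }
    }
  }
  list(dcq = dcq, dropped_samples = dropped, imputed = imputed)
}

#' Delta-delta-Cq relative quantification and differential expression
#'
#' For each target, `ddCq(sample) = dCq(sample) - mean(dCq over controls)`
#' and the relative quantity is `RQ = 2^(-ddCq)` (calibrated so the control
#' group averages RQ = 1 on the log scale). The group log2 fold-change of
#' treated vs control is `-(mean dCq_treated - mean dCq_control)`: planted
#' up-regulation (lower Cq in treated) gives a positive log2FC. The 95%
#' confidence interval uses the Welch t interval on the dCq group
#' difference. Significance comes from a one-way ANOVA across all sampled
#' groups with Tukey's post hoc adjustment, reported for the treated vs
#' control comparison (with two groups this reduces to the pairwise
#' comparison).
#'
#' @param dcq Samples x targets dCq matrix (e.g. `normalize_dcq()$dcq`).
#' @param classes Named vector or vector aligned with `rownames(dcq)`.
#' @param control_label,treated_label Group labels compared in the fold
#'   change (other groups still enter the ANOVA).
#' @param alpha Significance level.
#' @return List with `de` — a tibble (gene, log2_fc, ci95_low, ci95_high,
#'   p_value, significant) — and `rq`, the samples x targets RQ matrix
#'   (`log2(rq) = -ddCq`).
#' @export
delta_delta_cq <- function(dcq, classes, control_label = "control",
                           treated_label = "dex", alpha = 0.05) {
  if (!is.null(names(classes))) classes <- classes[rownames(dcq)]
  stopifnot(length(classes) == nrow(dcq))
  grp <- factor(classes)
  if (sum(grp == control_label, na.rm = TRUE) < 2) {
    stop("need >= 2 samples in the control (calibrator) group")
  }
  ctrl_mean <- colMeans(dcq[grp == control_label, , drop = FALSE], na.rm = TRUE)
  ddcq <- sweep(dcq, 2, ctrl_mean)
  rq <- 2^(-ddcq)

  comparison <- paste(treated_label, control_label, sep = "-")
  de <- lapply(colnames(dcq), function(g) {
    x <- dcq[, g]
    okc <- grp == control_label & !is.na(x)
    okt <- grp == treated_label & !is.na(x)
    if (sum(okc) < 2 || sum(okt) < 2) {
      return(tibble::tibble(gene = g, log2_fc = NA_real_,
                            ci95_low = NA_real_, ci95_high = NA_real_,
                            p_value = NA_real_, significant = NA))
    }
    log2_fc <- -(mean(x[okt]) - mean(x[okc]))
    if (stats::sd(x[okt]) == 0 && stats::sd(x[okc]) == 0) {
      # degenerate noise-free groups: the difference is exact
      ci <- c(log2_fc, log2_fc)
      p <- if (log2_fc == 0) 1 else 0
    } else {
      tt <- stats::t.test(x[okt], x[okc], conf.level = 0.95)
      ci <- sort(-tt$conf.int)               # flip sign convention
      ok <- !is.na(x)
      fit <- stats::aov(x[ok] ~ droplevels(grp[ok]))
      tk <- stats::TukeyHSD(fit)[[1]]
      row <- match_comparison(rownames(tk), treated_label, control_label)
      p <- unname(tk[row, "p adj"])
    }
    tibble::tibble(gene = g, log2_fc = log2_fc,
                   ci95_low = ci[1], ci95_high = ci[2],
                   p_value = p, significant = p < alpha)
  })
  list(de = dplyr::bind_rows(de), rq = rq, comparison = comparison)
}

match_comparison <- function(labels, a, b) {
  hit <- which(labels %in% c(paste(a, b, sep = "-"), paste(b, a, sep = "-")))
  if (length(hit) != 1) stop("treated/control comparison not found in Tukey table")
  hit
}
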