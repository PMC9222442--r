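#!/usr/bin/env Rscript
# Step 5 — pattern recognition and classification.
#
# For the expression-only (RQ) and fused (RQhisto) datasets: PCA after
# autoscaling; PLS-DA (2 LVs) and a supervised Kohonen map (8x8 toroidal,
# 200 epochs) in fitting and in repeated 20%-holdout cross-validation
# (200 iterations here); external prediction of the therapeutic-dose
# samples, which are never used for fitting; PCA of the trained SOM's
# neuron weights for interpretation.

suppressPackageStartupMessages(library(dexscreen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

meta <- readr::read_csv("results/study/metadata.csv", show_col_types = FALSE)
cls <- setNames(meta$class, meta$sample_id)
dcq <- read_matrix_csv("results/dcq_matrix.csv")
datasets <- list(RQ = -dcq,                       # log2 expression scale
                 RQhisto = read_matrix_csv("results/rqhisto_matrix.csv"))

specs <- list(`PLS-DA` = plsda_spec(n_lv = 2), SKN = skn_spec(seed = seed))
rows <- list()
for (nm in names(datasets)) {
  mat <- datasets[[nm]]
  grp <- cls[rownames(mat)]
  xm <- mat[grp != "therapeutic", ]
  xe <- mat[grp == "therapeutic", , drop = FALSE]
  ym <- grp[grp != "therapeutic"]

  pca <- pca_fit(autoscale(xm))
  cat(sprintf("\n== %s: %d modelling samples, %d variables; first 4 PCs explain %.1f%%\n",
              nm, nrow(xm), ncol(xm), sum(pca$explained_variance_pct[1:4])))

  for (mn in names(specs)) {
    sp <- specs[[mn]]
    fit <- fit_model(xm, ym, sp)
    cv <- cross_validate(xm, ym, sp, holdout_frac = 0.2, iterations = 200,
                         seed = seed)
    ext <- external_predict(fit, sp, xe)
    cat(sprintf("%s fitting NER%% %.2f / CV NER%% %.2f; therapeutic-dose predicted: %s\n",
                mn, fit$metrics$ner_pct, cv$ner_pct,
                paste(ext$predicted, collapse = ", ")))
    for (phase in c("fitting", "cv")) {
      met <- if (phase == "fitting") fit$metrics else cv$metrics
      rows[[length(rows) + 1]] <- dplyr::mutate(met$per_class, dataset = nm,
                                                model = mn, phase = phase,
                                                ner_pct = met$ner_pct,
                                                accuracy_pct = met$accuracy_pct)
    }
    if (mn == "SKN") {
      wp <- som_weight_pca(fit$model, n_components = 3)
      sep <- vapply(1:3, function(k) {
        abs(stats::t.test(wp$scores[wp$neuron_class == "control", k],
                          wp$scores[wp$neuron_class == "dex", k])$statistic)
      }, numeric(1))
      cat(sprintf("  SOM weight-map PCA: classes best separated on PC%d (|t| = %.1f)\n",
                  which.max(sep), max(sep)))
    }
  }
}

metrics <- dplyr::bind_rows(rows)
readr::write_csv(metrics, "results/classification_metrics.csv")
cat("\nWrote results/classification_metrics.csv\n")
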