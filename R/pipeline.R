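#' Pipeline configuration
#'
#' @param cq Cq table: a tibble or a CSV path (see [read_cq_csv()]).
#' @param fibres Fibre table (tibble or CSV path), or `NULL` to skip the
#'   morphometry / fused-dataset stages.
#' @param out_dir Directory for intermediate CSVs and the report; `NULL`
#'   keeps everything in memory.
#' @param cq_cutoff Late-Cq cutoff (cycles, > 0).
#' @param outlier_limit Replicate outlier limit (cycles).
#' @param reference_candidates Candidate reference genes for stability
#'   ranking.
#' @param references `"auto"` (geNorm/NormFinder selection) or an explicit
#'   gene pair (stability stage is then skipped).
#' @param n_lv PLS-DA latent variables.
#' @param som Settings list passed to [skn_spec()] (grid, epochs, lr, ...).
#' @param holdout_frac,cv_iterations Cross-validation protocol (the
#'   emulated study used 0.2 and 1000).
#' @param control_label,treated_label,external_label Class labels: the
#'   calibrator class, the treated class, and the class held back for
#'   external prediction.
#' @param seed Seed for the cross-validation holdout draws.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cq, fibres = NULL, out_dir = NULL,
                            cq_cutoff = 32, outlier_limit = 0.5,
                            reference_candidates = c("RPLP0", "HSPA8",
                                                     "GAPDH", "PPIA"),
                            references = "auto", n_lv = 2, som = list(),
                            holdout_frac = 0.2, cv_iterations = 1000,
                            control_label = "control", treated_label = "dex",
                            external_label = "therapeutic", seed = 1L) {
  if (cq_cutoff <= 0) stop("cq_cutoff must be > 0")
  if (holdout_frac < 0 || holdout_frac >= 1) {
    stop("holdout_frac must lie in [0, 1)")
  }
  if (!identical(references, "auto") && length(references) < 2) {
    stop("explicit `references` must name >= 2 genes")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes, in order: replicate aggregation and Cq filtering;
#' reference-gene stability ranking (geNorm + NormFinder) unless explicit
#' references are given; delta-Cq normalisation with worst-case
#' imputation; delta-delta-Cq relative quantification and ANOVA/Tukey
#' differential expression (on the undiluted profiles); fibre morphometry
#' and data fusion (when fibre data are supplied); then, for the
#' expression-only dataset and the fused dataset, PLS-DA and supervised
#' Kohonen classification in fitting and cross-validation plus external
#' prediction of the held-back class. All intermediate tables are written
#' as CSV when `out_dir` is set, together with a plain-text report.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `stability`, `de`, `morpho`,
#'   `datasets` (per dataset: feature matrix, PCA, per-model fitting/CV
#'   metrics and external predictions), `log` (per-stage exclusion
#'   counts), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()

  cq <- config$cq
  if (is.character(cq)) cq <- read_cq_csv(cq)
  fibres <- config$fibres
  if (is.character(fibres)) fibres <- read_fibres_csv(fibres)

  # --- stage 1: aggregate wells -------------------------------------------
  summaries <- aggregate_replicates(cq, cutoff = config$cq_cutoff,
                                    outlier_limit = config$outlier_limit)
  log$wells_cutoff <- sum(summaries$n_cutoff)
  log$wells_outlier <- sum(summaries$n_outlier)
  log$missing_measurements <- sum(summaries$n_valid == 0)

  meta <- dplyr::distinct(cq, .data$sample_id, .data$class,
                          .data$dilution)
  classes <- stats::setNames(meta$class, meta$sample_id)

  # --- stage 2: reference-gene stability ----------------------------------
  if (identical(config$references, "auto")) {
    stability <- select_references(summaries, config$reference_candidates,
                                   groups = c(config$control_label,
                                              config$treated_label))
    references <- stability$selected
  } else {
    stability <- NULL
    references <- config$references
  }

  # --- stage 3: normalisation + imputation --------------------------------
  norm <- normalize_dcq(summaries, references, impute = TRUE)
  log$samples_dropped_normalisation <- length(norm$dropped_samples)
  log$values_imputed <- sum(norm$imputed)

  # --- stage 4: differential expression on undiluted profiles -------------
  base_ids <- meta$sample_id[meta$dilution == 1]
  base_ids <- intersect(rownames(norm$dcq), base_ids)
  de <- delta_delta_cq(norm$dcq[base_ids, , drop = FALSE],
                       classes[base_ids],
                       control_label = config$control_label,
                       treated_label = config$treated_label)

  # RQ feature matrix on the log2 scale, all profiles
  rq_all <- delta_delta_cq(norm$dcq, classes[rownames(norm$dcq)],
                           control_label = config$control_label,
                           treated_label = config$treated_label)
  log2rq <- -sweep(norm$dcq, 2,
                   colMeans(norm$dcq[intersect(rownames(norm$dcq),
                     names(classes)[classes == config$control_label]),
                     , drop = FALSE]))

  datasets <- list(RQ = log2rq)

  # --- stage 5: morphometry + fusion --------------------------------------
  morpho <- NULL
  if (!is.null(fibres)) {
    if (!"class" %in% names(fibres)) {
      fibres$class <- unname(classes[fibres$sample_id])
    }
    morpho <- summarize_fibres(fibres, groups = c(config$treated_label,
                                                  config$control_label))
    fused <- fuse_datasets(log2rq, morpho)
    log$profiles_dropped_fusion <- length(fused$dropped)
    datasets$RQhisto <- fused$matrix
  }

  # --- stage 6: multivariate modelling per dataset ------------------------
  specs <- list(
    plsda = plsda_spec(n_lv = config$n_lv),
    skn = do.call(skn_spec, config$som)
  )
  model_one <- function(mat) {
    cls <- unname(classes[rownames(mat)])
    modelling <- cls != config$external_label
    xm <- mat[modelling, , drop = FALSE]
    ym <- cls[modelling]
    if (length(unique(ym)) < 2) {
      stop("modelling set has a single class; classifiers refuse it")
    }
    pca <- pca_fit(autoscale(xm))
    models <- lapply(specs, function(sp) {
      fit <- fit_model(xm, ym, sp)
      cv <- cross_validate(xm, ym, sp, holdout_frac = config$holdout_frac,
                           iterations = config$cv_iterations,
                           seed = config$seed)
      ext <- NULL
      if (any(!modelling)) {
        ext <- external_predict(fit, sp, mat[!modelling, , drop = FALSE],
                                expected_label = config$control_label)
      }
      list(spec = sp$name, fitting = fit$metrics, cv = cv, external = ext)
    })
    list(matrix = mat, n_modelling = sum(modelling),
         n_external = sum(!modelling), pca = pca, models = models)
  }
  datasets <- lapply(datasets, model_one)

  report <- structure(list(
    stability = stability, references = references, de = de$de,
    rq = rq_all$rq, morpho = morpho, datasets = datasets,
    summaries = summaries, dcq = norm$dcq, log = log,
    provenance = list(seed = config$seed, cq_cutoff = config$cq_cutoff,
                      references = references,
                      n_lv = config$n_lv,
                      cv_iterations = config$cv_iterations,
                      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  references:", paste(x$references, collapse = " + "), "\n")
  cat(sprintf("  DE genes (p < 0.05): %d of %d\n",
              sum(x$de$significant, na.rm = TRUE), nrow(x$de)))
  for (nm in names(x$datasets)) {
    d <- x$datasets[[nm]]
    cat(sprintf("  %s: %d modelling + %d external samples x %d variables\n",
                nm, d$n_modelling, d$n_external, ncol(d$matrix)))
    for (mn in names(d$models)) {
      m <- d$models[[mn]]
      cat(sprintf("    %-18s fitting NER%% %6.2f | CV NER%% %6.2f\n",
                  m$spec, m$fitting$ner_pct,
                  m$cv$ner_pct))
    }
  }
  invisible(x)
}

# serialise every reported table as CSV plus a text report
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name))
  w(report$summaries, "cq_summaries.csv")
  if (!is.null(report$stability)) {
    w(tibble::tibble(
      gene = names(report$stability$genorm$m_values),
      genorm_m = unname(report$stability$genorm$m_values),
      normfinder_stability =
        unname(report$stability$normfinder$stability[
          names(report$stability$genorm$m_values)])),
      "stability_ranking.csv")
  }
  w(report$de, "de_results.csv")
  write_matrix_csv(report$dcq, file.path(dir, "dcq_matrix.csv"))
  if (!is.null(report$morpho)) {
    w(report$morpho$per_sample, "morphometry_per_sample.csv")
    w(report$morpho$per_group, "morphometry_per_group.csv")
    w(report$morpho$test, "morphometry_test.csv")
  }
  rows <- list()
  for (nm in names(report$datasets)) {
    d <- report$datasets[[nm]]
    write_matrix_csv(d$matrix, file.path(dir, paste0(tolower(nm),
                                                     "_matrix.csv")))
    for (mn in names(d$models)) {
      m <- d$models[[mn]]
      for (phase in c("fitting", "cv")) {
        met <- if (phase == "fitting") m$fitting else m$cv$metrics
        pc <- met$per_class
        rows[[length(rows) + 1]] <- tibble::tibble(
          dataset = nm, model = m$spec, phase = phase,
          ner_pct = met$ner_pct, accuracy_pct = met$accuracy_pct,
          class = pc$class, precision_pct = pc$precision_pct,
          sensitivity_pct = pc$sensitivity_pct,
          specificity_pct = pc$specificity_pct)
      }
      if (!is.null(m$external)) {
        rows_ext <- dplyr::mutate(m$external, dataset = nm, model = m$spec)
        w(rows_ext, paste0("external_", tolower(nm), "_", mn, ".csv"))
      }
    }
  }
  w(dplyr::bind_rows(rows), "classification_metrics.csv")
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  cat("\nprovenance:\n")
  utils::str(report$provenance)
  invisible(dir)
}
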