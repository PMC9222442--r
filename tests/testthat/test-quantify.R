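dcq_summaries <- function(m, classes = NULL) {
  tb <- tidyr::expand_grid(sample_id = rownames(m), target = colnames(m))
  tb$mean_cq <- as.vector(t(m))
  if (!is.null(classes)) tb$class <- classes[tb$sample_id]
  tb
}

test_that("delta-Cq normalisation uses the reference mean and drops refs", {
  m <- rbind(s1 = c(gene = 28, r1 = 20, r2 = 22),
             s2 = c(gene = 30, r1 = 21, r2 = 23))
  norm <- normalize_dcq(dcq_summaries(m), c("r1", "r2"))
  expect_equal(norm$dcq["s1", "gene"], 7)      # 28 - mean(20, 22)
  expect_equal(norm$dcq["s2", "gene"], 8)
  expect_equal(colnames(norm$dcq), "gene")

  # a reference normalised against itself is identically zero
  self <- normalize_dcq(dcq_summaries(m[, "r1", drop = FALSE]), "r1",
                        impute = FALSE)
  expect_true(ncol(self$dcq) == 0)
  m2 <- cbind(m, r3 = c(20, 21))
  self2 <- normalize_dcq(dcq_summaries(m2), "r1", impute = FALSE)
  expect_equal(unname(self2$dcq[, "r3"] - (m2[, "r3"] - m2[, "r1"])), c(0, 0))
})

test_that("a global per-sample Cq shift leaves delta-Cq unchanged", {
  set.seed(6)
  m <- matrix(rnorm(5 * 6, 25, 2), 5,
              dimnames = list(sprintf("s%d", 1:5),
                              c("a", "b", "c", "d", "r1", "r2")))
  base <- normalize_dcq(dcq_summaries(m), c("r1", "r2"))$dcq
  shifted <- m + c(0.5, -1, 2, 0, 3.3)   # one constant per sample row
  shift <- normalize_dcq(dcq_summaries(shifted), c("r1", "r2"))$dcq
  expect_equal(base, shift, tolerance = 1e-12)
})

test_that("samples missing a reference are dropped with a warning", {
  m <- rbind(s1 = c(gene = 28, r1 = 20, r2 = 22),
             s2 = c(gene = 30, r1 = NA, r2 = 23))
  expect_warning(norm <- normalize_dcq(dcq_summaries(m), c("r1", "r2"),
                                       impute = FALSE), "s2")
  expect_equal(rownames(norm$dcq), "s1")
  expect_equal(norm$dropped_samples, "s2")
})

test_that("missing targets are imputed at the class-wise worst case", {
  cls <- setNames(rep(c("control", "dex"), each = 2), sprintf("s%d", 1:4))
  m <- rbind(s1 = c(gene = 28, r1 = 20),
             s2 = c(gene = 29, r1 = 20),
             s3 = c(gene = NA, r1 = 20),
             s4 = c(gene = 27, r1 = 20))
  norm <- normalize_dcq(dcq_summaries(m, cls), "r1")
  # s3 (dex) imputed at dex-wise max dCq + 0.5 = (27 - 20) + 0.5
  expect_equal(norm$dcq["s3", "gene"], 7.5)
  expect_true(norm$imputed["s3", "gene"])
  expect_equal(sum(norm$imputed), 1)
})

test_that("delta-delta-Cq has the documented closed forms and sign convention", {
  cls <- setNames(rep(c("control", "dex"), each = 3), sprintf("s%d", 1:6))
  dcq <- matrix(c(5, 5, 5, 3, 3, 3), ncol = 1,
                dimnames = list(names(cls), "gene"))
  res <- delta_delta_cq(dcq, cls)
  expect_equal(res$de$log2_fc, 2)              # lower dCq in treated = up
  expect_equal(unname(res$rq[, "gene"]), 2^-(dcq[, 1] - 5), ignore_attr = TRUE)
  expect_equal(unname(res$rq["s4", "gene"]), 4)
  expect_true(res$de$significant)

  # null case: treated identical to control
  dcq0 <- matrix(rep(c(5, 6, 7), 2), ncol = 1,
                 dimnames = list(names(cls), "gene"))
  res0 <- delta_delta_cq(dcq0, cls)
  expect_equal(res0$de$log2_fc, 0)
  expect_lte(res0$de$ci95_low, 0)
  expect_gte(res0$de$ci95_high, 0)
  expect_false(res0$de$significant)
  # CI brackets the estimate by construction
  expect_lte(res0$de$ci95_low, res0$de$log2_fc)
  expect_gte(res0$de$ci95_high, res0$de$log2_fc)
})

test_that("Tukey-adjusted p matches the two-group comparison run directly", {
  set.seed(8)
  cls <- setNames(rep(c("control", "dex", "therapeutic"), c(6, 6, 2)),
                  sprintf("s%d", 1:14))
  dcq <- matrix(rnorm(14, 5) - 1.2 * (cls == "dex"), ncol = 1,
                dimnames = list(names(cls), "gene"))
  res <- delta_delta_cq(dcq, cls)
  fit <- stats::aov(dcq[, 1] ~ factor(cls))
  ref <- stats::TukeyHSD(fit)[[1]]["dex-control", "p adj"]
  expect_equal(res$de$p_value, unname(ref), tolerance = 1e-12)
})

test_that("planted differential expression is recovered on a default study", {
  cache <- default_study_cache()
  study <- cache$study
  norm <- normalize_dcq(cache$summaries, c("RPLP0", "HSPA8"))
  meta <- study$metadata
  cls <- setNames(meta$class, meta$sample_id)
  base <- meta$sample_id[meta$dilution == 1]
  de <- delta_delta_cq(norm$dcq[base, ], cls[base])$de
  expect_equal(ncol(norm$dcq), 30)             # 32 targets - 2 references
  planted <- planted_de_genes(study$truth)
  truth <- study$truth
  # every strongly planted effect is detected with the right sign
  strong <- truth$symbol[abs(truth$log2_effect) >= 1.5 &
                           truth$role == "biomarker"]
  found <- de$gene[de$significant]
  expect_lte(length(setdiff(planted, found)), 1)
  sgn <- sign(de$log2_fc[match(planted, de$gene)])
  expect_equal(sgn, sign(truth$log2_effect[match(planted, truth$symbol)]))
  # significance flag is exactly p < 0.05
  expect_equal(de$significant, de$p_value < 0.05)
})
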