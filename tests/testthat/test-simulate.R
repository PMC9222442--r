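test_that("default study has the emulated trial's structure", {
  cache <- default_study_cache()
  study <- cache$study
  cq <- study$cq_table

  expect_length(unique(cq$target), 32)
  expect_length(unique(cq$source_sample), 37)          # 12 + 23 + 2 animals
  expect_equal(nrow(study$metadata), 52)               # profiles incl. replicates
  # one Cq per (profile, target, well), triplicate wells
  expect_equal(nrow(cq), 52 * 32 * 3)
  expect_false(anyDuplicated(cq[, c("sample_id", "target", "well")]) > 0)
  counts <- table(study$metadata$class[study$metadata$dilution == 1])
  expect_equal(as.integer(counts[c("control", "dex", "therapeutic")]),
               c(12L, 23L, 2L))
  # fibre data cover 35 animals x 25 diameters, all positive
  expect_equal(length(unique(study$fibre_table$sample_id)), 35)
  expect_true(all(table(study$fibre_table$sample_id) == 25))
  expect_true(all(study$fibre_table$diameter_um > 0))
})

test_that("generator is deterministic for a fixed seed", {
  d <- study_design(seed = 11)
  s1 <- generate_study(design = d)
  s2 <- generate_study(design = d)
  expect_identical(s1$cq_table, s2$cq_table)
  expect_identical(s1$fibre_table, s2$fibre_table)
  s3 <- generate_study(design = study_design(seed = 12))
  expect_false(identical(s1$cq_table$cq, s3$cq_table$cq))
})

test_that("noise-free planted shift moves treated Cq by exactly -log2_effect", {
  panel <- gene_spec("g1", baseline_cq = 25, log2_effect = 2,
                     replicate_sd = 0, sample_sd = 0)
  d <- small_design(n_control = 3, n_treated = 3, seed = 5)
  cq <- generate_cq_dataset(panel, d, sample_shift_sd = 0, response_sd = 0)
  expect_equal(unique(cq$cq[cq$class == "control"]), 25)
  expect_equal(unique(cq$cq[cq$class == "dex"]), 23)
})

test_that("technical replicates shift Cq by log2(dilution)", {
  panel <- gene_spec("g1", baseline_cq = 25, replicate_sd = 0, sample_sd = 0)
  d <- study_design(n_control = 4, n_treated = 0, n_therapeutic = 0,
                    tech_reps_control = 2, tech_reps_treated = 0,
                    dilution_levels = 10,
                    fibre_missing_treated = 0,
                    fibre_missing_therapeutic = 0, seed = 3)
  cq <- generate_cq_dataset(panel, d, sample_shift_sd = 0, response_sd = 0)
  expect_equal(unique(cq$cq[cq$dilution == 1]), 25)
  expect_equal(unique(cq$cq[cq$dilution == 10]), round(25 + log2(10), 4))
})

test_that("null effects make class labels exchangeable (type I ~ nominal)", {
  panel <- null_panel()
  rejections <- 0; tests <- 0
  for (s in 1:80) {
    cq <- generate_cq_dataset(panel, small_design(6, 6, seed = 1000 + s))
    m <- cq_matrix(aggregate_replicates(cq))
    cls <- rep(c("control", "dex"), each = 6)
    for (g in colnames(m)) {
      tests <- tests + 1
      rejections <- rejections +
        (stats::t.test(m[cls == "control", g], m[cls == "dex", g])$p.value < 0.05)
    }
  }
  # 240 nominal-5% tests: binomial 99.9% band around 12
  expect_gt(rejections / tests, 0.005)
  expect_lt(rejections / tests, 0.12)
})

test_that("empirical log2FC converges to the planted effect at large n, small noise", {
  panel <- dplyr::bind_rows(
    gene_spec("ref1", "reference_candidate", 20, replicate_sd = 0.05,
              sample_sd = 0),
    gene_spec("ref2", "reference_candidate", 21, replicate_sd = 0.05,
              sample_sd = 0),
    gene_spec("up", baseline_cq = 25, log2_effect = 1.5,
              replicate_sd = 0.05, sample_sd = 0),
    gene_spec("down", baseline_cq = 26, log2_effect = -1.2,
              replicate_sd = 0.05, sample_sd = 0)
  )
  d <- small_design(n_control = 200, n_treated = 200, seed = 9)
  cq <- generate_cq_dataset(panel, d, response_sd = 0)
  summ <- aggregate_replicates(cq)
  dcq <- normalize_dcq(summ, c("ref1", "ref2"))$dcq
  cls <- rep(c("control", "dex"), c(200, 200))
  names(cls) <- sprintf(rep(c("CTRL%02d", "DEX%02d"), c(200, 200)),
                        c(1:200, 1:200))
  de <- delta_delta_cq(dcq, cls)$de
  expect_equal(de$log2_fc[de$gene == "up"], 1.5, tolerance = 0.05)
  expect_equal(de$log2_fc[de$gene == "down"], -1.2, tolerance = 0.05)
})

test_that("fibre generator respects its degenerate and calibrated regimes", {
  d <- small_design(n_control = 6, n_treated = 6, seed = 2)
  # sd -> 0: every diameter equals its group mean
  f0 <- generate_fibre_data(d, control_mean = 44.6, treated_mean = 40.5,
                            sd = 0, within_sd = 0)
  expect_true(all(f0$diameter_um[f0$class == "control"] == 44.6))
  expect_true(all(f0$diameter_um[f0$class == "dex"] == 40.5))
  # determinism
  expect_identical(generate_fibre_data(d), generate_fibre_data(d))
  # group means of per-sample means near targets at default spread
  d2 <- small_design(n_control = 12, n_treated = 22, seed = 4)
  f <- generate_fibre_data(d2)
  ps <- tapply(f$diameter_um, f$sample_id, mean)
  cls <- f$class[match(names(ps), f$sample_id)]
  for (g in c("control", "dex")) {
    target <- if (g == "control") 44.6 else 40.5
    n_g <- sum(cls == g)
    sem <- sd(ps[cls == g]) / sqrt(n_g)
    expect_lt(abs(mean(ps[cls == g]) - target), 2 * sem + 1e-9)
  }
  expect_error(generate_fibre_data(d, control_mean = -1), "must be > 0")
})

test_that("invalid panels and designs are rejected", {
  dup <- dplyr::bind_rows(gene_spec("g1", baseline_cq = 20),
                          gene_spec("g1", baseline_cq = 22))
  expect_error(generate_cq_dataset(dup, small_design()), "duplicate")
  expect_error(study_design(n_control = -1), "counts")
  expect_error(study_design(wells_per_target = 0), "wells_per_target")
  bad_ref <- gene_spec("r", "reference_candidate", 20, log2_effect = 3)
  expect_error(validate_panel(bad_ref), "reference candidates")
  expect_error(validate_panel(gene_spec("g", baseline_cq = 20,
                                        dropout_rate = 1.5)), "dropout")
})

test_that("therapeutic animals are drawn from the control distribution", {
  panel <- gene_spec("g1", baseline_cq = 25, log2_effect = 3,
                     replicate_sd = 0, sample_sd = 0)
  d <- study_design(n_control = 3, n_treated = 3, n_therapeutic = 3,
                    tech_reps_control = 0, tech_reps_treated = 0,
                    fibre_missing_treated = 0,
                    fibre_missing_therapeutic = 0, seed = 8)
  cq <- generate_cq_dataset(panel, d, sample_shift_sd = 0, response_sd = 0)
  expect_equal(unique(cq$cq[cq$class == "therapeutic"]),
               unique(cq$cq[cq$class == "control"]))
})
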