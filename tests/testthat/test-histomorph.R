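fibre_tbl <- function(values, sample_id = "s1", class = "control") {
  tibble::tibble(sample_id = sample_id, class = class,
                 fibre_index = seq_along(values), diameter_um = values)
}

test_that("constant diameters give degenerate descriptive statistics", {
  tb <- dplyr::bind_rows(
    fibre_tbl(rep(40, 25), "s1", "control"),
    fibre_tbl(rep(40, 25), "s2", "control"),
    fibre_tbl(rep(42, 25), "s3", "dex"),
    fibre_tbl(rep(38, 25), "s4", "dex")
  )
  ms <- summarize_fibres(tb)
  s1 <- ms$per_sample[ms$per_sample$sample_id == "s1", ]
  expect_equal(s1$mean, 40); expect_equal(s1$sd, 0)
  expect_equal(s1$median, 40); expect_equal(s1$min, 40); expect_equal(s1$max, 40)
  grp <- ms$per_group[ms$per_group$class == "dex", ]
  expect_equal(grp$group_mean, 40)
  expect_equal(grp$group_sem, grp$group_sd / sqrt(grp$n))
  expect_true(grp$group_min <= grp$group_median &&
                grp$group_median <= grp$group_max)
})

test_that("summaries are invariant to diameter order", {
  set.seed(9)
  tb <- dplyr::bind_rows(lapply(1:4, function(i) {
    fibre_tbl(rlnorm(25, log(38 + i), 0.2), sprintf("s%d", i),
              if (i <= 2) "control" else "dex")
  }))
  shuffled <- tb[order(tb$sample_id, runif(nrow(tb))), ]
  shuffled$fibre_index <- tb$fibre_index
  a <- summarize_fibres(tb)
  b <- summarize_fibres(shuffled)
  expect_equal(a$per_sample, b$per_sample)
  expect_equal(a$test, b$test)
})

test_that("group t-test holds its nominal level on null fibre data", {
  rej <- 0; n_sim <- 150
  for (s in 1:n_sim) {
    d <- small_design(n_control = 8, n_treated = 8, seed = 3000 + s)
    f <- generate_fibre_data(d, control_mean = 42, treated_mean = 42, sd = 7)
    rej <- rej + (summarize_fibres(f)$test$p_value < 0.05)
  }
  # binomial band around 5% of 150
  expect_gt(rej / n_sim, 0.005)
  expect_lt(rej / n_sim, 0.12)
})

test_that("the emulated trial's effect size is mostly non-significant", {
  hits <- 0; n_sim <- 30
  for (s in 1:n_sim) {
    d <- study_design(seed = 4000 + s)
    f <- generate_fibre_data(d)   # defaults: 44.6 vs 40.5, sd 8
    f <- f[f$class != "therapeutic", ]
    hits <- hits + (summarize_fibres(f)$test$p_value > 0.05)
  }
  expect_gt(hits / n_sim, 0.5)
})

test_that("fusion appends exactly the three histology summaries", {
  cache <- default_study_cache()
  study <- cache$study
  norm <- normalize_dcq(cache$summaries, c("RPLP0", "HSPA8"))
  morpho <- summarize_fibres(study$fibre_table)
  fused <- fuse_datasets(norm$dcq, morpho)
  expect_equal(ncol(fused$matrix), 33)                # 30 + mean, median, sd
  expect_equal(tail(colnames(fused$matrix), 3),
               c("fibre_mean", "fibre_median", "fibre_sd"))
  # profiles without morphometry (tech replicates + missing animals) dropped
  expect_equal(nrow(fused$matrix), 35)
  expect_equal(sort(unique(c(rownames(fused$matrix), fused$dropped))),
               sort(rownames(norm$dcq)))
  expect_false(anyNA(fused$matrix))
})

test_that("fusion rejects degenerate inputs", {
  morpho <- summarize_fibres(dplyr::bind_rows(
    fibre_tbl(rep(40, 5), "s1", "control"), fibre_tbl(rep(41, 5), "s2", "control"),
    fibre_tbl(rep(42, 5), "s3", "dex"), fibre_tbl(rep(39, 5), "s4", "dex")))
  empty <- matrix(numeric(0), nrow = 0, ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fuse_datasets(empty, morpho), "empty")
  other <- matrix(1:6, 2, dimnames = list(c("x1", "x2"), c("a", "b", "c")))
  expect_error(fuse_datasets(other, morpho), "overlapping")
})

test_that("empty diameter lists are skipped with a warning", {
  tb <- dplyr::bind_rows(
    fibre_tbl(c(40, 41, 42), "s1", "control"),
    fibre_tbl(c(39, 40, 41), "s2", "control"),
    tibble::tibble(sample_id = "s3", class = "dex",
                   fibre_index = 1, diameter_um = NA_real_),
    fibre_tbl(c(43, 44, 45), "s4", "dex"),
    fibre_tbl(c(41, 42, 43), "s5", "dex")
  )
  expect_warning(ms <- summarize_fibres(tb), "s3")
  expect_false("s3" %in% ms$per_sample$sample_id)
})
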