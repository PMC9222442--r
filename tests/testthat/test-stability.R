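make_summaries <- function(m, classes = NULL) {
  # samples x genes mean-Cq matrix -> summaries tibble
  tb <- tidyr::expand_grid(sample_id = rownames(m), target = colnames(m))
  tb$mean_cq <- as.vector(t(m))
  if (!is.null(classes)) tb$class <- classes[tb$sample_id]
  tb
}

test_that("a constant-offset gene pair is perfectly stable under geNorm", {
  set.seed(1)
  base <- rnorm(8, 24, 1)
  m <- cbind(g1 = base, g2 = base + 2, g3 = base + rnorm(8, 0, 1.5))
  rownames(m) <- sprintf("s%d", 1:8)
  g <- genorm_rank(make_summaries(m), c("g1", "g2", "g3"))
  expect_equal(g$selected, c("g1", "g2"))
  expect_equal(sd(m[, "g1"] - m[, "g2"]), 0)
  expect_equal(g$ranking[1], "g3")          # excluded first
})

test_that("geNorm M equals brute-force pairwise-SD enumeration", {
  set.seed(2)
  for (k in 3:6) {
    m <- matrix(rnorm(8 * k, 25, 2), 8,
                dimnames = list(sprintf("s%d", 1:8), sprintf("g%d", 1:k)))
    g <- genorm_rank(make_summaries(m), colnames(m))
    # independent double loop over gene pairs
    for (j in colnames(m)) {
      vs <- vapply(setdiff(colnames(m), j),
                   function(l) sd(m[, j] - m[, l]), numeric(1))
      expect_equal(unname(g$m_values[j]), mean(vs), tolerance = 1e-12)
    }
  }
})

test_that("geNorm refuses underdetermined inputs", {
  m <- matrix(rnorm(16), 8, 2,
              dimnames = list(sprintf("s%d", 1:8), c("g1", "g2")))
  expect_error(genorm_rank(make_summaries(m), c("g1", "g2")), ">= 3")
})

test_that("NormFinder puts a noiseless class-invariant gene first", {
  set.seed(3)
  cls <- setNames(rep(c("control", "dex"), each = 50), sprintf("s%d", 1:100))
  m <- cbind(flat = rep(25, 100),
             noisy = rnorm(100, 25, 1),
             mid = rnorm(100, 24, 0.5),
             other = rnorm(100, 25, 0.7))
  rownames(m) <- names(cls)
  nf <- normfinder_rank(make_summaries(m, cls), colnames(m), cls)
  expect_equal(nf$ranking[1], "flat")
  expect_equal(unname(which.min(nf$stability)), 1L)
})

test_that("planted reference genes outrank differential genes", {
  set.seed(4)
  cls <- setNames(rep(c("control", "dex"), each = 10), sprintf("s%d", 1:20))
  shift <- rep(c(0, 1), each = 10)
  m <- cbind(ref1 = rnorm(20, 20, 0.15), ref2 = rnorm(20, 21, 0.15),
             de1 = rnorm(20, 24, 0.3) - 1.5 * shift,
             de2 = rnorm(20, 25, 0.3) + 1.2 * shift,
             de3 = rnorm(20, 26, 0.3) - 2.0 * shift)
  rownames(m) <- names(cls)
  nf <- normfinder_rank(make_summaries(m, cls), colnames(m), cls)
  expect_setequal(nf$ranking[1:2], c("ref1", "ref2"))
  g <- genorm_rank(make_summaries(m), colnames(m))
  expect_setequal(g$selected, c("ref1", "ref2"))
})

test_that("geNorm and NormFinder agree on balanced homoscedastic nulls", {
  set.seed(5)
  cls <- setNames(rep(c("control", "dex"), each = 12), sprintf("s%d", 1:24))
  sds <- c(a = 0.1, b = 0.12, c = 0.8, d = 1.0)
  m <- sapply(names(sds), function(g) rnorm(24, 25, sds[g]))
  rownames(m) <- names(cls)
  g <- genorm_rank(make_summaries(m), colnames(m))
  nf <- normfinder_rank(make_summaries(m, cls), colnames(m), cls)
  expect_setequal(g$selected, c("a", "b"))
  expect_setequal(nf$selected, c("a", "b"))
})

test_that("NormFinder needs two groups and enough genes", {
  cls <- setNames(rep("control", 8), sprintf("s%d", 1:8))
  m <- matrix(rnorm(8 * 4, 25, 1), 8,
              dimnames = list(names(cls), sprintf("g%d", 1:4)))
  expect_error(normfinder_rank(make_summaries(m, cls), colnames(m), cls),
               "2 groups")
  cls2 <- setNames(rep(c("control", "dex"), each = 4), rownames(m))
  expect_error(normfinder_rank(make_summaries(m, cls2), c("g1", "g2"), cls2),
               ">= 3")
})

test_that("stability selection recovers the planted pair on a full study", {
  cache <- default_study_cache()
  sel <- select_references(cache$summaries,
                           c("RPLP0", "HSPA8", "GAPDH", "PPIA"))
  expect_equal(sel$genorm$selected, c("HSPA8", "RPLP0"))
  expect_equal(sel$normfinder$selected, c("HSPA8", "RPLP0"))
  expect_true(sel$agreement)
})
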