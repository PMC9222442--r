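test_that("toroidal ring distances are symmetric, translation invariant, max 4", {
  D <- torus_distances(c(8, 8))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 64))
  expect_equal(max(D), 4)
  # wraparound: distances depend only on the index offset on the torus
  idx <- function(r, c) (c - 1) * 8 + r
  for (k in 1:20) {
    set.seed(k)
    a <- sample(8, 2); b <- sample(8, 2); s <- sample(8, 2)
    shift <- function(p) c((p[1] + s[1] - 1) %% 8 + 1, (p[2] + s[2] - 1) %% 8 + 1)
    expect_equal(D[idx(a[1], a[2]), idx(b[1], b[2])],
                 D[idx(shift(a)[1], shift(a)[2]), idx(shift(b)[1], shift(b)[2])])
  }
})

test_that("one batch step on a 2x2 map equals the hand-computed update", {
  p <- 3
  x <- rbind(c(0.1, 0.2, 0.3), c(0.9, 0.8, 0.7))
  colnames(x) <- c("a", "b", "c")
  cls <- c("control", "dex")
  seed <- 99
  model <- skn_fit(x, cls, grid = c(2, 2), epochs = 1, lr = c(0.5, 0.5),
                   neighbourhood = "bubble", seed = seed)

  # replicate initialisation and one radius-0, rate-0.5 batch update by hand
  set.seed(seed)
  Wx <- matrix(runif(4 * p), 4)
  Wy <- matrix(runif(4 * 2), 4)
  Y <- rbind(c(1, 0), c(0, 1))
  win <- integer(2)
  for (i in 1:2) {
    d <- rowSums(sweep(Wx, 2, x[i, ])^2) + rowSums(sweep(Wy, 2, Y[i, ])^2)
    win[i] <- which.min(d)
  }
  expect_length(unique(win), 2)   # distinct winners for these samples
  for (i in 1:2) {
    j <- win[i]
    Wx[j, ] <- Wx[j, ] + 0.5 * (x[i, ] - Wx[j, ])
    Wy[j, ] <- Wy[j, ] + 0.5 * (Y[i, ] - Wy[j, ])
  }
  Wy[Wy < 0] <- 0; Wy[Wy > 1] <- 1
  expect_equal(unname(model$input_weights), unname(Wx), tolerance = 1e-12)
  expect_equal(unname(model$class_weights), unname(Wy), tolerance = 1e-12)
})

test_that("a single training sample becomes a fixed point of its winner", {
  x <- matrix(c(0.3, 0.6, 0.9, 0.1), 1,
              dimnames = list("s1", sprintf("v%d", 1:4)))
  # two identical samples in different classes is degenerate; use two copies
  xx <- rbind(s1 = x[1, ], s2 = x[1, ])
  model <- skn_fit(xx, c("control", "dex"), grid = c(4, 4), epochs = 200,
                   seed = 2)
  pred <- skn_predict(model, x)
  expect_lt(pred$distance, 1e-6)
})

test_that("training is deterministic for a fixed seed and rejects bad input", {
  d <- separable_data(n_per = 6, p = 4, seed = 24)
  xs <- range_scale(autoscale(d$x))$X
  m1 <- skn_fit(xs, d$classes, epochs = 30, seed = 5)
  m2 <- skn_fit(xs, d$classes, epochs = 30, seed = 5)
  expect_identical(m1$input_weights, m2$input_weights)
  expect_identical(m1$neuron_class, m2$neuron_class)

  expect_error(skn_fit(d$x, d$classes), "range-scaled")
  expect_error(skn_fit(xs, rep("control", nrow(xs))), "classes")
  expect_error(skn_predict(m1, xs[, 1:2]), "mismatch")
  expect_true(all(m1$class_weights >= 0 & m1$class_weights <= 1))
})

test_that("well-separated classes are fit perfectly with contiguous regions", {
  d <- separable_data(n_per = 12, p = 5, delta = 6, seed = 25)
  fit <- fit_model(d$x, d$classes, skn_spec(seed = 7))
  expect_equal(fit$metrics$ner_pct, 100)
  tab <- table(fit$model$neuron_class)
  expect_true(all(tab > 0))       # both classes own part of the map
  # class regions are spatially coherent: most neurons have a same-class
  # neighbour at ring distance 1
  D <- torus_distances(c(8, 8))
  same <- vapply(seq_len(64), function(j) {
    nb <- which(D[j, ] == 1)
    any(fit$model$neuron_class[nb] == fit$model$neuron_class[j])
  }, logical(1))
  expect_gt(mean(same), 0.9)
})

test_that("weight-map PCA reflects the planted structure", {
  # one-variable map: single PC carries all variance
  x1 <- matrix(seq(0, 1, length.out = 10), ncol = 1,
               dimnames = list(NULL, "v"))
  m1 <- skn_fit(x1, rep(c("control", "dex"), each = 5), grid = c(4, 4),
                epochs = 50, seed = 3)
  wp1 <- som_weight_pca(m1)
  expect_equal(ncol(wp1$loadings), 1)
  expect_equal(wp1$explained_variance_pct[1], 100)
  expect_error(som_weight_pca(list()), "skn_model")

  # separated classes: neuron scores separate classes on an early PC, and
  # oppositely moving variables load with opposite signs
  set.seed(26)
  n <- 12
  up <- c(rnorm(n, 0), rnorm(n, 3))       # higher in dex
  down <- c(rnorm(n, 3), rnorm(n, 0))     # lower in dex
  x <- cbind(up = up, down = down, noise = rnorm(2 * n))
  cls <- rep(c("control", "dex"), each = n)
  fit <- fit_model(x, cls, skn_spec(seed = 11))
  wp <- som_weight_pca(fit$model)
  tvals <- vapply(1:min(3, ncol(wp$scores)), function(k) {
    abs(t.test(wp$scores[wp$neuron_class == "control", k],
               wp$scores[wp$neuron_class == "dex", k])$statistic)
  }, numeric(1))
  best <- which.max(tvals)
  expect_gt(tvals[best], 3)
  expect_lt(wp$loadings["up", best] * wp$loadings["down", best], 0)
})
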