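make_toy_dataset <- function(n_per_class = 10, sep = 4, noise = 0.3,
                             n_feat = 12, seed = 1) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(n_per_class * n_feat, 0, noise), n_per_class),
    matrix(rnorm(n_per_class * n_feat, 0, noise), n_per_class) +
      matrix(rep(c(rep(sep, n_feat / 2), rep(0, n_feat / 2)), each = n_per_class),
             n_per_class)
  )
  spectral_dataset(m, rep(c("a", "b"), each = n_per_class), seq_len(n_feat))
}

test_that("separable classes are fit perfectly and prediction is labelled", {
  ds <- make_toy_dataset(sep = 6, noise = 0.05)
  model <- fit_plsda(ds, n_components = 1)
  pred <- predict(model, ds$matrix)
  expect_equal(pred$label, ds$labels)

  one <- raman_spectrum(ds$axis, ds$matrix[1, ])
  d <- predict(model, one)
  expect_s3_class(d, "diagnosis")
  expect_equal(d$label, "a")
  expect_length(d$scores, 2)
})

test_that("model fitting validates its inputs", {
  ds <- make_toy_dataset()
  single <- spectral_dataset(ds$matrix, rep("a", nrow(ds$matrix)), ds$axis)
  expect_error(fit_plsda(single), "two classes")
  expect_error(fit_plsda(ds, n_components = 100), "n_components")
  expect_error(predict(fit_plsda(ds), matrix(0, 1, 3)), "axis")
})

test_that("latent-variable scores match a brute-force eigen-decomposition oracle", {
  set.seed(21)
  X <- matrix(rnorm(24), 6, 4)
  labels <- rep(c("a", "b"), each = 3)
  ds <- spectral_dataset(X, labels, 1:4)
  model <- fit_plsda(ds, n_components = 2)
  Y <- outer(labels, sort(unique(labels)), `==`) * 1
  oracle <- eigen_pls_oracle(X, Y, 2)
  for (h in 1:2) {
    agreement <- abs(cor(model$scores[, h], oracle[, h]))
    expect_gt(agreement, 1 - 1e-8)
    expect_equal(abs(model$scores[, h]), abs(oracle[, h]), tolerance = 1e-6)
  }
})

test_that("latent variables agree with an independent PLS-DA implementation", {
  ds <- make_toy_dataset(n_per_class = 8, sep = 3, noise = 0.5, seed = 5)
  model <- fit_plsda(ds, n_components = 2)
  ref <- mixOmics::plsda(ds$matrix, factor(ds$labels), ncomp = 2,
                         scale = FALSE)
  for (h in 1:2) {
    expect_gt(abs(cor(model$scores[, h], ref$variates$X[, h])), 0.99)
  }
})

test_that("threshold semantics are monotone with sensible bounds", {
  ds <- make_toy_dataset(sep = 6, noise = 0.05)
  model <- fit_plsda(ds, positive_class = "b")
  all_pos <- predict(model, ds$matrix, threshold = -1e6)
  expect_true(all(all_pos$positive))
  none <- predict(model, ds$matrix, threshold = 1e6)
  expect_false(any(none$positive))

  counts <- vapply(seq(-0.5, 1.5, by = 0.1), function(thr) {
    sum(predict(model, ds$matrix, threshold = thr)$positive)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("venetian-blinds folds follow index arithmetic", {
  folds <- venetian_folds(10, 5)
  expect_equal(folds, rep(1:5, 2))
  for (f in 1:5) {
    expect_equal(which(folds == f), c(f, f + 5L))
  }
})

test_that("cross-validation is perfect for separable data and invariant to duplication", {
  ds <- make_toy_dataset(sep = 6, noise = 0.1)
  cv <- venetian_blinds_cv(ds, n_components = 2, n_splits = 5)
  expect_equal(cv$overall_accuracy, 1)
  expect_equal(unname(cv$per_class_accuracy), c(1, 1))

  dup <- spectral_dataset(rbind(ds$matrix, ds$matrix),
                          c(ds$labels, ds$labels), ds$axis)
  cv2 <- venetian_blinds_cv(dup, n_components = 2, n_splits = 5)
  expect_equal(cv2$overall_accuracy, cv$overall_accuracy)

  expect_error(venetian_blinds_cv(ds, n_splits = 1000), "exceeds")
})

test_that("confusion matrix and per-class accuracies are mutually consistent", {
  ds <- make_toy_dataset(sep = 1, noise = 1, seed = 3)
  cv <- venetian_blinds_cv(ds, n_components = 2, n_splits = 5)
  expect_equal(sum(cv$confusion), nrow(ds$matrix))
  expect_equal(unname(diag(cv$confusion) / rowSums(cv$confusion)),
               unname(cv$per_class_accuracy))
  expect_equal(sum(diag(cv$confusion)) / sum(cv$confusion),
               cv$overall_accuracy)
})

test_that("cross-validated accuracy collapses to chance for unrelated labels", {
  accs <- vapply(1:5, function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(60 * 20), 60, 20)
    labels <- sample(rep(c("a", "b"), each = 30))
    ds <- spectral_dataset(m, labels, 1:20)
    venetian_blinds_cv(ds, n_components = 2, n_splits = 10)$overall_accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.72)
  expect_gt(mean(accs), 0.28)
})

test_that("pca scores satisfy variance ordering and match an eigen oracle", {
  # data on a line: one dominant direction
  set.seed(2)
  t <- rnorm(20)
  m <- cbind(t, 2 * t, -t) + matrix(rnorm(60, 0, 1e-4), 20, 3)
  ds <- spectral_dataset(m, rep(c("a", "b"), 10), 1:3)
  pc <- pca_scores(ds, 2)
  expect_gt(pc$explained_variance[1], 0.999)
  expect_true(all(diff(pc$explained_variance) <= 0))
  expect_lte(sum(pc$explained_variance), 1)

  set.seed(8)
  X <- matrix(rnorm(20), 5, 4)
  ds <- spectral_dataset(X, rep(c("a", "b"), c(2, 3)), 1:4)
  pc <- pca_scores(ds, 2)
  ev <- eigen(cov(X), symmetric = TRUE)
  Xc <- scale(X, scale = FALSE)
  for (h in 1:2) {
    expect_equal(abs(pc$scores[, h]), abs(as.numeric(Xc %*% ev$vectors[, h])),
                 tolerance = 1e-8)
  }
  expect_error(pca_scores(ds, 10), "n_pcs")
})
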