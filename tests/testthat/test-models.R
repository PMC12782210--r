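# Classical per-user models: grid-search CV, prediction contract,
# determinism.

test_that("all classical kinds separate well-separated clusters", {
  d <- separable_clusters()
  for (kind in c("knn", "rf", "nn")) {
    grid <- hyperparameter_grid(knn_k = 5L, rf_max_depth = 10L,
                                nn_l2_alpha = 1e-4)
    m <- fit_classical(kind, d$X, d$y, grid = grid, seed = 2)
    pred <- predict(m, d$X)
    expect_equal(compute_metrics(d$y, pred$decision)$f1, 1.0,
                 info = kind)
  }
})

test_that("single-class training labels are rejected", {
  d <- separable_clusters()
  expect_error(fit_classical("knn", d$X, rep(0L, nrow(d$X))), "single class")
})

test_that("a one-setting grid equals fitting that setting directly", {
  d <- separable_clusters(seed = 5)
  m1 <- fit_classical("knn", d$X, d$y,
                      grid = hyperparameter_grid(knn_k = 5L), seed = 9)
  m2 <- fit_classical("knn", d$X, d$y,
                      grid = hyperparameter_grid(knn_k = c(5L, 10L)), seed = 9)
  expect_null(m1$cv_table)                      # no search ran
  expect_identical(m1$hyperparameters$k, 5L)
  set.seed(77)
  Xnew <- matrix(rnorm(80), 10, 8)
  # scores with the same k agree regardless of how k was chosen
  if (m2$hyperparameters$k == 5L)
    expect_equal(predict(m1, Xnew)$score, predict(m2, Xnew)$score)
})

test_that("k values at or above the training size are skipped, not fatal", {
  d <- separable_clusters(n_pos = 6L, n_neg = 9L, seed = 3)
  expect_warning(
    m <- fit_classical("knn", d$X, d$y,
                       grid = hyperparameter_grid(knn_k = c(3L, 100L, 200L)),
                       seed = 1),
    "skipping k")
  expect_identical(m$hyperparameters$k, 3L)
  expect_error(
    suppressWarnings(
      fit_classical("knn", d$X, d$y,
                    grid = hyperparameter_grid(knn_k = c(100L, 200L)))),
    "skipped")
})

test_that("grid search selects a setting no other setting beats on CV F1", {
  d <- separable_clusters(n_pos = 30L, n_neg = 60L, gap = 1.2, seed = 7)
  m <- fit_classical("knn", d$X, d$y,
                     grid = hyperparameter_grid(knn_k = c(5L, 10L, 25L)),
                     seed = 4)
  tab <- m$cv_table
  expect_s3_class(tab, "data.frame")
  chosen <- tab$cv_f1[tab$setting == m$hyperparameters$k]
  expect_true(all(chosen >= tab$cv_f1))
  # first-in-grid tie-break: the chosen setting is the first argmax
  expect_identical(m$hyperparameters$k,
                   as.integer(tab$setting[which.max(tab$cv_f1)]))
})

test_that("decisions are a fixed threshold of scores with 0.5 positive", {
  d <- separable_clusters(seed = 11)
  m <- fit_classical("knn", d$X, d$y,
                     grid = hyperparameter_grid(knn_k = 2L), seed = 1)
  set.seed(12)
  pred <- predict(m, rbind(d$X, matrix(rnorm(160, 3), 20, 8)))
  expect_identical(pred$decision, as.integer(pred$score >= 0.5))
  # with k = 2, midpoints between the classes produce exact 0.5 scores
  mid <- (d$X[1, ] + d$X[nrow(d$X), ]) / 2
  ps <- predict(m, rbind(mid))
  if (ps$score == 0.5) expect_identical(ps$decision, 1L)
})

test_that("fits are reproducible from their seeds", {
  d <- separable_clusters(n_pos = 20L, n_neg = 40L, gap = 1.5, seed = 8)
  set.seed(99)
  Xnew <- matrix(rnorm(14 * 8), 14, 8)
  for (kind in c("rf", "nn")) {
    grid <- hyperparameter_grid(rf_max_depth = c(10L, 50L),
                                nn_l2_alpha = c(1e-2, 1e-4))
    m1 <- fit_classical(kind, d$X, d$y, grid = grid, seed = 21)
    m2 <- fit_classical(kind, d$X, d$y, grid = grid, seed = 21)
    expect_identical(predict(m1, Xnew), predict(m2, Xnew), info = kind)
  }
})
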