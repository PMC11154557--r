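make_blobs <- function(n = 120, sep = 6, d = 4, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * d), n, d) + sep * y
  list(X = X, y = y)
}

test_that("window labels follow the any-overlap rule on half-open extents", {
  ann <- data.frame(t_start = c(3.9, 10), t_end = c(6.0, 11),
                    label = c("eating_gesture", "chewing"))
  anchors <- data.frame(t_start = c(3, 3, 5, 6), t_end = c(4, 4, 6, 7))
  expect_equal(label_vectors(anchors[1, ], ann, "eating_gesture"), 1L)
  expect_equal(label_vectors(anchors[2, ], ann, "chewing"), 0L)
  # interval starting exactly at window end: zero overlap
  touch <- data.frame(t_start = 3, t_end = 4)
  ann2 <- data.frame(t_start = 4, t_end = 5, label = "chewing")
  expect_equal(label_vectors(touch, ann2, "chewing"), 0L)
  expect_equal(label_vectors(anchors, ann, "eating_gesture"),
               c(1L, 1L, 1L, 0L))
})

test_that("label prevalence tracks the annotated time fraction", {
  sf <- cached_features()
  y <- label_vectors(sf$imu$windows, sf$annotations, "chewing")
  iv <- sf$annotations[sf$annotations$label == "chewing", ]
  covered <- sum(iv$t_end - iv$t_start)
  dur <- max(sf$imu$windows$t_end)
  # windows overlap-labelled: prevalence >= coverage, within quantization
  expect_gte(mean(y), covered / dur - 0.02)
  expect_lte(mean(y), covered / dur + 2 * nrow(iv) * 1 / dur + 0.02)
})

test_that("the split is 2:1 and statistics are fitted on train only", {
  set.seed(3)
  X <- matrix(stats::rnorm(300 * 8), 300, 8)
  y <- rep(c(0L, 1L), each = 150)
  sp <- split_scale_project(X, y, model_config(), seed = 2)
  expect_lte(abs(length(sp$train$y) - 200), 1)
  expect_lte(abs(length(sp$test$y) - 100), 1)
  # leakage check: replacing one test row leaves the fitted transform alone
  X2 <- X
  te_row <- sp$test_index[1]
  X2[te_row, ] <- X2[te_row, ] + 100
  sp2 <- split_scale_project(X2, y, model_config(), seed = 2)
  expect_identical(sp$scaler, sp2$scaler)
  expect_identical(sp$pca$rotation, sp2$pca$rotation)
  expect_identical(sp$train$X, sp2$train$X)
  # transforming a train-identical copy reproduces the train scores
  own <- bitewatch:::apply_scale_pca(
    list(scaler = sp$scaler, pca = sp$pca, k = sp$n_components),
    X[sp$train_index, , drop = FALSE])
  expect_equal(unname(own), unname(sp$train$X), tolerance = 1e-9)
})

test_that("PCA keeps the smallest component count reaching 95 % variance", {
  set.seed(8)
  X <- matrix(stats::rnorm(200 * 6), 200, 6)
  X <- cbind(X, X[, 1])   # duplicated column collapses under collinearity
  y <- rep(c(0L, 1L), 100)
  sp <- split_scale_project(X, y, model_config(), seed = 1)
  v <- sp$pca$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- sp$n_components
  expect_gte(cum[k], 0.95)
  if (k > 1) expect_lt(cum[k - 1], 0.95)
  # rank argument: the duplicate adds no dimension
  Xs <- matrix(stats::rnorm(200 * 6), 200, 6)
  spa <- split_scale_project(Xs, y, model_config(), seed = 1)
  spb <- split_scale_project(cbind(Xs, Xs[, 1]), y, model_config(), seed = 1)
  expect_equal(spb$n_components, spa$n_components)
})

test_that("degenerate training sets are rejected", {
  X <- matrix(stats::rnorm(40 * 3), 40, 3)
  expect_error(split_scale_project(X[1:20, ], rep(0L, 20), seed = 1),
               ">= 30 vectors")
  expect_error(split_scale_project(X, rep(0L, 40), seed = 1),
               "single class")
  expect_error(train_svm(list(X = X, y = rep(1L, 40))), "single class")
})

test_that("hyperparameter search is deterministic and finds easy structure", {
  blobs <- make_blobs()
  cfg <- model_config(n_iter = 8)
  a <- train_svm(list(X = blobs$X, y = blobs$y), cfg, seed = 4)
  b <- train_svm(list(X = blobs$X, y = blobs$y), cfg, seed = 4)
  expect_identical(a$cost, b$cost)
  expect_identical(a$gamma, b$gamma)
  expect_identical(a$search, b$search)
  expect_equal(a$cv_f1, 1.0)   # linearly separable blobs
})

test_that("label permutation drives CV micro-F1 to chance", {
  blobs <- make_blobs(n = 200, sep = 0)
  set.seed(6)
  yp <- sample(blobs$y)
  fit <- train_svm(list(X = blobs$X, y = yp), model_config(n_iter = 6),
                   seed = 7)
  expect_gte(fit$cv_f1, 0.4)
  expect_lte(fit$cv_f1, 0.65)
})

test_that("micro-averaged F1 equals accuracy for single-label problems", {
  expect_equal(micro_f1(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(micro_f1(c(rep(1, 2), rep(0, 8)), rep(0, 10)), 0.8)
  set.seed(12)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    truth <- sample(seq_len(k), 50, replace = TRUE)
    pred <- sample(seq_len(k), 50, replace = TRUE)
    expect_equal(micro_f1(truth, pred), mean(truth == pred))
  }
})

test_that("a full classification cell is reproducible and beats baseline", {
  blobs <- make_blobs(n = 180, sep = 3)
  cfg <- model_config(n_iter = 6)
  sp <- split_scale_project(blobs$X, blobs$y, cfg, seed = 11)
  fit <- train_svm(sp$train, cfg, seed = 12)
  res <- evaluate_model(fit, sp$test)
  expect_equal(res$tp + res$fp + res$fn + res$tn, res$n_test)
  expect_gte(res$micro_f1, 0)
  expect_lte(res$micro_f1, 1)
  maj <- mean(sp$test$y == as.integer(names(which.max(table(sp$train$y)))))
  expect_gt(res$micro_f1, maj)
})

test_that("an imbalanced measure still beats the all-negative baseline", {
  sf <- fixture("full_features",
                function() session_features(simulate_session(5)))
  cell <- run_cell(list(sf), "eating_gesture", "S", 0, 0,
                   model_config(n_iter = 6), seed = 21)
  expect_lt(cell$prevalence, 0.15)
  expect_gt(cell$micro_f1, cell$baseline_f1)
})

test_that("grid runs enumerate cells and summarize per-measure peaks", {
  sf <- cached_features()
  cfgs <- data.frame(past_s = c(0, 3), future_s = c(0, 3))
  g <- run_grid(list(sf), measures = "chewing",
                combos = list(chewing = c("P", "SPR")), configs = cfgs,
                config = model_config(n_iter = 4), seed = 2)
  expect_equal(nrow(g), 4)
  expect_true(all(g$micro_f1 >= 0 & g$micro_f1 <= 1))
  g2 <- run_grid(list(sf), measures = "chewing",
                 combos = list(chewing = c("P", "SPR")), configs = cfgs,
                 config = model_config(n_iter = 4), seed = 2)
  expect_identical(g$micro_f1, g2$micro_f1)
  s <- summarize_grid(g)
  expect_equal(nrow(s), 1)
  expect_equal(s$peak_micro_f1, max(g$micro_f1))
})
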