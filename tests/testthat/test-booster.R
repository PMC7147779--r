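test_that("leaf weights follow the closed form", {
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_equal(leaf_weight(0, 5, 2), 0)
  w <- sapply(c(0, 1, 5, 50), function(l) abs(leaf_weight(3, 2, l)))
  expect_true(all(diff(w) < 0))
  expect_error(leaf_weight(1, -3, 1), "positive")
  # L1 soft-thresholding shrinks the numerator
  expect_equal(leaf_weight(2, 3, 1, alpha = 0.5), -1.5 / 4)
  expect_equal(leaf_weight(0.3, 3, 1, alpha = 0.5), 0)
})

test_that("a single round at depth 1 equals the exhaustive split oracle", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- as.numeric(runif(n) < plogis(1.5 * x[, 1] - x[, 2]))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    params <- booster_params(eta = 1, max_depth = 1, nrounds = 1,
                             lambda = sample(c(0, 1), 1), gamma = 0)
    fit <- fit_booster(x, y, params)
    want <- oracle_stump(x, y, params$lambda, params$gamma, params$eta,
                         qlogis(mean(y)))
    tree <- fit$trees[[1]]
    if (is.null(want)) {
      expect_true(tree$leaf)
    } else {
      expect_false(tree$leaf)
      expect_equal(tree$feature, colnames(x)[want$feature])
      expect_equal(tree$threshold, want$threshold)
      expect_equal(tree$left$value, want$w_left, tolerance = 1e-12)
      expect_equal(tree$right$value, want$w_right, tolerance = 1e-12)
    }
  }
})

test_that("separable 1-D data splits at the class boundary", {
  x <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), ncol = 1, dimnames = list(NULL, "v"))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_booster(x, y, booster_params(max_depth = 1, nrounds = 1, gamma = 0))
  expect_equal(fit$trees[[1]]$threshold, 7)
})

test_that("an infinite leaf penalty suppresses all splits", {
  set.seed(5)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 15)
  fit <- fit_booster(x, y, booster_params(nrounds = 3, gamma = 1e9))
  expect_true(all(vapply(fit$trees, function(t) t$leaf, logical(1))))
  expect_equal(unique(predict(fit, x, type = "logodds")), fit$base_score,
               tolerance = 1e-12)
})

test_that("training log-loss is non-increasing over rounds", {
  set.seed(8)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.numeric(x[, 1] + 0.5 * x[, 3] + rnorm(50, 0, 0.5) > 0)
  fit <- fit_booster(x, y, booster_params(eta = 0.3, nrounds = 25))
  expect_true(all(diff(fit$train_logloss) <= 1e-10))
})

test_that("with no regularization a depth-1 round is the Newton step", {
  x <- matrix(c(-2, -1, -1.5, 1, 1.5, 2), ncol = 1, dimnames = list(NULL, "v"))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_booster(x, y, booster_params(eta = 1, max_depth = 1, nrounds = 1,
                                          lambda = 0, gamma = 0))
  # base = qlogis(0.5) = 0, so p = 1/2, g = 1/2 - y, h = 1/4 per example
  # left leaf: G = 3/2, H = 3/4 -> w = -2; right leaf: w = +2
  expect_equal(fit$trees[[1]]$left$value, -2, tolerance = 1e-12)
  expect_equal(fit$trees[[1]]$right$value, 2, tolerance = 1e-12)
})

test_that("prediction is the sigmoid of base plus tree sum", {
  mock <- structure(list(trees = list(), params = booster_params(nrounds = 0),
                         feature_names = "f1", base_score = 0,
                         train_logloss = numeric(0)),
                    class = "depscreen_booster")
  x <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "f1"))
  expect_equal(predict(mock, x, type = "prob"), rep(0.5, 5))
  expect_error(predict(mock, matrix(1, 1, 1, dimnames = list(NULL, "zz"))),
               "lacks model features")
})

test_that("explanations are exactly additive and localize single splits", {
  set.seed(12)
  x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(x[, 2] > 0.2)
  fit <- fit_booster(x, y, booster_params(nrounds = 20, max_depth = 3))
  for (i in c(1, 7, 40)) {
    ex <- explain_booster(fit, x[i, ])
    expect_equal(ex$base + sum(ex$deltas),
                 predict(fit, x[i, , drop = FALSE], type = "logodds"),
                 tolerance = 1e-9)
    expect_equal(ex$probability, plogis(ex$logodds))
  }

  stump <- fit_booster(x, y, booster_params(nrounds = 1, max_depth = 1, eta = 1))
  tree <- stump$trees[[1]]
  ex <- explain_booster(stump, x[1, ])
  expect_equal(sum(ex$deltas != 0), 1)
  leaf <- if (x[1, tree$feature_index] < tree$threshold) tree$left else tree$right
  expect_equal(unname(ex$deltas[tree$feature]), leaf$value - tree$value)
})

test_that("input validation", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_booster(x, rep(2, 10)), "0/1")
  expect_error(fit_booster(x, c(1, rep(0, 9))), "at least 2")
})

test_that("JSON serialization round-trips predictions", {
  set.seed(2)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.numeric(x[, 1] > 0)
  fit <- fit_booster(x, y, booster_params(nrounds = 5))
  path <- withr::local_tempfile(fileext = ".json")
  booster_to_json(fit, path)
  back <- booster_from_json(path)
  expect_equal(predict(back, x), predict(fit, x), tolerance = 1e-12)
})

test_that("matches an independent boosting library on shared hyperparameters", {
  skip_if_not_installed("xgboost")
  set.seed(77)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0, 1), n / 2)  # balanced, so both base scores are logit(0.5) = 0
  params <- booster_params(eta = 0.3, max_depth = 2, nrounds = 5, lambda = 1,
                           gamma = 0)
  ours <- fit_booster(x, y, params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgb <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.3, max_depth = 2,
                  lambda = 1, gamma = 0, tree_method = "exact",
                  base_score = 0.5, min_child_weight = 0),
    data = dtrain, nrounds = 5
  )
  expect_equal(predict(ours, x, type = "prob"),
               as.numeric(predict(xgb, dtrain)), tolerance = 1e-5)
})
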