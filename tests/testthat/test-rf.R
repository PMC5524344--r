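test_that("fitting is deterministic in the seed and invariant to row identity", {
  td <- toy_design(1)
  cfg <- forest_config(ntree = 100, mtry = 2, seed = 42)
  m1 <- fit_forest(td$x, td$y, cfg)
  m2 <- fit_forest(td$x, td$y, cfg)
  expect_identical(m1$oob_pred, m2$oob_pred)
  expect_identical(predict(m1, td$x), predict(m2, td$x))
  # a fixed fitted model predicts row-wise: permuting rows permutes output
  perm <- sample(nrow(td$x))
  expect_equal(predict(m1, td$x[perm, ]), predict(m1, td$x)[perm])
  # duplicated rows get identical predictions
  dup <- td$x[c(1, 1, 2), ]
  expect_equal(predict(m1, dup)[1], predict(m1, dup)[2])
})

test_that("a separable step function is recovered out of bag", {
  set.seed(5)
  n <- 80
  x <- data.frame(x1 = rep(c(0, 1), each = n / 2),
                  z = rnorm(n))
  y <- ifelse(x$x1 > 0.5, 3, -2)
  m <- suppressWarnings(
    fit_forest(x, y, forest_config(ntree = 100, mtry = 1, seed = 9)))
  expect_gt(pct_var_explained(m), 90)
  expect_lt(mean(abs(m$oob_pred[x$x1 > 0.5] - 3)), 0.5)
  expect_lt(mean(abs(m$oob_pred[x$x1 < 0.5] + 2)), 0.5)
})

test_that("pure-noise predictors explain no variance on average", {
  pve <- vapply(1:10, function(s) {
    set.seed(s)
    x <- as.data.frame(matrix(rnorm(10 * 5), 10))
    y <- rnorm(10)
    pct_var_explained(fit_forest(x, y, forest_config(ntree = 1000, mtry = 2,
                                                     seed = s)))
  }, numeric(1))
  expect_lt(mean(pve), 0)
})

test_that("OOB error and variance explained follow their definitions", {
  mock <- structure(list(response = c(1, -1), oob_pred = c(0, 0),
                         sigma2 = 1), class = "forest_model")
  expect_equal(oob_mse(mock), 1)
  expect_equal(pct_var_explained(mock), 0)
  mock$oob_pred <- mock$response
  expect_equal(oob_mse(mock), 0)
  expect_equal(pct_var_explained(mock), 100)
  mock$oob_pred <- c(NaN, 0)
  expect_error(oob_mse(mock), "ntree")
})

test_that("fit preconditions are enforced", {
  td <- toy_design(2)
  expect_error(fit_forest(td$x, rep(1, nrow(td$x)), forest_config(seed = 1)),
               "constant")
  expect_error(fit_forest(td$x, td$y,
                          forest_config(ntree = 50, mtry = 99, seed = 1)),
               "mtry")
  xna <- td$x; xna[1, 1] <- NA
  expect_error(fit_forest(xna, td$y, forest_config(ntree = 50, mtry = 2,
                                                   seed = 1)), "missing")
})

test_that("permutation importance isolates informative predictors", {
  # informative x1 ranks first in nearly all seeds; independent noise ~ 0
  firsts <- 0
  null_pcts <- numeric(0)
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
    y <- 2 * sin(x$x1) + rnorm(n, 0, 0.2)
    m <- fit_forest(x, y, forest_config(ntree = 200, mtry = 2, seed = s))
    imp <- permutation_importance(m)
    firsts <- firsts + (imp$variable[1] == "x1")
    null_pcts <- c(null_pcts, imp$pct_inc_mse[imp$variable == "x3"])
  }
  expect_gte(firsts, 9)
  expect_lt(abs(mean(null_pcts)), 10)
})

test_that("permutation importance agrees with the ensemble engine's internal measure", {
  td <- toy_design(3, n = 80, noise_sd = 0.2)
  m <- fit_forest(td$x, td$y, forest_config(ntree = 300, mtry = 2, seed = 4))
  ours <- permutation_importance(m)
  theirs <- randomForest::importance(m$rf, scale = FALSE)[, "%IncMSE"]
  merged <- merge(ours, data.frame(variable = names(theirs),
                                   engine = unname(theirs)))
  expect_gt(cor(merged$raw_inc_mse, merged$engine), 0.95)
  expect_equal(ours$variable[1], names(which.max(theirs)))
})

test_that("mtry tuning respects boundaries and finds signal-appropriate values", {
  td <- toy_design(6, n = 50, p_noise = 0)
  m <- tune_mtry(td$x, td$y, forest_config(ntree = 200, mtry = NULL, seed = 2),
                 ntree = 200)
  expect_true(m %in% c(1, 2))
  # one informative predictor among 12: larger mtry usually preferred
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 70
    x <- as.data.frame(matrix(rnorm(n * 12), n))
    y <- 2 * x[[1]] + rnorm(n, 0, 0.2)
    m <- tune_mtry(x, y, forest_config(ntree = 200, mtry = NULL, seed = s),
                   ntree = 200)
    hits <- hits + (m >= 4)
  }
  expect_gte(hits, 3)
})

test_that("partial dependence tracks the generative relationship", {
  td <- toy_design(7, n = 80, beta = c(-2, 0), noise_sd = 0.1)
  m <- fit_forest(td$x, td$y, forest_config(ntree = 300, mtry = 2, seed = 3))
  pd <- partial_dependence(m, "x1")
  expect_lt(cor(pd$value, pd$yhat, method = "spearman"), -0.9)
  expect_error(partial_dependence(m, "nope"), "unknown")
  # a single tree with one leaf predicts the overall response mean, flatly
  m1 <- fit_forest(td$x, td$y,
                   forest_config(ntree = 1, mtry = 2,
                                 nodesize = nrow(td$x) + 10, seed = 8))
  pd1 <- partial_dependence(m1, "x1")
  expect_equal(diff(range(pd1$yhat)), 0)
  # near-single-leaf predictions stay inside the response range
  expect_true(pd1$yhat[1] >= min(td$y) && pd1$yhat[1] <= max(td$y))
})

test_that("prediction enforces the training schema and beats the mean baseline", {
  td <- toy_design(8, n = 100, noise_sd = 0.3)
  m <- fit_forest(td$x[1:70, ], td$y[1:70],
                  forest_config(ntree = 300, mtry = 2, seed = 5))
  expect_error(predict(m, td$x[, -1]), "x1")
  extra <- td$x; extra$bogus <- 1
  expect_error(predict(m, extra), "bogus")
  test_x <- td$x[71:100, ]; test_y <- td$y[71:100]
  rmse <- sqrt(mean((predict(m, test_x) - test_y)^2))
  rmse0 <- sqrt(mean((mean(td$y[1:70]) - test_y)^2))
  expect_lt(rmse, rmse0)
  expect_equal(predict(m, test_x, type = "response"),
               exp(predict(m, test_x)))
})

test_that("OOB error is an honest estimate of generalization error", {
  # paired OOB vs independent-test MSE over replicate draws of one
  # generative model: the mean difference is within 2 MC standard errors
  reps <- 200
  diffs <- vapply(seq_len(reps), function(s) {
    set.seed(s)
    n <- 40
    x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- x$x1 - 0.5 * x$x2 + rnorm(n, 0, 0.4)
    m <- fit_forest(x, y, forest_config(ntree = 120, mtry = 1, seed = s))
    xt <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    yt <- xt$x1 - 0.5 * xt$x2 + rnorm(n, 0, 0.4)
    oob_mse(m) - mean((predict(m, xt) - yt)^2)
  }, numeric(1))
  se <- sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs)), 2 * se + 1e-12)
})
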