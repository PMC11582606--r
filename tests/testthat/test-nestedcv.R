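# Inner tuning and nested leave-one-out cross-validation: determinism,
# oracle agreement, order invariance and leakage freedom.

toy_xy <- function(n = 8, seed = 10) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("s%02d", 1:n), c("f1", "f2")))
  y <- setNames(3 * X[, 1] + rnorm(n, sd = 0.5), rownames(X))
  list(X = X, y = y)
}

test_that("a one-point grid is returned as-is and tuning is deterministic", {
  d <- toy_xy(10)
  g1 <- hyper_grid(pearson_cutoff = 0.2, alpha = 1, lambda = 0.3, gamma = 0.5)
  t1 <- inner_tune(d$X, d$y, g1, folds = 5, repeats = 2, seed = 3)
  expect_equal(t1$best,
               list(pearson_cutoff = 0.2, alpha = 1, lambda = 0.3, gamma = 0.5))
  t2 <- inner_tune(d$X, d$y, g1, folds = 5, repeats = 2, seed = 3)
  expect_identical(t1, t2)
})

test_that("the generative grid point wins on noise-free data", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20),
                                                c("f1", "f2")))
  y <- setNames(2 * X[, 1], rownames(X))  # exact linear model, no noise
  g <- hyper_grid(pearson_cutoff = 0, alpha = 1, lambda = c(0, 50), gamma = 1)
  tuned <- inner_tune(X, y, g, folds = 5, repeats = 3, seed = 1)
  expect_equal(tuned$best$lambda, 0)  # unpenalized fit is exact here
  expect_error(inner_tune(X[1:3, ], y[1:3], g, folds = 5), "folds")
})

test_that("nested LOOCV is near-perfect on a noise-free cohort", {
  set.seed(12)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(sprintf("s%02d", 1:12),
                                                c("f1", "f2")))
  y <- setNames(5 + 3 * X[, 1], rownames(X))
  g <- hyper_grid(pearson_cutoff = 0.5, alpha = 1, lambda = 0.01, gamma = 0)
  cv <- nested_loocv(X, y, g, seed = 2, folds = 4, repeats = 1)
  expect_lt(cv$rmse, 1e-8)
  expect_equal(cv$r_squared, 1)
  expect_true(cv$r2_defined)
})

test_that("constant responses and undersized cohorts are rejected", {
  d <- toy_xy(8)
  g <- hyper_grid(pearson_cutoff = 0, alpha = 1, lambda = 0.1, gamma = 1)
  expect_error(nested_loocv(d$X, rep(4, 8), g), "degenerate")
  expect_error(nested_loocv(d$X[1:3, ], d$y[1:3], g), "at least 4")
})

test_that("intercept-only folds predict the fold-training mean; constant predictions flag r-squared", {
  d <- toy_xy(8, seed = 13)
  g <- hyper_grid(pearson_cutoff = 0, alpha = 1, lambda = 1e6, gamma = 1)
  cv <- nested_loocv(d$X, d$y, g, seed = 1, folds = 4, repeats = 1)
  # every fold collapses to the intercept: prediction for sample i is the
  # mean of the other n-1 responses
  loo_mean <- (sum(d$y) - d$y) / 7
  expect_equal(setNames(cv$predictions$predicted, cv$predictions$sample),
               loo_mean, tolerance = 1e-10)
  # an intercept-only model predicting a fresh cohort is exactly constant:
  # r-squared is undefined, reported as 0 with the flag down
  res <- fit_full_and_predict(d$X, d$y, g, d$X, d$y, seed = 1, repeats = 1)
  expect_false(res$r2_defined)
  expect_equal(res$r_squared, 0)
})

test_that("per-fold predictions match an independent re-run of the pipeline", {
  # with cutoff 0, lambda 0, gamma 0 the per-fold model is plain OLS, so each
  # held-out prediction can be recomputed with lm()
  d <- toy_xy(8, seed = 14)
  g <- hyper_grid(pearson_cutoff = 0, alpha = 1, lambda = 0, gamma = 0)
  cv <- nested_loocv(d$X, d$y, g, seed = 5, folds = 4, repeats = 1)
  for (i in seq_len(8)) {
    dd <- data.frame(y = d$y[-i], d$X[-i, ])
    m <- lm(y ~ f1 + f2, data = dd)
    pred <- predict(m, newdata = as.data.frame(d$X)[i, ])
    expect_equal(cv$predictions$predicted[cv$predictions$sample ==
                                            rownames(d$X)[i]],
                 unname(pred), tolerance = 1e-8)
  }
})

test_that("results are invariant to sample and feature order", {
  d <- toy_xy(10, seed = 15)
  g <- hyper_grid(pearson_cutoff = c(0, 0.4), alpha = c(0.5, 1),
                  lambda = c(0.01, 0.5), gamma = c(0, 1))
  cv1 <- nested_loocv(d$X, d$y, g, seed = 9, folds = 5, repeats = 2)
  sp <- sample(10); fp <- 2:1
  cv2 <- nested_loocv(d$X[sp, fp], d$y[sp], g, seed = 9, folds = 5, repeats = 2)
  expect_identical(cv1$rmse, cv2$rmse)
  m1 <- cv1$predictions[order(cv1$predictions$sample), ]
  m2 <- cv2$predictions[order(cv2$predictions$sample), ]
  expect_identical(m1$predicted, m2$predicted)
})

test_that("perturbing a held-out sample never changes that fold's trained model", {
  d <- toy_xy(8, seed = 16)
  g <- hyper_grid(pearson_cutoff = c(0, 0.4), alpha = 1,
                  lambda = c(0.05, 0.5), gamma = c(0, 1))
  base <- nested_loocv(d$X, d$y, g, seed = 4, folds = 4, repeats = 2)
  strip <- function(a) a[c("best", "selected", "support", "intercept",
                           "coefficients")]
  for (i in seq_len(8)) {
    y2 <- d$y
    y2[i] <- y2[i] + 500  # sentinel on the held-out response
    pert <- nested_loocv(d$X, y2, g, seed = 4, folds = 4, repeats = 2)
    id <- rownames(d$X)[i]
    expect_identical(hash_object(strip(base$artifacts[[id]])),
                     hash_object(strip(pert$artifacts[[id]])))
  }
})

test_that("full-cohort fit predicts a verification cohort with frozen rules", {
  set.seed(17)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("t%02d", 1:20),
                                                c("f1", "f2", "f3")))
  y <- setNames(2 * X[, 1] - X[, 2], rownames(X))
  g <- hyper_grid(pearson_cutoff = 0, alpha = 1, lambda = 0.01, gamma = 0)
  # verify == train: resubstitution
  res <- fit_full_and_predict(X, y, g, X, y, seed = 1, repeats = 1)
  expect_lt(res$rmse, 1e-6)
  # noise-free generative verification set
  Xv <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("v%02d", 1:10),
                                                 colnames(X)))
  yv <- 2 * Xv[, 1] - Xv[, 2]
  res2 <- fit_full_and_predict(X, y, g, Xv, yv, seed = 1, repeats = 1)
  expect_lt(res2$rmse, 1e-6)
  expect_equal(res2$r_squared, 1)
  # schema mismatch and empty verification sets are errors
  expect_error(fit_full_and_predict(X, y, g, Xv[, 1:2], yv, repeats = 1),
               "schema")
  expect_error(fit_full_and_predict(X, y, g, Xv[0, ], numeric(0), repeats = 1),
               "empty")
})
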