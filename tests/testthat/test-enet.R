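# The penalized and relaxed elastic-net fitter against closed-form and
# independent-package oracles.

test_that("the penalty vanishes at lambda = 0 (OLS agreement)", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(20, sd = 0.2)
  ols <- unname(coef(lm(y ~ X)))
  for (a in c(0, 0.5, 1)) {
    f <- fit_elastic_net(X, y, alpha = a, lambda = 0)
    expect_lt(max(abs(unname(coef(f)) - ols)), 1e-8)
  }
})

test_that("a huge penalty shrinks every slope to zero", {
  set.seed(2)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, letters[1:5]))
  y <- rnorm(10, mean = 4)
  f <- fit_elastic_net(X, y, alpha = 1, lambda = 1e6)
  expect_true(all(f$coefficients == 0))
  expect_equal(f$intercept, mean(y))
  expect_length(f$support, 0)
})

test_that("lasso on an orthonormal design equals soft-thresholding", {
  X <- orthonormal_design(24, 5, seed = 3)
  set.seed(4)
  y <- rnorm(24, sd = 2)
  bols <- drop(crossprod(X, y - mean(y)) / 24)
  for (lam in c(0.05, 0.2, 0.8)) {
    f <- fit_elastic_net(X, y, alpha = 1, lambda = lam)
    expect_lt(max(abs(f$coefficients - oracle_soft_threshold(bols, lam))), 1e-6)
  }
})

test_that("ridge matches its closed form", {
  set.seed(5)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- drop(X %*% c(1, -2, 0)) + rnorm(30)
  st <- primava:::standardize_design(X)
  for (lam in c(0.1, 1)) {
    b_std <- solve(crossprod(st$Xs) / 30 + lam * diag(3),
                   crossprod(st$Xs, y - mean(y)) / 30)
    f <- fit_elastic_net(X, y, alpha = 0, lambda = lam)
    expect_lt(max(abs(f$coefficients * st$xs - drop(b_std))), 1e-7)
  }
})

test_that("solutions satisfy the elastic-net KKT conditions", {
  set.seed(6)
  for (i in 1:6) {
    n <- sample(15:40, 1); p <- sample(3:12, 1)
    a <- runif(1); lam <- runif(1, 0.01, 0.5)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("x%d", 1:p)))
    y <- drop(X %*% rnorm(p, sd = 0.5)) + rnorm(n)
    f <- fit_elastic_net(X, y, a, lam)
    st <- primava:::standardize_design(X)
    b <- f$coefficients * st$xs
    grad <- drop(crossprod(st$Xs, (y - mean(y)) - st$Xs %*% b)) / n
    act <- b != 0
    if (any(act))
      expect_lt(max(abs(grad[act] - lam * a * sign(b[act]) -
                          lam * (1 - a) * b[act])), 1e-6)
    if (any(!act))
      expect_lte(max(abs(grad[!act])), lam * a + 1e-6)
  }
})

test_that("the lasso path agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  X <- matrix(rnorm(35 * 12), 35, 12, dimnames = list(NULL, sprintf("g%d", 1:12)))
  y <- drop(X %*% c(3, -2, rep(0, 10))) + rnorm(35)
  lams <- lambda_max(X, y, 1) * c(0.6, 0.2, 0.05)
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lams, thresh = 1e-12)
  for (l in lams) {
    f <- fit_elastic_net(X, y, 1, l)
    gb <- as.numeric(glmnet::coef.glmnet(g, s = l, exact = TRUE, x = X, y = y))
    expect_lt(max(abs(unname(coef(f)) - gb)), 1e-4)
  }
})

test_that("relaxation blends penalized and support-OLS coefficients", {
  set.seed(8)
  X <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, sprintf("x%d", 1:6)))
  y <- 2 * X[, 1] + X[, 3] + rnorm(25, sd = 0.3)
  pen <- fit_elastic_net(X, y, 1, 0.15)
  expect_gt(length(pen$support), 0)
  # gamma = 0: exactly the unpenalized refit on the support
  r0 <- relax_fit(pen, X, y, gamma = 0)
  ols <- coef(lm(y ~ X[, pen$support]))
  expect_equal(unname(r0$intercept), unname(ols[1]))
  expect_equal(unname(r0$coefficients[pen$support]), unname(ols[-1]))
  expect_true(all(r0$coefficients[setdiff(colnames(X), pen$support)] == 0))
  # gamma = 1: identical to the penalized fit
  r1 <- relax_fit(pen, X, y, gamma = 1)
  expect_identical(r1$coefficients, pen$coefficients)
  # mid blend is the exact convex combination
  r5 <- relax_fit(pen, X, y, gamma = 0.4)
  expect_equal(r5$coefficients,
               0.4 * pen$coefficients + 0.6 * r0$coefficients)
  # empty support: intercept-only, prediction = mean(y)
  big <- fit_elastic_net(X, y, 1, 1e5)
  re <- relax_fit(big, X, y, gamma = 0)
  expect_equal(unname(predict(re, X))[1], mean(y))
})

test_that("relaxation falls back to penalized coefficients on a singular refit", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10), c = rnorm(5))
  y <- c(1, 3, 2, 5, 4)
  pen <- fit_elastic_net(X, y, 0.5, 1e-4)
  if (all(c("a", "b") %in% pen$support)) {
    expect_warning(r <- relax_fit(pen, X, y, gamma = 0), "singular")
    expect_identical(r$coefficients, pen$coefficients)
  }
})

test_that("parameter validation rejects out-of-range hyperparameters", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(fit_elastic_net(X, y, alpha = 1.5, lambda = 0.1), "alpha")
  expect_error(fit_elastic_net(X, y, alpha = 1, lambda = -1), "lambda")
  expect_error(fit_elastic_net(X[1, , drop = FALSE], y[1], 1, 0.1), "2 samples")
  f <- fit_elastic_net(X, y, 1, 0.1)
  expect_error(relax_fit(f, X, y, gamma = 2), "gamma")
})

test_that("the Pearson filter selects by absolute correlation", {
  set.seed(9)
  X <- cbind(x1 = 1:10, x2 = rnorm(10), x3 = rnorm(10), const = rep(2, 10))
  y <- 2 * X[, "x1"]
  expect_equal(as.character(pearson_filter(X, y, 0.95)), "x1")
  expect_setequal(as.character(pearson_filter(X, y, 0)), c("x1", "x2", "x3"))
  # hand-computed correlations on a 4-sample matrix
  Xs <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  ys <- c(0, 1, 1, 2)
  r_hand <- function(x) {
    sum((x - mean(x)) * (ys - mean(ys))) /
      sqrt(sum((x - mean(x))^2) * sum((ys - mean(ys))^2))
  }
  sel <- pearson_filter(Xs, ys, 0.7)
  expect_identical(as.character(sel),
                   colnames(Xs)[abs(c(r_hand(Xs[, 1]), r_hand(Xs[, 2]))) >= 0.7])
  expect_length(pearson_filter(X, rnorm(10), 0.9999), 0)
  expect_error(pearson_filter(X, y, 1.2), "cutoff")
})
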