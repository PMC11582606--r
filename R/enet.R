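# Relaxed elastic net. The penalized fit minimizes
#   (1/2n) * sum((y - b0 - X b)^2) + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)
# by coordinate descent on internally standardized predictors (population sd,
# zero-variance columns dropped to zero coefficients); coefficients are
# reported on the original scale. The relaxation refits unpenalized least
# squares on the selected support and blends with the penalized coefficients
# by the debiasing factor gamma (gamma = 1: pure penalized; gamma = 0: pure
# refit).

CD_TOL <- 1e-7
CD_MAX_SWEEPS <- 100000L

standardize_design <- function(X) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  keep <- which(xs > 0)
  Xs <- sweep(X[, keep, drop = FALSE], 2, xm[keep], "-")
  Xs <- sweep(Xs, 2, xs[keep], "/")
  list(Xs = Xs, xm = xm, xs = xs, keep = keep)
}

#' Largest penalty with any active coefficient
#'
#' `lambda_max = max_j |x_j' y_c| / (n * max(alpha, 0.001))` on the
#' standardized design; the usual start of a regularization path.
#'
#' @param X design matrix (samples x features)
#' @param y response
#' @param alpha elastic-net mixing
#' @return the scalar lambda_max
#' @export
lambda_max <- function(X, y, alpha = 1) {
  st <- standardize_design(X)
  if (length(st$keep) == 0L) return(0)
  yc <- y - mean(y)
  max(abs(crossprod(st$Xs, yc))) / (nrow(st$Xs) * max(alpha, 1e-3))
}

lambda_sequence <- function(lmax, nlambda = 50L, min_ratio = 1e-4) {
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

# Coefficient path on the original scale for a decreasing lambda sequence.
# Returns p x L original-scale betas, intercepts, and the standardized betas
# (used for support detection; supports coincide since scales are positive).
enet_path <- function(X, y, alpha, lambdas, tol = CD_TOL,
                      max_sweeps = CD_MAX_SWEEPS) {
  st <- standardize_design(X)
  p <- ncol(X)
  ym <- mean(y)
  if (length(st$keep) == 0L) {
    L <- length(lambdas)
    return(list(beta = matrix(0, p, L, dimnames = list(colnames(X), NULL)),
                intercept = rep(ym, L), beta_std = matrix(0, 0, L)))
  }
  fit <- cd_enet_path(st$Xs, y - ym, alpha, lambdas, tol, max_sweeps)
  beta <- matrix(0, p, length(lambdas), dimnames = list(colnames(X), NULL))
  beta[st$keep, ] <- fit$beta / st$xs[st$keep]
  intercept <- ym - drop(crossprod(beta, st$xm))
  list(beta = beta, intercept = intercept, beta_std = fit$beta)
}

#' Fit a penalized elastic-net regression
#'
#' Deterministic coordinate-descent fit at a single penalty. At `lambda = 0`
#' on a full-column-rank design the solution is computed exactly by least
#' squares (the penalty vanishes). Zero-coefficient features are retained as
#' explicit zeros.
#'
#' @param X samples x features numeric matrix (named columns)
#' @param y numeric response, length `nrow(X)` (>= 2)
#' @param alpha elastic-net mixing in \[0, 1\] (1 = lasso, 0 = ridge)
#' @param lambda penalty strength (>= 0)
#' @return an object of class `enet_fit` with elements `intercept`,
#'   `coefficients` (named, zeros retained), `support`, `hyperparameters`
#' @export
fit_elastic_net <- function(X, y, alpha, lambda) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_input("X and y are not sample-aligned")
  if (nrow(X) < 2L) stop_input("need at least 2 samples")
  if (alpha < 0 || alpha > 1) stop_input("alpha must lie in [0, 1]")
  if (lambda < 0) stop_input("lambda must be >= 0")
  nm <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  if (ncol(X) > 0) colnames(X) <- nm
  if (lambda == 0 && ncol(X) > 0 && qr(cbind(1, X))$rank == ncol(X) + 1L) {
    ls <- lm.fit(cbind(`(Intercept)` = 1, X), y)
    beta <- ls$coefficients[-1]
    b0 <- ls$coefficients[1]
  } else {
    path <- enet_path(X, y, alpha, lambda)
    beta <- setNames(drop(path$beta), nm)
    b0 <- path$intercept[1]
  }
  structure(
    list(intercept = unname(b0), coefficients = beta,
         support = nm[beta != 0],
         hyperparameters = list(alpha = alpha, lambda = lambda, gamma = 1)),
    class = "enet_fit"
  )
}

# Unpenalized least squares restricted to a support; NULL if singular.
ols_on_support <- function(X, y, support) {
  if (length(support) == 0L)
    return(list(intercept = mean(y),
                coefficients = setNames(numeric(ncol(X)), colnames(X))))
  fit <- lm.fit(cbind(`(Intercept)` = 1, X[, support, drop = FALSE]), y)
  cf <- fit$coefficients
  if (anyNA(cf)) return(NULL)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[support] <- cf[-1]
  list(intercept = unname(cf[1]), coefficients = beta)
}

#' Relax a penalized fit (debiasing refit on the support)
#'
#' Refits unpenalized least squares on the features the penalized fit
#' selected, then blends: `gamma * beta_penalized + (1 - gamma) * beta_relaxed`
#' (intercepts blended likewise). An empty support yields the intercept-only
#' model. A singular refit falls back to the penalized coefficients with a
#' warning.
#'
#' @param fit an `enet_fit` from [fit_elastic_net()] on the same data
#' @param X,y the data the fit was produced on
#' @param gamma relaxation blend in \[0, 1\]; 0 = pure unpenalized refit
#' @return an object of class `c("relaxnet", "enet_fit")`
#' @export
relax_fit <- function(fit, X, y, gamma) {
  if (!inherits(fit, "enet_fit")) stop_input("fit must come from fit_elastic_net")
  if (gamma < 0 || gamma > 1) stop_input("gamma must lie in [0, 1]")
  X <- as.matrix(X)
  ols <- ols_on_support(X, y, fit$support)
  if (is.null(ols)) {
    warning("singular refit on support; falling back to penalized coefficients")
    ols <- list(intercept = fit$intercept, coefficients = fit$coefficients)
  }
  beta <- gamma * fit$coefficients + (1 - gamma) * ols$coefficients
  structure(
    list(intercept = gamma * fit$intercept + (1 - gamma) * ols$intercept,
         coefficients = beta, support = fit$support,
         penalized = fit$coefficients, relaxed = ols$coefficients,
         hyperparameters = utils::modifyList(fit$hyperparameters,
                                             list(gamma = gamma))),
    class = c("relaxnet", "enet_fit")
  )
}

#' Relaxed elastic net in one call
#'
#' Convenience wrapper: [fit_elastic_net()] followed by [relax_fit()].
#'
#' @inheritParams fit_elastic_net
#' @param gamma relaxation blend in \[0, 1\]
#' @return a `relaxnet` object
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- 2 * X[, 1] + rnorm(20, sd = 0.1)
#' fit <- relaxnet(X, y, alpha = 1, lambda = 0.05, gamma = 0)
#' coef(fit)
#' @export
relaxnet <- function(X, y, alpha = 1, lambda = 0, gamma = 1) {
  fit <- fit_elastic_net(X, y, alpha, lambda)
  relax_fit(fit, X, y, gamma)
}

#' @export
print.enet_fit <- function(x, ...) {
  h <- x$hyperparameters
  cat(if (inherits(x, "relaxnet")) "Relaxed elastic net" else "Elastic net",
      sprintf("(alpha = %g, lambda = %g, gamma = %g)\n", h$alpha, h$lambda, h$gamma))
  cat("  support:", if (length(x$support)) paste(x$support, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' @export
coef.enet_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.enet_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  nm <- names(object$coefficients)
  if (!is.null(colnames(newdata))) {
    if (!all(nm %in% colnames(newdata)))
      stop_input("newdata lacks features: ",
                 paste(setdiff(nm, colnames(newdata)), collapse = ", "))
    newdata <- newdata[, nm, drop = FALSE]
  } else if (ncol(newdata) != length(nm)) {
    stop_input("newdata has the wrong number of columns")
  }
  drop(object$intercept + newdata %*% object$coefficients)
}

#' @export
residuals.enet_fit <- function(object, X, y, ...) {
  y - predict(object, X)
}

#' @export
summary.enet_fit <- function(object, ...) {
  cf <- coef(object)
  out <- list(hyperparameters = object$hyperparameters,
              n_selected = length(object$support),
              coefficients = cf[cf != 0])
  class(out) <- "summary.enet_fit"
  out
}

#' @export
print.summary.enet_fit <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf("alpha = %g, lambda = %g, gamma = %g; %d feature(s) selected\n",
              h$alpha, h$lambda, h$gamma, x$n_selected))
  print(x$coefficients)
  invisible(x)
}

#' Pearson correlation filter
#'
#' Keeps features whose absolute Pearson correlation with the response is at
#' least `cutoff`. Zero-variance features are excluded before correlation. An
#' empty selection is returned as `character(0)`; callers fall back to the
#' intercept-only model.
#'
#' @param X samples x features matrix
#' @param y response, sample-aligned with `X`
#' @param cutoff absolute-correlation threshold in \[0, 1\]
#' @return selected feature names, with correlations in attribute `"r"`
#' @export
pearson_filter <- function(X, y, cutoff) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_input("X and y are not sample-aligned")
  if (cutoff < 0 || cutoff > 1) stop_input("cutoff must lie in [0, 1]")
  xs <- sqrt(colMeans(X^2) - colMeans(X)^2)
  ok <- xs > 0 & sd(y) > 0
  r <- rep(NA_real_, ncol(X))
  if (any(ok)) r[ok] <- drop(cor(X[, ok, drop = FALSE], y))
  sel <- which(!is.na(r) & abs(r) >= cutoff)
  structure(colnames(X)[sel], r = r[sel])
}
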