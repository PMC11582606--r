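# Nested cross-validation for the Pearson-filter -> relaxed elastic-net
# pipeline. The outer loop is leave-one-out; the inner loop tunes the four
# hyperparameters (Pearson cutoff, alpha, lambda, gamma) by repeated k-fold CV
# on the n-1 training samples only, so the held-out sample never touches any
# inner computation (no leakage). Fold assignment and all seeds are keyed by
# sample id, not position, making results invariant to sample and feature
# order.

#' Hyperparameter grid for the relaxed elastic net
#'
#' Defaults: Pearson cutoff \{0, 0.2, 0.4, 0.6\}; alpha \{0, 0.25, 0.5, 0.75,
#' 1\}; lambda on a 50-point log grid from `lambda_max` of the tuning data down
#' to `lambda_max * 1e-4` (per alpha); gamma \{0, 0.25, 0.5, 0.75, 1\}.
#'
#' @param pearson_cutoff absolute-correlation thresholds
#' @param alpha elastic-net mixing values
#' @param lambda explicit penalty values, or `NULL` to derive a log grid from
#'   the data
#' @param gamma relaxation blends
#' @param nlambda,lambda_min_ratio log-grid shape when `lambda` is `NULL`; the
#'   default ratio (`NULL`) resolves to 1e-4 when the tuning data have more
#'   samples than features and 1e-2 otherwise (the usual convention for
#'   high-dimensional fits, where tiny penalties are both slow and useless)
#' @return an object of class `hyper_grid`
#' @export
hyper_grid <- function(pearson_cutoff = c(0, 0.2, 0.4, 0.6),
                       alpha = c(0, 0.25, 0.5, 0.75, 1),
                       lambda = NULL,
                       gamma = c(0, 0.25, 0.5, 0.75, 1),
                       nlambda = 50L, lambda_min_ratio = NULL) {
  if (length(pearson_cutoff) == 0L || length(alpha) == 0L || length(gamma) == 0L)
    stop_input("hyperparameter grid must be non-empty")
  if (any(alpha < 0 | alpha > 1) || any(gamma < 0 | gamma > 1) ||
      any(pearson_cutoff < 0 | pearson_cutoff > 1))
    stop_input("alpha, gamma and pearson_cutoff must lie in [0, 1]")
  if (!is.null(lambda) && any(lambda < 0)) stop_input("lambda must be >= 0")
  if (!is.null(lambda_min_ratio) &&
      (lambda_min_ratio <= 0 || lambda_min_ratio >= 1))
    stop_input("lambda_min_ratio must lie in (0, 1)")
  structure(list(pearson_cutoff = sort(pearson_cutoff), alpha = sort(alpha),
                 lambda = if (is.null(lambda)) NULL else sort(lambda, decreasing = TRUE),
                 gamma = sort(gamma), nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "hyper_grid")
}

# Deterministic, sample-id-keyed fold assignment (balanced round-robin over a
# hash-ordered permutation).
assign_folds <- function(ids, folds, rep, seed) {
  u <- vapply(ids, function(id) derive_seed(seed, "fold", rep, id), integer(1))
  f <- integer(length(ids))
  f[order(u, ids)] <- rep_len(seq_len(folds), length(ids))
  f
}

canonicalize <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%04d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  y <- setNames(as.numeric(y), rownames(X))
  ro <- order(rownames(X))
  co <- order(colnames(X))
  prov <- provenance(X)[co]
  X <- X[ro, co, drop = FALSE]
  attr(X, "provenance") <- prov
  list(X = X, y = y[ro])
}

# Validation predictions for every grid point on one train/validation split.
# Returns SSE array [cutoff, alpha, lambda, gamma] over the validation set.
eval_fold_sse <- function(Xtr, ytr, Xval, yval, grid, lambda_list) {
  nc <- length(grid$pearson_cutoff); na <- length(grid$alpha)
  nl <- length(lambda_list[[1]]); ng <- length(grid$gamma)
  sse <- array(0, dim = c(nc, na, nl, ng))
  for (ci in seq_len(nc)) {
    sel <- pearson_filter(Xtr, ytr, grid$pearson_cutoff[ci])
    for (ai in seq_len(na)) {
      lam <- lambda_list[[ai]]
      if (length(sel) == 0L) {
        err2 <- sum((yval - mean(ytr))^2)
        sse[ci, ai, , ] <- err2
        next
      }
      Xs <- Xtr[, sel, drop = FALSE]
      path <- enet_path(Xs, ytr, grid$alpha[ai], lam)
      Xv <- Xval[, sel, drop = FALSE]
      pred_pen <- sweep(Xv %*% path$beta, 2, path$intercept, "+")
      # relaxed coefficients per lambda, caching the OLS refit per support
      beta_rel <- path$beta
      int_rel <- path$intercept
      cache <- new.env(parent = emptyenv())
      for (l in seq_along(lam)) {
        supp <- sel[path$beta[, l] != 0]
        key <- paste0("s:", paste(supp, collapse = "\r"))
        hit <- cache[[key]]
        if (is.null(hit)) {
          hit <- ols_on_support(Xs, ytr, supp)
          if (is.null(hit))  # singular refit: fall back to penalized
            hit <- list(intercept = path$intercept[l],
                        coefficients = path$beta[, l])
          cache[[key]] <- hit
        }
        beta_rel[, l] <- hit$coefficients
        int_rel[l] <- hit$intercept
      }
      pred_rel <- sweep(Xv %*% beta_rel, 2, int_rel, "+")
      for (gi in seq_len(ng)) {
        g <- grid$gamma[gi]
        pred <- g * pred_pen + (1 - g) * pred_rel
        sse[ci, ai, , gi] <- colSums((yval - pred)^2)
      }
    }
  }
  sse
}

#' Tune hyperparameters by repeated k-fold cross-validation
#'
#' For every grid point the mean validation RMSE over `repeats` x `folds`
#' splits is computed; the argmin is returned, with ties broken toward larger
#' lambda, then larger gamma, then larger Pearson cutoff, then larger alpha
#' (parsimony). Fold assignments are seeded per (repeat, sample id).
#'
#' @param X samples x features matrix (row names are sample ids)
#' @param y response
#' @param grid a [hyper_grid()]
#' @param folds inner folds (default 5); requires `nrow(X) >= folds`
#' @param repeats inner repeats (default 20)
#' @param seed integer seed for the fold assignments
#' @return a list with `best` (the tuned hyperparameters), `cv_rmse` (the full
#'   grid with mean validation RMSE) and the tuning settings
#' @export
inner_tune <- function(X, y, grid = hyper_grid(), folds = 5L, repeats = 20L,
                       seed = 1L) {
  if (!inherits(grid, "hyper_grid")) stop_input("grid must be a hyper_grid")
  cc <- canonicalize(X, y)
  X <- cc$X; y <- cc$y
  n <- nrow(X)
  if (n < folds) stop_input("need at least as many samples as folds")
  min_ratio <- grid$lambda_min_ratio %||% (if (nrow(X) > ncol(X)) 1e-4 else 1e-2)
  lambda_list <- lapply(grid$alpha, function(a) {
    grid$lambda %||%
      lambda_sequence(lambda_max(X, y, a), grid$nlambda, min_ratio)
  })
  nl <- length(lambda_list[[1]])
  sse <- array(0, dim = c(length(grid$pearson_cutoff), length(grid$alpha),
                          nl, length(grid$gamma)))
  nval_total <- 0L
  ids <- rownames(X)
  for (rep_i in seq_len(repeats)) {
    fold_of <- assign_folds(ids, folds, rep_i, seed)
    for (f in seq_len(folds)) {
      val <- fold_of == f
      sse <- sse + eval_fold_sse(X[!val, , drop = FALSE], y[!val],
                                 X[val, , drop = FALSE], y[val],
                                 grid, lambda_list)
      nval_total <- nval_total + sum(val)
    }
  }
  rmse <- sqrt(sse / nval_total)
  # tie-break: larger lambda, then gamma, then cutoff, then alpha
  idx <- which(rmse <= min(rmse) + 1e-12, arr.ind = TRUE)
  lam_at <- function(r) lambda_list[[r[2]]][r[3]]
  score <- cbind(vapply(seq_len(nrow(idx)), function(i) lam_at(idx[i, ]), 0),
                 grid$gamma[idx[, 4]], grid$pearson_cutoff[idx[, 1]],
                 grid$alpha[idx[, 2]])
  pick <- idx[order(-score[, 1], -score[, 2], -score[, 3], -score[, 4])[1], ]
  best <- list(pearson_cutoff = grid$pearson_cutoff[pick[1]],
               alpha = grid$alpha[pick[2]],
               lambda = lambda_list[[pick[2]]][pick[3]],
               gamma = grid$gamma[pick[4]])
  cv <- expand.grid(pearson_cutoff = grid$pearson_cutoff, alpha = grid$alpha,
                    lambda_index = seq_len(nl), gamma = grid$gamma,
                    KEEP.OUT.ATTRS = FALSE)
  cv$lambda <- vapply(seq_len(nrow(cv)), function(i)
    lambda_list[[match(cv$alpha[i], grid$alpha)]][cv$lambda_index[i]], 0)
  cv$rmse <- as.vector(rmse)
  list(best = best, cv_rmse = cv, folds = folds, repeats = repeats, seed = seed)
}

# Fit the full pipeline (filter -> penalized -> relax) at fixed hyperparameters.
fit_pipeline <- function(X, y, hp) {
  sel <- pearson_filter(X, y, hp$pearson_cutoff)
  fit <- fit_elastic_net(X[, sel, drop = FALSE], y, hp$alpha, hp$lambda)
  rfit <- relax_fit(fit, X[, sel, drop = FALSE], y, hp$gamma)
  list(fit = rfit, selected = as.character(sel))
}

predict_pipeline <- function(pl, newdata) {
  if (length(pl$selected) == 0L)
    return(rep(pl$fit$intercept, nrow(newdata)))
  predict(pl$fit, newdata[, pl$selected, drop = FALSE])
}

#' Nested leave-one-out cross-validation of the relaxed elastic net
#'
#' For each sample, hyperparameters are tuned by [inner_tune()] on the other
#' n - 1 samples, the Pearson-filter -> elastic-net -> relaxation pipeline is
#' fitted on those n - 1 samples, and the held-out sample is predicted. The
#' held-out sample enters no inner computation (feature filtering,
#' standardization, tuning), so outer-fold artifacts are leakage-free by
#' construction. Aggregate accuracy is `RMSE = sqrt(mean((pred - obs)^2))` and
#' `r_squared`, the squared Pearson correlation between held-out predictions
#' and observations (the coefficient of determination is also reported as
#' `r2_cod`). When the predictions are constant, r-squared is undefined and
#' reported as 0 with `r2_defined = FALSE`.
#'
#' @param X samples x features matrix with sample ids as row names
#' @param y response (percent cell death), aligned with `X`
#' @param grid a [hyper_grid()]
#' @param seed integer seed; per-fold inner seeds are derived from it and the
#'   held-out sample id
#' @param folds,repeats inner-loop CV shape (default 5-fold, 20 repeats)
#' @return an object of class `nested_cv`: per-fold predictions and tuned
#'   hyperparameters, aggregate `rmse`, `r_squared`, `r2_cod`, and per-fold
#'   `artifacts` (tuned hyperparameters, selection, coefficients)
#' @export
nested_loocv <- function(X, y, grid = hyper_grid(), seed = 1L,
                         folds = 5L, repeats = 20L) {
  orig_ids <- rownames(as.matrix(X)) %||% sprintf("S%04d", seq_len(nrow(X)))
  cc <- canonicalize(X, y)
  X <- cc$X; y <- cc$y
  n <- nrow(X)
  if (n < 4L) stop_input("need at least 4 samples for nested LOOCV")
  if (sd(y) == 0) stop_input("degenerate response: y is constant")
  ids <- rownames(X)
  fold_out <- lapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    tuned <- inner_tune(Xtr, ytr, grid, folds, repeats,
                        seed = derive_seed(seed, "outer", ids[i]))
    pl <- fit_pipeline(Xtr, ytr, tuned$best)
    pred <- predict_pipeline(pl, X[i, , drop = FALSE])
    list(sample = ids[i], best = tuned$best, prediction = unname(pred),
         selected = pl$selected, support = pl$fit$support,
         intercept = pl$fit$intercept, coefficients = pl$fit$coefficients)
  })
  names(fold_out) <- ids
  pred <- vapply(fold_out, `[[`, numeric(1), "prediction")
  preds <- data.frame(
    sample = ids, observed = unname(y), predicted = unname(pred),
    pearson_cutoff = vapply(fold_out, function(f) f$best$pearson_cutoff, 0),
    alpha = vapply(fold_out, function(f) f$best$alpha, 0),
    lambda = vapply(fold_out, function(f) f$best$lambda, 0),
    gamma = vapply(fold_out, function(f) f$best$gamma, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  preds <- preds[match(orig_ids, preds$sample), , drop = FALSE]
  rownames(preds) <- NULL
  rmse <- sqrt(mean((preds$predicted - preds$observed)^2))
  r2_defined <- sd(preds$predicted) > 0
  r2 <- if (r2_defined) cor(preds$predicted, preds$observed)^2 else 0
  r2_cod <- 1 - sum((preds$observed - preds$predicted)^2) /
    sum((preds$observed - mean(preds$observed))^2)
  structure(
    list(predictions = preds, rmse = rmse, r_squared = r2,
         r2_defined = r2_defined, r2_cod = r2_cod,
         inner = list(folds = folds, repeats = repeats, grid = grid),
         seed = seed, artifacts = fold_out),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf(
    "Nested LOOCV (%d outer folds; inner %d-fold x %d repeats)\n",
    nrow(x$predictions), x$inner$folds, x$inner$repeats))
  cat(sprintf("  RMSE = %.4g, r-squared (Pearson^2) = %.4g%s\n",
              x$rmse, x$r_squared,
              if (x$r2_defined) "" else " [undefined: constant predictions]"))
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  hp <- object$predictions[, c("pearson_cutoff", "alpha", "lambda", "gamma")]
  out <- list(rmse = object$rmse, r_squared = object$r_squared,
              r2_cod = object$r2_cod, r2_defined = object$r2_defined,
              n = nrow(object$predictions),
              hyperparameter_summary = summary(hp))
  class(out) <- "summary.nested_cv"
  out
}

#' @export
print.summary.nested_cv <- function(x, ...) {
  cat(sprintf("Nested LOOCV over %d samples\n", x$n))
  cat(sprintf("  RMSE = %.4g\n  r-squared (Pearson^2) = %.4g\n  r2 (1 - SSres/SStot) = %.4g\n",
              x$rmse, x$r_squared, x$r2_cod))
  cat("Tuned hyperparameters across outer folds:\n")
  print(x$hyperparameter_summary)
  invisible(x)
}

#' @export
plot.nested_cv <- function(x, ...) {
  p <- x$predictions
  graphics::plot(p$observed, p$predicted,
                 xlab = "observed % cell death",
                 ylab = "held-out prediction", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Fit on a full training cohort and predict a verification cohort
#'
#' Hyperparameters are tuned on the training cohort with the same inner
#' algorithm, the pipeline is fitted on the whole training cohort, and the
#' verification samples are predicted. Verification features must be built
#' with the same construction rules (same feature names); cohort-level
#' statistics such as the MGMT expression median or the response mean must be
#' frozen from training upstream of this call.
#'
#' @param train_X,train_y training cohort
#' @param verify_X,verify_y verification cohort (same feature names)
#' @param grid a [hyper_grid()]
#' @param seed,folds,repeats inner-tuning settings
#' @return list with `predictions`, `rmse`, `r_squared`, `r2_cod`, the tuned
#'   `best` hyperparameters and the fitted `relaxnet`
#' @export
fit_full_and_predict <- function(train_X, train_y, grid, verify_X, verify_y,
                                 seed = 1L, folds = 5L, repeats = 20L) {
  train_X <- as.matrix(train_X); verify_X <- as.matrix(verify_X)
  if (nrow(verify_X) == 0L) stop_input("verification cohort is empty")
  if (!setequal(colnames(train_X), colnames(verify_X)))
    stop_input("feature schema mismatch between training and verification cohorts")
  verify_X <- verify_X[, colnames(train_X), drop = FALSE]
  tuned <- inner_tune(train_X, train_y, grid, folds, repeats, seed)
  cc <- canonicalize(train_X, train_y)
  pl <- fit_pipeline(cc$X, cc$y, tuned$best)
  pred <- predict_pipeline(pl, verify_X)
  rmse <- sqrt(mean((pred - verify_y)^2))
  r2_defined <- sd(pred) > 0 && sd(verify_y) > 0
  list(
    predictions = data.frame(sample = rownames(verify_X) %||% seq_along(pred),
                             observed = verify_y, predicted = unname(pred)),
    rmse = rmse,
    r_squared = if (r2_defined) cor(pred, verify_y)^2 else 0,
    r2_defined = r2_defined,
    r2_cod = 1 - sum((verify_y - pred)^2) / sum((verify_y - mean(verify_y))^2),
    best = tuned$best, fit = pl$fit
  )
}
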