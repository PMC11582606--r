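# Independent oracles used across tests. These deliberately avoid the package's
# own computational paths.

# Hill release, written directly from the functional form.
oracle_hill <- function(conc, ec50, hill, max_release = 100) {
  ifelse(conc > 0, max_release * conc^hill / (conc^hill + ec50^hill), 0)
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities <= the observed
# table's probability).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  x <- tab[1, 1]
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, c1, c2, r1)
  p_obs <- dhyper(x, c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUROC via explicit trapezoidal integration of the ROC curve (tie groups
# collapse to single curve vertices).
oracle_auroc_trapezoid <- function(score, labels) {
  labels <- as.integer(labels)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[labels == 0] >= t), 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Soft-threshold, the closed-form lasso solution on an orthonormal design.
oracle_soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# A design whose centered columns are orthonormal in the n-scaled sense
# (X'X / n = I, column means 0): internal standardization is then a no-op.
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Z <- scale(matrix(rnorm(n * (p + 1)), n, p + 1), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))[, seq_len(p), drop = FALSE]
  X <- sqrt(n) * Q
  colnames(X) <- sprintf("f%02d", seq_len(p))
  X
}

# Simulated cohort plus assembled analysis inputs for one arm.
make_analysis <- function(seed, arm = "IR", ...) {
  cohort <- simulate_cohort(sim_config(seed = seed, ...))
  c(list(cohort = cohort), cohort_features(cohort, arm))
}
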