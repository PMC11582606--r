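# GAVA: the GBM Apoptotic Vulnerability Assessment. A sample is GAVA positive
# when it is highly primed AND TP53 wild-type AND MDM2 wild-type (AND MGMT
# negative for the TMZ + BCL-xLi arm) -- the top-ranked IMF product features
# applied as binary variables. Priming cutoffs come from either an ROC curve
# (Youden's J) or the cohort median; evaluation reports sensitivity,
# specificity, a rank-statistic AUROC of the continuous pre-threshold score,
# and Fisher's exact test on the 2x2 call x response table.

#' ROC-derived priming threshold (Youden's J)
#'
#' Scans midpoints between sorted unique priming scores and returns the
#' threshold maximizing `J = sensitivity + specificity - 1` for the rule
#' "highly primed iff `bim_auc >= threshold`". Ties favor the lowest
#' threshold (the more inclusive cutoff).
#'
#' @param bim_auc per-sample priming scores
#' @param sensitive binary response labels (both classes must be present)
#' @return list with `threshold`, `j`, `sensitivity`, `specificity`,
#'   `uninformative` (TRUE when the best J is 0), `rule = "roc"`
#' @export
priming_threshold_roc <- function(bim_auc, sensitive) {
  sensitive <- as.integer(sensitive)
  if (length(unique(sensitive)) < 2L)
    stop_input("both response classes must be present for an ROC threshold")
  u <- sort(unique(bim_auc))
  if (length(u) < 2L) {
    return(list(threshold = u[1], j = 0, sensitivity = 1, specificity = 0,
                uninformative = TRUE, rule = "roc"))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(sensitive == 1); n0 <- sum(sensitive == 0)
  stats <- vapply(cand, function(t) {
    hp <- bim_auc >= t
    se <- sum(hp & sensitive == 1) / n1
    sp <- sum(!hp & sensitive == 0) / n0
    c(se + sp - 1, se, sp)
  }, numeric(3))
  best <- which(stats[1, ] >= max(stats[1, ]) - 1e-12)
  pick <- best[1]  # lowest threshold among maximizers
  list(threshold = cand[pick], j = stats[1, pick],
       sensitivity = stats[2, pick], specificity = stats[3, pick],
       uninformative = stats[1, pick] <= 0, rule = "roc")
}

#' Median priming threshold
#'
#' The cohort median of the priming scores; samples strictly above it are
#' highly primed (used for ex vivo and patient cohorts).
#'
#' @param bim_auc per-sample priming scores (>= 2 samples)
#' @return list with `threshold` and `rule = "median"`
#' @export
priming_threshold_median <- function(bim_auc) {
  if (length(bim_auc) < 2L) stop_input("need at least 2 samples")
  list(threshold = median(bim_auc), rule = "median")
}

#' Classify samples as highly primed
#'
#' The ROC rule is inclusive at the threshold (`>=`); the median rule is
#' strictly above.
#'
#' @param bim_auc priming scores
#' @param threshold a threshold list from [priming_threshold_roc()] /
#'   [priming_threshold_median()], or a bare number (treated with the rule
#'   given by `rule`)
#' @param rule `"roc"` or `"median"`; ignored when `threshold` carries one
#' @return integer vector, 1 = highly primed
#' @export
classify_primed <- function(bim_auc, threshold, rule = c("roc", "median")) {
  if (is.list(threshold)) {
    rule <- threshold$rule
    threshold <- threshold$threshold
  } else rule <- match.arg(rule)
  if (rule == "roc") as.integer(bim_auc >= threshold)
  else as.integer(bim_auc > threshold)
}

#' GAVA binary call
#'
#' IR + BCL-xLi arm: positive iff highly primed AND TP53 WT AND MDM2 WT.
#' TMZ + BCL-xLi arm: additionally requires MGMT-negative status (the TMZ
#' requirement set is a superset, so a TMZ-positive call implies an
#' IR-positive call).
#'
#' @param primed,tp53_wt,mdm2_wt binary indicators in \{0, 1\} (vectorized)
#' @param mgmt_negative binary indicator; required for the TMZ arm
#' @param arm `"IR"` or `"TMZ"`
#' @param sample_ids optional sample identifiers
#' @return a data.frame of class `gava_call`: per-sample component indicators
#'   and `call` ("positive"/"negative")
#' @export
gava_score <- function(primed, tp53_wt, mdm2_wt, mgmt_negative = NULL,
                       arm = c("IR", "TMZ"), sample_ids = NULL) {
  arm <- match.arg(arm)
  comp <- list(primed = primed, tp53_wt = tp53_wt, mdm2_wt = mdm2_wt)
  if (arm == "TMZ") {
    if (is.null(mgmt_negative))
      stop_input("mgmt_negative is required for the TMZ arm")
    comp$mgmt_negative <- mgmt_negative
  }
  if (any(vapply(comp, is.null, TRUE)) ||
      !all(unlist(comp) %in% c(0, 1)))
    stop_input("all required indicators must be supplied as 0/1")
  pos <- Reduce(`*`, comp)
  out <- data.frame(
    sample = sample_ids %||% seq_along(primed), arm = arm,
    primed = as.integer(primed), tp53_wt = as.integer(tp53_wt),
    mdm2_wt = as.integer(mdm2_wt),
    mgmt_negative = if (arm == "TMZ") as.integer(mgmt_negative) else NA_integer_,
    call = ifelse(pos == 1, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gava_call", "data.frame")
  out
}

#' AUROC by the rank statistic
#'
#' The probability that a random positive outscores a random negative
#' (Wilcoxon U / (n1 n0); ties count one half).
#'
#' @param score continuous classifier scores
#' @param labels binary labels (both classes required)
#' @return the AUROC in \[0, 1\]
#' @export
auroc <- function(score, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop_input("both classes required for AUROC")
  r <- rank(score)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate GAVA calls against response labels
#'
#' Reports sensitivity `P(positive | sensitive)`, specificity
#' `P(negative | insensitive)`, the 2x2 contingency table, Fisher's exact
#' two-sided p-value, and -- when a continuous pre-threshold `score` is given
#' (the priming score masked by the molecular indicators, i.e. the top IMF
#' product feature itself) -- the rank-statistic AUROC. When a call group or
#' label class is empty the corresponding entries are `NA` and flagged.
#'
#' @param calls a `gava_call` data.frame from [gava_score()], or a character
#'   vector of "positive"/"negative"
#' @param sensitive binary response labels, aligned with the calls
#' @param score optional continuous score for the AUROC
#' @return an object of class `gava_eval`
#' @export
evaluate_gava <- function(calls, sensitive, score = NULL) {
  call_vec <- if (is.data.frame(calls)) calls$call else calls
  sensitive <- as.integer(sensitive)
  if (length(call_vec) != length(sensitive))
    stop_input("calls and labels are not aligned")
  pos <- call_vec == "positive"
  tab <- matrix(c(sum(pos & sensitive == 1), sum(pos & sensitive == 0),
                  sum(!pos & sensitive == 1), sum(!pos & sensitive == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(call = c("positive", "negative"),
                                response = c("sensitive", "insensitive")))
  n_sens <- sum(sensitive == 1); n_insens <- sum(sensitive == 0)
  flags <- character(0)
  sens <- if (n_sens > 0) tab[1, 1] / n_sens else NA_real_
  spec <- if (n_insens > 0) tab[2, 2] / n_insens else NA_real_
  if (n_sens == 0 || n_insens == 0) flags <- c(flags, "one response class empty")
  fisher_p <- NA_real_
  if (all(rowSums(tab) > 0)) {
    fisher_p <- fisher.test(tab)$p.value
  } else flags <- c(flags, "one call group empty: Fisher test skipped")
  auc <- NA_real_
  if (!is.null(score) && n_sens > 0 && n_insens > 0)
    auc <- auroc(score, sensitive)
  structure(
    list(contingency = tab, sensitivity = sens, specificity = spec,
         fisher_p = fisher_p, auroc = auc, flags = flags),
    class = "gava_eval"
  )
}

#' @export
print.gava_eval <- function(x, ...) {
  cat("GAVA evaluation\n")
  print(x$contingency)
  cat(sprintf("  sensitivity = %.3f, specificity = %.3f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  Fisher exact p = %.4g; AUROC = %s\n", x$fisher_p,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
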