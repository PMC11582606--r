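# BH3-profiling analytics: DMSO normalization, the BIM AUC priming statistic,
# dynamic-profiling deltas, cohort z-scores and anti-apoptotic dependency calls.
#
# All release values are percentages of cytochrome c release in [0, 100];
# concentrations are in micromolar.

#' Standard BH3 peptide panel
#'
#' The single-concentration peptide panel used for basal profiling, with each
#' peptide's anti-apoptotic target(s) and assay concentration: ABT-199 (BCL-2,
#' 1 uM), MS1 (MCL-1, 10 uM), HRK (BCL-xL, 100 uM), BAD (BCL-2/BCL-xL, 10 uM).
#' BIM is pan-anti-apoptotic and run as a titration (see
#' [bim_titration_grid()]).
#'
#' @return a data.frame with columns `peptide`, `target`, `concentration_uM`
#'   (`NA` for the BIM titration)
#' @export
peptide_panel <- function() {
  data.frame(
    peptide = c("ABT-199", "MS1", "HRK", "BAD", "BIM"),
    target = c("BCL-2", "MCL-1", "BCL-xL", "BCL-2/BCL-xL", "pan"),
    concentration_uM = c(1, 10, 100, 10, NA),
    stringsAsFactors = FALSE
  )
}

#' BIM peptide titration grid
#'
#' The eight BIM concentrations (uM) used for priming titrations:
#' 0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10.
#'
#' @return numeric vector of concentrations in uM
#' @export
bim_titration_grid <- function() c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)

#' Construct a titration curve
#'
#' @param sample_id sample identifier
#' @param concentrations strictly increasing non-negative concentrations (uM)
#' @param release percent cytochrome c release at each concentration, in
#'   \[0, 100\]
#' @return an object of class `titration_curve`
#' @export
titration_curve <- function(sample_id, concentrations, release) {
  if (length(concentrations) != length(release))
    stop_input("concentrations and release must have equal length")
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stop_input("concentrations must be non-negative and strictly increasing")
  if (any(release < 0 | release > 100))
    stop_input("release values must lie in [0, 100]")
  structure(
    list(sample_id = sample_id, concentrations = as.numeric(concentrations),
         release = as.numeric(release)),
    class = "titration_curve"
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("BH3 titration curve for sample", x$sample_id, "\n")
  print(data.frame(concentration_uM = x$concentrations, pct_release = x$release))
  invisible(x)
}

#' Normalize raw release to the DMSO (vehicle) negative control
#'
#' Background cytochrome c release measured in the DMSO control is subtracted
#' from the raw measurement and the result clipped to \[0, 100\].
#'
#' @param raw_release raw percent release, in \[0, 100\] (vectorized)
#' @param dmso_release DMSO-control percent release, in \[0, 100\]
#' @return normalized percent release in \[0, 100\]
#' @export
normalize_to_vehicle <- function(raw_release, dmso_release) {
  if (any(raw_release < 0 | raw_release > 100, na.rm = TRUE) ||
      any(dmso_release < 0 | dmso_release > 100, na.rm = TRUE))
    stop_input("release values must lie in [0, 100]")
  clip01(raw_release - dmso_release)
}

#' Mitochondrial priming score: BIM AUC over the titration's dynamic range
#'
#' Integrates percent cytochrome c release over log10(concentration) across the
#' titration points falling inside the dynamic range (closed interval, default
#' 0.03-3 uM, the concentrations with the greatest spread of responses), using
#' the trapezoid rule, then divides by the spanned log10 width. The score
#' therefore reads as a mean percent release over the dynamic range and lies in
#' \[0, 100\]; it is invariant to titration points outside the range.
#'
#' @param curve a [titration_curve()], or a numeric vector of concentrations if
#'   `release` is supplied
#' @param release percent release values (only when `curve` is a numeric vector)
#' @param dynamic_range closed concentration interval (uM) to integrate over
#' @return the BIM AUC priming score (percent, 0-100)
#' @examples
#' cc <- bim_titration_grid()
#' rel <- 100 * cc / (cc + 0.3)  # Hill curve, EC50 0.3 uM
#' compute_bim_auc(titration_curve("s1", cc, rel))
#' @export
compute_bim_auc <- function(curve, release = NULL, dynamic_range = c(0.03, 3)) {
  if (inherits(curve, "titration_curve")) {
    conc <- curve$concentrations
    rel <- curve$release
  } else {
    conc <- curve
    rel <- release
    if (is.null(rel)) stop_input("release values are required")
  }
  if (length(dynamic_range) != 2L || dynamic_range[1] <= 0 ||
      dynamic_range[2] <= dynamic_range[1])
    stop_input("dynamic_range must be a positive increasing interval")
  keep <- conc >= dynamic_range[1] & conc <= dynamic_range[2]
  if (sum(keep) < 2L)
    stop_input("need at least 2 titration points inside the dynamic range")
  lx <- log10(conc[keep])
  h <- rel[keep]
  auc <- sum(diff(lx) * (h[-1] + h[-length(h)]) / 2)
  auc / (lx[length(lx)] - lx[1])
}

#' Dynamic BH3-profiling delta (treated minus vehicle)
#'
#' Both inputs must already be normalized to the DMSO control. The sign is
#' preserved: a negative delta means release fell with treatment.
#'
#' @param treated normalized percent release after treatment
#' @param vehicle normalized percent release in the vehicle condition
#' @param peptide peptide name (e.g. "HRK", "MS1", "ABT-199")
#' @param sample_id sample identifier
#' @param treatment treatment label
#' @return a one-row data.frame: sample, peptide, treatment, delta_release
#' @export
dynamic_delta <- function(treated, vehicle, peptide,
                          sample_id = NA_character_, treatment = NA_character_) {
  if (any(treated < 0 | treated > 100) || any(vehicle < 0 | vehicle > 100))
    stop_input("normalized release values must lie in [0, 100]")
  data.frame(
    sample = sample_id, peptide = peptide, treatment = treatment,
    delta_release = treated - vehicle, stringsAsFactors = FALSE
  )
}

#' Z-scores across samples
#'
#' Centers and scales a per-sample statistic using the sample standard
#' deviation (n - 1 denominator), as used for cross-sample display of BH3
#' responses.
#'
#' @param values numeric vector, one value per sample (>= 2 samples)
#' @return z-scores with mean 0 and sample sd 1
#' @export
zscore_across_samples <- function(values) {
  if (length(values) < 2L) stop_input("need at least 2 samples")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop_input("zero spread across samples: z-scores are undefined")
  (values - mean(values)) / s
}

#' Call anti-apoptotic dependency from dynamic deltas
#'
#' Classifies a sample's treatment-induced dependency shift from its HRK
#' (BCL-xL) and MS1 (MCL-1) deltas: a single dependency is called when only
#' that peptide's delta exceeds the threshold, `dual` when both do, `none`
#' otherwise.
#'
#' @param deltas named numeric vector of delta-release values containing at
#'   least `HRK` and `MS1`, or a data.frame with columns `peptide` and
#'   `delta_release`
#' @param threshold percentage-point cutoff (default 10)
#' @return one of `"single-BCLXL"`, `"single-MCL1"`, `"dual"`, `"none"`
#' @export
call_dependency <- function(deltas, threshold = 10) {
  if (is.data.frame(deltas))
    deltas <- setNames(deltas$delta_release, deltas$peptide)
  if (!all(c("HRK", "MS1") %in% names(deltas)))
    stop_input("deltas must include the HRK and MS1 peptides")
  hrk <- deltas[["HRK"]] > threshold
  ms1 <- deltas[["MS1"]] > threshold
  if (hrk && ms1) "dual"
  else if (hrk) "single-BCLXL"
  else if (ms1) "single-MCL1"
  else "none"
}

#' Per-sample priming scores from a long-format BH3 table
#'
#' Replicate measurements are averaged per sample and concentration before the
#' AUC is computed (mean-first convention).
#'
#' @param bh3_long data.frame with columns `sample`, `peptide`,
#'   `concentration_uM`, `pct_release` (and optionally `replicate`)
#' @param peptide the titrated peptide to score (default "BIM")
#' @param dynamic_range passed to [compute_bim_auc()]
#' @return data.frame with columns `sample`, `bim_auc`
#' @export
priming_scores <- function(bh3_long, peptide = "BIM", dynamic_range = c(0.03, 3)) {
  need <- c("sample", "peptide", "concentration_uM", "pct_release")
  if (!all(need %in% names(bh3_long)))
    stop_input("bh3_long must have columns: ", paste(need, collapse = ", "))
  d <- bh3_long[bh3_long$peptide == peptide, , drop = FALSE]
  if (nrow(d) == 0L) stop_input("no rows for peptide ", peptide)
  agg <- stats::aggregate(pct_release ~ sample + concentration_uM, data = d, FUN = mean)
  ids <- sort(unique(agg$sample))
  auc <- vapply(ids, function(s) {
    sub <- agg[agg$sample == s, , drop = FALSE]
    sub <- sub[order(sub$concentration_uM), , drop = FALSE]
    compute_bim_auc(sub$concentration_uM, sub$pct_release, dynamic_range)
  }, numeric(1))
  data.frame(sample = ids, bim_auc = unname(auc), stringsAsFactors = FALSE)
}
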