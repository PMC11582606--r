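# Molecular feature processing: MGMT composite status, EGFRvIII transcript
# allele frequency calls, duplicate-column merging, and construction of the
# IMF (integrated molecular + functional) and GM (global molecular) feature
# matrices, plus response binarization.
#
# Feature matrices are samples x features numeric matrices carrying a
# per-feature provenance attribute ("IMF" or "GM"). Feature names are the
# construction formulas (e.g. "BIMAUC*TP53*MDM2").

#' Create a feature matrix with provenance
#'
#' @param x numeric matrix, samples in rows, named feature columns
#' @param provenance `"IMF"` or `"GM"`, recycled to the number of columns
#' @return the matrix with a `provenance` attribute
#' @export
feature_matrix <- function(x, provenance) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop_input("features must be named")
  if (anyDuplicated(colnames(x))) stop_input("feature names must be unique")
  attr(x, "provenance") <- rep_len(provenance, ncol(x))
  x
}

#' Feature provenance tags
#'
#' @param x a feature matrix
#' @return character vector of provenance tags, one per column
#' @export
provenance <- function(x) {
  attr(x, "provenance") %||% rep(NA_character_, ncol(x))
}

#' Pool feature matrices, keeping provenance
#'
#' @param ... feature matrices with identical row sets
#' @return the column-bound feature matrix
#' @export
pool_features <- function(...) {
  mats <- list(...)
  rn <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), rn))
      stop_input("feature matrices must share the same samples in the same order")
  }
  out <- do.call(cbind, lapply(mats, unclass))
  if (anyDuplicated(colnames(out))) stop_input("pooled feature names collide")
  attr(out, "provenance") <- unlist(lapply(mats, provenance), use.names = FALSE)
  out
}

#' MGMT composite status
#'
#' A tumour is MGMT negative (repair-deficient, temozolomide-sensitive) when
#' its promoter is methylated OR its MGMT RNA expression falls below the
#' cohort median; only unmethylated tumours with expression at or above the
#' median are MGMT positive. The median must be computed over the analysis
#' cohort and, for verification cohorts, frozen from training.
#'
#' @param methylated binary promoter-methylation indicator (vectorized)
#' @param expression MGMT RNA expression (TPM-like)
#' @param cohort_expression_median the cohort median expression cutoff
#' @return character vector, `"negative"` or `"positive"`
#' @export
mgmt_status <- function(methylated, expression, cohort_expression_median) {
  if (missing(methylated) && missing(expression))
    stop_input("MGMT status undetermined: need methylation or expression")
  if (any(is.na(methylated) & is.na(expression)))
    stop_input("MGMT status undetermined for samples missing both inputs")
  neg <- (methylated == 1) | (expression < cohort_expression_median)
  ifelse(neg, "negative", "positive")
}

#' EGFRvIII call from junction read counts
#'
#' The transcript allele frequency (TAF) is the percentage of junction reads
#' supporting the aberrant exon 1-8 junction out of all reads at the exon 1-8
#' and exon 7-8 junctions; samples with TAF strictly over 10% are called
#' positive.
#'
#' @param reads_ex1_8 read count at the aberrant exon 1-8 junction
#' @param reads_ex7_8 read count at the wild-type exon 7-8 junction
#' @return a list with `taf` (percent) and `positive` (logical)
#' @export
egfrviii_call <- function(reads_ex1_8, reads_ex7_8) {
  if (any(reads_ex1_8 < 0) || any(reads_ex7_8 < 0))
    stop_input("read counts must be non-negative")
  total <- reads_ex1_8 + reads_ex7_8
  if (any(total == 0))
    stop_input("EGFRvIII call undetermined: zero total junction reads")
  taf <- 100 * reads_ex1_8 / total
  list(taf = taf, positive = taf > 10)
}

#' Merge features with exactly identical values
#'
#' Collinearity reduction: columns whose value vectors are bitwise identical
#' collapse to a single column named by concatenating the member names with
#' `"|"` (in original column order). Idempotent.
#'
#' @param x a feature matrix (samples x features)
#' @return the merged feature matrix (provenance of each group's first member)
#' @export
merge_identical_features <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) return(x)
  had_prov <- !is.null(attr(x, "provenance"))
  prov <- provenance(x)
  keys <- vapply(seq_len(ncol(x)), function(j) hash_object(unname(x[, j])), "")
  groups <- unname(split(seq_len(ncol(x)), factor(keys, levels = unique(keys))))
  first <- vapply(groups, `[`, integer(1), 1L)
  out <- x[, first, drop = FALSE]
  colnames(out) <- vapply(groups, function(g)
    paste(colnames(x)[g], collapse = "|"), "")
  if (had_prov) attr(out, "provenance") <- prov[first]
  out
}

#' All products over non-empty subsets of base variables
#'
#' Expands k named per-sample variables into the 2^k - 1 simple products
#' (singletons included, no separately added main effects beyond the
#' singletons themselves); names join the member names with `"*"`.
#'
#' @param vars named list of equal-length numeric vectors
#' @param provenance provenance tag for the resulting features
#' @return a samples x (2^k - 1) feature matrix
#' @export
interaction_products <- function(vars, provenance = "IMF") {
  if (length(vars) == 0L || is.null(names(vars)) || any(names(vars) == ""))
    stop_input("vars must be a non-empty named list")
  n <- unique(lengths(vars))
  if (length(n) != 1L) stop_input("all base variables must have equal length")
  k <- length(vars)
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  subsets <- subsets[order(lengths(subsets))]
  cols <- lapply(subsets, function(s) Reduce(`*`, vars[s]))
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(subsets, function(s) paste(names(vars)[s], collapse = "*"), "")
  rownames(out) <- names(vars[[1]])
  feature_matrix(out, provenance)
}

#' Build the IMF (Integrated Molecular and Functional) feature set
#'
#' The 15 features are all non-empty subset products of the four base
#' variables: the BIM AUC priming score and favorable-status indicators for
#' TP53 (wild-type = 1), MDM2 (not amplified = 1) and MGMT (negative = 1).
#' Products read as "all conditions met" scores, e.g. `BIMAUC*TP53*MDM2` is
#' the priming score masked by an intact p53 axis.
#'
#' @param bim_auc per-sample priming score
#' @param tp53_wt,mdm2_wt,mgmt_negative binary indicators in \{0, 1\}
#' @param sample_ids optional row names
#' @return a samples x 15 feature matrix with provenance `"IMF"`
#' @export
build_imf_features <- function(bim_auc, tp53_wt, mdm2_wt, mgmt_negative,
                               sample_ids = NULL) {
  if (missing(bim_auc) || missing(tp53_wt) || missing(mdm2_wt) ||
      missing(mgmt_negative))
    stop_input("all four base variables are required")
  bins <- list(tp53_wt, mdm2_wt, mgmt_negative)
  if (!all(vapply(bins, function(b) all(b %in% c(0, 1)), TRUE)))
    stop_input("status indicators must be binary 0/1")
  vars <- list(BIMAUC = as.numeric(bim_auc), TP53 = as.numeric(tp53_wt),
               MDM2 = as.numeric(mdm2_wt), MGMT = as.numeric(mgmt_negative))
  if (!is.null(sample_ids)) vars <- lapply(vars, setNames, sample_ids)
  interaction_products(vars, provenance = "IMF")
}

#' Build the GM (Global Molecular) feature set
#'
#' Per omics block (gene expression, copy-number, mutations), identical genes
#' are merged with [merge_identical_features()]; the blocks are then
#' concatenated (name-spaced `RNA:`, `CNA:`, `MUT:`) and zero-variance columns
#' dropped. Optionally, products of every block feature with supplied binary
#' molecular indicators are appended (without indicator main effects);
#' zero-variance products are excluded.
#'
#' @param expression,cna,mutations gene x sample matrices (any subset, at
#'   least one)
#' @param interact_with optional named list of per-sample binary indicators to
#'   form products with (default: none)
#' @return a samples x features matrix with provenance `"GM"`
#' @export
build_gm_features <- function(expression = NULL, cna = NULL, mutations = NULL,
                              interact_with = NULL) {
  blocks <- list(RNA = expression, CNA = cna, MUT = mutations)
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (length(blocks) == 0L) stop_input("at least one omics block is required")
  mats <- lapply(names(blocks), function(nm) {
    b <- t(as.matrix(blocks[[nm]]))  # to samples x genes
    colnames(b) <- paste0(nm, ":", colnames(b))
    merge_identical_features(feature_matrix(b, "GM"))
  })
  out <- do.call(pool_features, mats)
  if (!is.null(interact_with)) {
    prods <- lapply(names(interact_with), function(v) {
      p <- out * interact_with[[v]]
      colnames(p) <- paste0(colnames(out), "*", v)
      p
    })
    prods <- do.call(cbind, prods)
    attr(prods, "provenance") <- rep("GM", ncol(prods))
    out <- pool_features(out, prods)
  }
  keep <- apply(out, 2, function(v) length(unique(v)) > 1L)
  if (!any(keep)) stop_input("no non-constant GM features remain after filtering")
  prov <- provenance(out)[keep]
  out <- out[, keep, drop = FALSE]
  attr(out, "provenance") <- prov
  out
}

#' Binarize treatment response at the arm mean
#'
#' Samples with cell death strictly above the arm's mean response are labelled
#' sensitive. Invariant to adding a constant to all responses.
#'
#' @param responses named numeric vector of percent cell death for one arm
#' @return named integer vector (1 = sensitive)
#' @export
binarize_response <- function(responses) {
  if (length(responses) < 2L) stop_input("need at least 2 samples")
  as.integer(responses > mean(responses)) |> setNames(names(responses))
}
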