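# End-to-end orchestration: simulate (or read) a cohort, score priming, build
# IMF/GM features, fit both models under nested LOOCV, rank the pooled
# features with a permutation null, apply GAVA, and write TSV/JSON outputs
# plus a machine-diffable manifest. Identical config + seed gives identical
# metric outputs; every output file carries the config hash. Ground-truth
# columns of synthetic cohorts are never consumed.

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e)
    stop_input("stage '", name, "' failed: ", conditionMessage(e)))
  message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  out
}

write_tsv_stamped <- function(d, path, config_hash, row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", config_hash), con)
  suppressWarnings(write.table(d, con, sep = "\t", quote = FALSE,
                               row.names = row_names,
                               col.names = if (row_names) NA else TRUE))
}

#' Assemble analysis inputs from cohort tables
#'
#' Convenience layer shared by the pipeline: computes priming scores from the
#' long BH3 table, MGMT composite status at the cohort expression median,
#' the IMF and (if omics are present) GM feature matrices, and the response
#' vector for one arm. Only analysis-facing columns are consumed; ground truth
#' in synthetic cohorts is ignored.
#'
#' @param cohort a `synthetic_cohort` or the list returned by [read_cohort()]
#' @param arm `"IR"` or `"TMZ"`
#' @return list with `bim_auc` (named), `mgmt_negative`, `imf`, `gm` (or
#'   `NULL`), `y` (named response vector) and `sensitive` (mean-binarized)
#' @export
cohort_features <- function(cohort, arm = c("IR", "TMZ")) {
  arm <- match.arg(arm)
  st <- cohort$sample_table
  ids <- st$sample
  pr <- priming_scores(cohort$bh3_long)
  bim_auc <- setNames(pr$bim_auc, pr$sample)[ids]
  if (anyNA(bim_auc)) stop_input("priming scores missing for some samples")
  mgmt_neg <- as.integer(mgmt_status(st$MGMT_methylated, st$MGMT_expression,
                                     median(st$MGMT_expression)) == "negative")
  imf <- build_imf_features(bim_auc, st$TP53_WT, st$MDM2_WT, mgmt_neg,
                            sample_ids = ids)
  gm <- if (!is.null(cohort$omics))
    build_gm_features(expression = cohort$omics) else NULL
  y <- arm_response(cohort$responses, arm)[ids]
  if (anyNA(y)) stop_input("responses missing for some samples")
  list(bim_auc = bim_auc, mgmt_negative = mgmt_neg, tp53_wt = st$TP53_WT,
       mdm2_wt = st$MDM2_WT, imf = imf, gm = gm, y = y,
       sensitive = binarize_response(y))
}

#' Run the full analysis pipeline
#'
#' Composes the stages: simulate (or read) -> priming scores -> feature
#' construction -> nested-LOOCV fits of the IMF and GM models -> LASSO-path
#' ranking with permutation null -> GAVA stratification and evaluation.
#'
#' @param config a list, or the path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer, mandatory; every stochastic stage derives its
#'       stream from it}
#'     \item{simulate}{optional list of [sim_config()] overrides; when absent,
#'       `input_dir` must point to cohort TSVs as written by [write_cohort()]}
#'     \item{input_dir}{directory of input tables (checked before any compute)}
#'     \item{arm}{`"IR"` (default) or `"TMZ"`}
#'     \item{grid}{optional list of [hyper_grid()] arguments}
#'     \item{inner}{list(folds = 5, repeats = 20)}
#'     \item{ranking}{list(k = 100, n_shuffles = 1000, nlambda = 200)}
#'     \item{threshold_rule}{`"roc"` (default) or `"median"`}
#'     \item{outdir}{optional output directory; when given, writes
#'       priming.tsv, features_imf.tsv, features_gm.tsv, gava.tsv and
#'       manifest.json}
#'   }
#' @return the run manifest (invisibly): config hash, input hashes, per-stage
#'   metrics
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_input("config validation: seed is mandatory")
  seed <- as.integer(config$seed)
  if (is.null(config$simulate)) {
    if (is.null(config$input_dir))
      stop_input("config validation: either simulate or input_dir is required")
    need <- c("samples.tsv", "bh3_long.tsv", "responses.tsv")
    miss <- need[!file.exists(file.path(config$input_dir, need))]
    if (length(miss))
      stop_input("config validation: missing input files: ",
                 paste(miss, collapse = ", "))
  }
  arm <- match.arg(config$arm %||% "IR", c("IR", "TMZ"))
  grid <- do.call(hyper_grid, config$grid %||% list())
  inner <- utils::modifyList(list(folds = 5L, repeats = 20L), config$inner %||% list())
  rk <- utils::modifyList(list(k = 100L, n_shuffles = 1000L, nlambda = 200L),
                          config$ranking %||% list())
  rule <- match.arg(config$threshold_rule %||% "roc", c("roc", "median"))
  config_hash <- hash_object(config)

  cohort <- run_stage("cohort", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(seed, "simulate")
      simulate_cohort(do.call(sim_config, sim_args))
    } else read_cohort(config$input_dir)
  })
  st <- cohort$sample_table
  ids <- st$sample

  priming <- run_stage("bh3", priming_scores(cohort$bh3_long))
  bim_auc <- setNames(priming$bim_auc, priming$sample)[ids]

  feats <- run_stage("features", cohort_features(cohort, arm))
  y <- feats$y

  fit_imf <- run_stage("fit IMF", nested_loocv(
    feats$imf, y, grid, seed = derive_seed(seed, "fit", "IMF", arm),
    folds = inner$folds, repeats = inner$repeats))
  fit_gm <- if (!is.null(feats$gm)) run_stage("fit GM", nested_loocv(
    feats$gm, y, grid, seed = derive_seed(seed, "fit", "GM", arm),
    folds = inner$folds, repeats = inner$repeats)) else NULL

  rank_res <- NULL
  if (!is.null(feats$gm)) {
    rank_res <- run_stage("rank", {
      pooled <- pool_features(feats$imf, feats$gm)
      list(ranking = lasso_path_order(pooled, y, nlambda = rk$nlambda),
           perm = permutation_pvalue(pooled, y, k = min(rk$k, ncol(pooled)),
                                     n_shuffles = rk$n_shuffles,
                                     seed = derive_seed(seed, "rank", arm),
                                     nlambda = rk$nlambda))
    })
  }

  gava <- run_stage("gava", {
    sensitive <- binarize_response(y)
    thr <- if (rule == "roc") priming_threshold_roc(bim_auc, sensitive)
           else priming_threshold_median(bim_auc)
    primed <- classify_primed(bim_auc, thr)
    calls <- gava_score(primed, st$TP53_WT, st$MDM2_WT, feats$mgmt_negative,
                        arm = arm, sample_ids = ids)
    score <- bim_auc * st$TP53_WT * st$MDM2_WT *
      (if (arm == "TMZ") feats$mgmt_negative else 1)
    list(threshold = thr, calls = calls,
         evaluation = evaluate_gava(calls, sensitive, score = score))
  })

  manifest <- list(
    package_version = as.character(packageVersion("primava")),
    config_hash = config_hash,
    seed = seed,
    arm = arm,
    input_hashes = list(
      samples = hash_object(st),
      bh3 = hash_object(cohort$bh3_long),
      responses = hash_object(cohort$responses),
      omics = if (!is.null(cohort$omics)) hash_object(cohort$omics) else NULL
    ),
    stages = list(
      priming = list(n = nrow(priming), mean_bim_auc = mean(priming$bim_auc)),
      features = list(n_imf = ncol(feats$imf),
                      n_gm = if (!is.null(feats$gm)) ncol(feats$gm) else 0L),
      fit_imf = list(rmse = fit_imf$rmse, r_squared = fit_imf$r_squared),
      fit_gm = if (!is.null(fit_gm))
        list(rmse = fit_gm$rmse, r_squared = fit_gm$r_squared) else NULL,
      ranking = if (!is.null(rank_res)) list(
        top_feature = rank_res$ranking$feature[1],
        imf_in_top_k = rank_res$perm$observed,
        k = rank_res$perm$k,
        permutation_p = rank_res$perm$p_value) else NULL,
      gava = list(threshold = gava$threshold$threshold, rule = rule,
                  sensitivity = gava$evaluation$sensitivity,
                  specificity = gava$evaluation$specificity,
                  auroc = gava$evaluation$auroc,
                  fisher_p = gava$evaluation$fisher_p)
    )
  )

  if (!is.null(config$outdir)) {
    run_stage("write", {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_stamped(priming, file.path(config$outdir, "priming.tsv"), config_hash)
      write_tsv_stamped(as.data.frame(feats$imf),
                        file.path(config$outdir, "features_imf.tsv"),
                        config_hash, row_names = TRUE)
      if (!is.null(feats$gm))
        write_tsv_stamped(as.data.frame(feats$gm),
                          file.path(config$outdir, "features_gm.tsv"),
                          config_hash, row_names = TRUE)
      write_tsv_stamped(gava$calls, file.path(config$outdir, "gava.tsv"), config_hash)
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
      invisible(NULL)
    })
  }
  results <- list(manifest = manifest, priming = priming, features = feats,
                  fit_imf = fit_imf, fit_gm = fit_gm, ranking = rank_res,
                  gava = gava)
  class(results) <- "primava_run"
  invisible(results)
}

#' @export
print.primava_run <- function(x, ...) {
  m <- x$manifest
  cat("primava pipeline run (arm", m$arm, ", seed", m$seed, ")\n")
  cat("  IMF nested-CV RMSE:", format(m$stages$fit_imf$rmse), "\n")
  if (!is.null(m$stages$fit_gm))
    cat("  GM  nested-CV RMSE:", format(m$stages$fit_gm$rmse), "\n")
  if (!is.null(m$stages$ranking))
    cat("  top pooled feature:", m$stages$ranking$top_feature,
        sprintf("(permutation p = %.4g)\n", m$stages$ranking$permutation_p))
  cat(sprintf("  GAVA: sensitivity %.2f, specificity %.2f\n",
              m$stages$gava$sensitivity, m$stages$gava$specificity))
  invisible(x)
}
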