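# Synthetic-cohort generator. Emulates the statistical structure the analysis
# assumes: binary genotype prevalences, sigmoidal (Hill) BIM titration curves
# with measurement noise, an uninformative global omics matrix containing
# duplicated genes, and cell-death responses driven by a genotype x priming
# interaction plus Gaussian noise. Ground truth is recorded separately and is
# never consumed by the analysis modules.

#' Simulation configuration
#'
#' Defaults encode a desk-scale glioma cohort: 40 samples; TP53 mutation in
#' ~35% of samples and MDM2 amplification in ~15% (the two mechanisms of p53
#' pathway loss); MGMT promoter methylation in half; MGMT expression
#' log-normal with a lower location for methylated samples; per-sample BIM
#' EC50 log-uniform across the titration range so roughly half the cohort is
#' highly primed; a favorable-interaction effect of 30 percentage points of
#' cell death over a 10-point baseline with 5-point response noise; and 2000
#' uninformative genes of which 50 duplicate other genes.
#'
#' @param n_samples number of samples (>= 4)
#' @param prevalence_tp53_mut probability a sample is TP53 mutant
#' @param prevalence_mdm2_amp probability a sample is MDM2 amplified
#' @param prevalence_mgmt_methylated probability of MGMT promoter methylation
#' @param mgmt_expr_params list with `methylated` and `unmethylated` elements,
#'   each `c(meanlog, sdlog)` for the log-normal TPM-like MGMT expression
#' @param priming_ec50_range uM interval from which per-sample BIM EC50s are
#'   drawn log-uniformly
#' @param priming_hill Hill slope of the titration curves
#' @param priming_auc_cutoff generative cutoff (percent) on the noise-free BIM
#'   AUC above which a sample is latently "highly primed"
#' @param release_noise_sd sd (percentage points) of titration measurement noise
#' @param n_replicates biological replicates per titration point
#' @param effect_size_beta percentage points of cell death added for the
#'   favorable genotype x priming interaction
#' @param response_baseline percent cell death for unfavorable samples
#' @param response_noise_sd sd (percentage points) of response noise
#' @param n_genes total genes in the omics matrix (including duplicates)
#' @param n_duplicate_genes how many of those genes duplicate another gene's
#'   values exactly
#' @param seed integer seed; a fixed seed makes the cohort bit-identical
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_samples = 40,
                       prevalence_tp53_mut = 0.35,
                       prevalence_mdm2_amp = 0.15,
                       prevalence_mgmt_methylated = 0.5,
                       mgmt_expr_params = list(
                         methylated = c(meanlog = log(2), sdlog = 0.5),
                         unmethylated = c(meanlog = log(20), sdlog = 0.5)
                       ),
                       priming_ec50_range = c(0.01, 10),
                       priming_hill = 1,
                       priming_auc_cutoff = 50,
                       release_noise_sd = 3,
                       n_replicates = 2,
                       effect_size_beta = 30,
                       response_baseline = 10,
                       response_noise_sd = 5,
                       n_genes = 2000,
                       n_duplicate_genes = 50,
                       seed = 1L) {
  probs <- c(prevalence_tp53_mut, prevalence_mdm2_amp, prevalence_mgmt_methylated)
  if (any(probs < 0 | probs > 1)) stop_input("prevalences must lie in [0, 1]")
  if (n_samples < 4) stop_input("n_samples must be >= 4 for downstream CV")
  if (effect_size_beta < 0) stop_input("effect_size_beta must be >= 0")
  if (priming_ec50_range[1] <= 0 || diff(priming_ec50_range) < 0)
    stop_input("priming_ec50_range must be a positive increasing interval")
  if (n_duplicate_genes >= n_genes) stop_input("n_duplicate_genes must be < n_genes")
  cfg <- list(
    n_samples = as.integer(n_samples),
    prevalence_tp53_mut = prevalence_tp53_mut,
    prevalence_mdm2_amp = prevalence_mdm2_amp,
    prevalence_mgmt_methylated = prevalence_mgmt_methylated,
    mgmt_expr_params = mgmt_expr_params,
    priming_ec50_range = priming_ec50_range,
    priming_hill = priming_hill,
    priming_auc_cutoff = priming_auc_cutoff,
    release_noise_sd = release_noise_sd,
    n_replicates = as.integer(n_replicates),
    effect_size_beta = effect_size_beta,
    response_baseline = response_baseline,
    response_noise_sd = response_noise_sd,
    n_genes = as.integer(n_genes),
    n_duplicate_genes = as.integer(n_duplicate_genes),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

# Noise-free Hill release at given concentrations; release(0) = 0.
hill_release <- function(concentrations, ec50, hill, max_release) {
  r <- numeric(length(concentrations))
  pos <- concentrations > 0
  cp <- concentrations[pos]
  r[pos] <- max_release * cp^hill / (cp^hill + ec50^hill)
  r
}

#' Simulate a BIM titration curve
#'
#' Hill-shaped percent cytochrome c release with additive Gaussian measurement
#' noise, clipped to \[0, 100\]. Release at zero concentration is noise only.
#' Draws from the current RNG stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param ec50 half-release concentration (uM, > 0)
#' @param hill Hill slope (> 0)
#' @param max_release plateau release (percent)
#' @param concentrations titration grid (uM), non-negative strictly increasing
#' @param noise_sd measurement noise sd (percentage points)
#' @param sample_id identifier stored on the curve
#' @return a [titration_curve()]
#' @export
simulate_titration_curve <- function(ec50, hill = 1, max_release = 100,
                                     concentrations = bim_titration_grid(),
                                     noise_sd = 0, sample_id = NA_character_) {
  if (ec50 <= 0) stop_input("ec50 must be positive")
  if (hill <= 0) stop_input("hill slope must be positive")
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stop_input("concentrations must be non-negative and strictly increasing")
  mu <- hill_release(concentrations, ec50, hill, max_release)
  rel <- clip01(mu + rnorm(length(mu), 0, noise_sd))
  titration_curve(sample_id, concentrations, rel)
}

#' Simulate a synthetic cohort
#'
#' Generates sample genotypes, per-sample BIM titration curves (with
#' replicates), an uninformative gene x sample omics matrix containing exact
#' duplicate genes, and percent-cell-death responses for the two treatment
#' arms. The response model is
#' `baseline + beta * primed * TP53_WT * MDM2_WT (* MGMT_negative for TMZ) + N(0, sd)`,
#' clipped to \[0, 100\], where `primed` is the latent indicator that the
#' noise-free BIM AUC exceeds the generative cutoff. Four purpose-specific RNG
#' streams (genotype, titration, omics, response) are derived from the config
#' seed, so e.g. changing `n_genes` does not perturb the genotypes.
#'
#' @param config a [sim_config()]
#' @return an object of class `synthetic_cohort`: a list with `sample_table`,
#'   `bh3_long`, `responses` (long: sample, arm, pct_death), `omics`
#'   (gene x sample matrix), `truth` (latent priming and true sensitivity
#'   labels; never used by analysis code) and `config`
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_input("config must be a sim_config")
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))

  set.seed(config$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 4L)

  # genotypes ------------------------------------------------------------
  set.seed(streams[1])
  tp53_wt <- 1L - rbinom(n, 1, config$prevalence_tp53_mut)
  mdm2_wt <- 1L - rbinom(n, 1, config$prevalence_mdm2_amp)
  mgmt_meth <- rbinom(n, 1, config$prevalence_mgmt_methylated)
  pm <- config$mgmt_expr_params
  mgmt_expr <- ifelse(
    mgmt_meth == 1,
    rlnorm(n, pm$methylated[["meanlog"]], pm$methylated[["sdlog"]]),
    rlnorm(n, pm$unmethylated[["meanlog"]], pm$unmethylated[["sdlog"]])
  )

  # titrations -----------------------------------------------------------
  set.seed(streams[2])
  lr <- log(config$priming_ec50_range)
  ec50 <- exp(runif(n, lr[1], lr[2]))
  grid <- bim_titration_grid()
  latent_auc <- vapply(ec50, function(e) {
    compute_bim_auc(grid, hill_release(grid, e, config$priming_hill, 100))
  }, numeric(1))
  primed <- as.integer(latent_auc > config$priming_auc_cutoff)
  bh3 <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_len(config$n_replicates), function(rep) {
      cv <- simulate_titration_curve(
        ec50[i], config$priming_hill, 100, grid,
        noise_sd = config$release_noise_sd, sample_id = ids[i]
      )
      data.frame(sample = ids[i], peptide = "BIM",
                 concentration_uM = cv$concentrations,
                 pct_release = cv$release, replicate = rep,
                 stringsAsFactors = FALSE)
    }))
  }))

  # omics ----------------------------------------------------------------
  set.seed(streams[3])
  n_indep <- config$n_genes - config$n_duplicate_genes
  omics <- matrix(rlnorm(n_indep * n, meanlog = log(10), sdlog = 1),
                  nrow = n_indep, ncol = n)
  if (config$n_duplicate_genes > 0) {
    src <- sample.int(n_indep, config$n_duplicate_genes, replace = TRUE)
    omics <- rbind(omics, omics[src, , drop = FALSE])
  }
  rownames(omics) <- sprintf("G%05d", seq_len(config$n_genes))
  colnames(omics) <- ids

  # responses ------------------------------------------------------------
  set.seed(streams[4])
  mgmt_negative <- as.integer(
    mgmt_status(mgmt_meth, mgmt_expr, median(mgmt_expr)) == "negative"
  )
  fav_ir <- primed * tp53_wt * mdm2_wt
  fav_tmz <- fav_ir * mgmt_negative
  # a sample is truly sensitive only when the interaction actually moves death
  lab_ir <- as.integer(config$effect_size_beta > 0) * fav_ir
  lab_tmz <- as.integer(config$effect_size_beta > 0) * fav_tmz
  resp_ir <- clip01(config$response_baseline + config$effect_size_beta * fav_ir +
                      rnorm(n, 0, config$response_noise_sd))
  resp_tmz <- clip01(config$response_baseline + config$effect_size_beta * fav_tmz +
                       rnorm(n, 0, config$response_noise_sd))

  sample_table <- data.frame(
    sample = ids, TP53_WT = tp53_wt, MDM2_WT = mdm2_wt,
    MGMT_methylated = mgmt_meth, MGMT_expression = mgmt_expr,
    stringsAsFactors = FALSE
  )
  responses <- data.frame(
    sample = rep(ids, 2), arm = rep(c("IR", "TMZ"), each = n),
    pct_death = c(resp_ir, resp_tmz), stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample = ids, latent_auc = latent_auc, primed = primed,
    mgmt_negative = mgmt_negative,
    sensitive_IR = lab_ir, sensitive_TMZ = lab_tmz,
    stringsAsFactors = FALSE
  )
  structure(
    list(sample_table = sample_table, bh3_long = bh3, responses = responses,
         omics = omics, truth = truth, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_samples, "samples,",
      nrow(x$omics), "genes (", x$config$n_duplicate_genes, "duplicated ),",
      "seed", x$config$seed, "\n")
  cat("  highly primed (truth):", sum(x$truth$primed), "samples\n")
  cat("  sensitive (truth): IR", sum(x$truth$sensitive_IR),
      "| TMZ", sum(x$truth$sensitive_TMZ), "\n")
  invisible(x)
}

#' Extract a response vector for one treatment arm
#'
#' @param cohort a `synthetic_cohort` or a long responses data.frame
#' @param arm `"IR"` or `"TMZ"` (the IR + BCL-xLi / TMZ + BCL-xLi combinations)
#' @return named numeric vector of percent cell death per sample
#' @export
arm_response <- function(cohort, arm = c("IR", "TMZ")) {
  arm <- match.arg(arm)
  resp <- if (inherits(cohort, "synthetic_cohort")) cohort$responses else cohort
  d <- resp[resp$arm == arm, , drop = FALSE]
  if (nrow(d) == 0L) stop_input("no responses for arm ", arm)
  setNames(d$pct_death, d$sample)
}

#' Write a cohort to disk as TSV files plus a YAML config
#'
#' Writes `samples.tsv`, `bh3_long.tsv`, `expression.tsv`, `responses.tsv`,
#' `truth.tsv` and `config.yaml` under `dir`.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, f, rn = FALSE)
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = rn, col.names = if (rn) NA else TRUE)
  tsv(cohort$sample_table, "samples.tsv")
  tsv(cohort$bh3_long, "bh3_long.tsv")
  tsv(cohort$responses, "responses.tsv")
  tsv(cohort$truth, "truth.tsv")
  tsv(as.data.frame(cohort$omics), "expression.tsv", rn = TRUE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir directory containing the TSV files
#' @return a list with `sample_table`, `bh3_long`, `responses`, `omics`
#'   (no truth: analysis inputs only)
#' @export
read_cohort <- function(dir) {
  need <- c("samples.tsv", "bh3_long.tsv", "responses.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop_input("missing cohort files: ", paste(miss, collapse = ", "))
  out <- list(
    sample_table = read.delim(file.path(dir, "samples.tsv")),
    bh3_long = read.delim(file.path(dir, "bh3_long.tsv")),
    responses = read.delim(file.path(dir, "responses.tsv"))
  )
  expr_path <- file.path(dir, "expression.tsv")
  if (file.exists(expr_path)) {
    e <- read.delim(expr_path, row.names = 1, check.names = FALSE)
    out$omics <- as.matrix(e)
  }
  out
}
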