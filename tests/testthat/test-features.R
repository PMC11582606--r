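# Molecular feature processing and feature-matrix construction.

test_that("MGMT composite status follows the methylation-or-low-expression rule", {
  med <- 10
  expect_equal(mgmt_status(1, 15, med), "negative")  # methylated, high expression
  expect_equal(mgmt_status(0, 15, med), "positive")  # unmethylated, high
  expect_equal(mgmt_status(0, 5, med), "negative")   # unmethylated, low
  expect_equal(mgmt_status(c(1, 0, 0), c(15, 15, 5), med),
               c("negative", "positive", "negative"))
  expect_error(mgmt_status(NA, NA, med), "undetermined")
})

test_that("MGMT status depends only on rank relative to the median", {
  set.seed(8)
  meth <- rbinom(20, 1, 0.4)
  expr <- rlnorm(20)
  s1 <- mgmt_status(meth, expr, median(expr))
  s2 <- mgmt_status(meth, exp(expr), median(exp(expr)))  # monotone rescale
  expect_identical(s1, s2)
})

test_that("EGFRvIII TAF uses a strict 10% cutoff", {
  expect_equal(egfrviii_call(15, 85), list(taf = 15, positive = TRUE))
  expect_equal(egfrviii_call(5, 95), list(taf = 5, positive = FALSE))
  expect_equal(egfrviii_call(10, 90), list(taf = 10, positive = FALSE))
  expect_error(egfrviii_call(0, 0), "undetermined")
  expect_error(egfrviii_call(-1, 5), "non-negative")
})

test_that("identical feature columns merge by value, idempotently", {
  X <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(4, 5, 6))
  m <- merge_identical_features(X)
  expect_equal(colnames(m), c("A|B", "C"))
  expect_equal(unname(m[, 1]), c(1, 2, 3))
  # all distinct: unchanged
  Y <- cbind(A = 1:3, B = 4:6)
  expect_equal(merge_identical_features(Y), Y)
  # one duplicated pair plus one triplicated set among 5 columns -> 3 columns
  v1 <- c(1, 0, 2); v2 <- c(5, 5, 5)
  Z <- cbind(p = v1, q = v1, r = v2, s = v2, t = v2)
  expect_equal(ncol(merge_identical_features(Z)), 2)  # {p,q}, {r,s,t}
  Z2 <- cbind(Z, u = c(9, 8, 7))
  expect_equal(ncol(merge_identical_features(Z2)), 3)
  expect_identical(merge_identical_features(merge_identical_features(Z2)),
                   merge_identical_features(Z2))
})

test_that("merging is order-invariant up to column naming", {
  set.seed(5)
  X <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, letters[1:5]))
  X <- cbind(X, dup = X[, "b"])
  perm <- c(4, 6, 1, 3, 5, 2)
  m1 <- merge_identical_features(X)
  m2 <- merge_identical_features(X[, perm])
  key <- function(m) apply(m, 2, paste, collapse = ",")
  expect_setequal(unname(key(m1)), unname(key(m2)))
})

test_that("IMF construction enumerates all non-empty subset products", {
  imf <- build_imf_features(bim_auc = 0.5, tp53_wt = 1, mdm2_wt = 1,
                            mgmt_negative = 0)
  expect_equal(ncol(imf), 15)
  expect_true(all(provenance(imf) == "IMF"))
  expect_equal(unname(imf[, "BIMAUC*TP53*MDM2"]), 0.5)
  expect_equal(unname(imf[, "BIMAUC*TP53*MDM2*MGMT"]), 0)
  expect_equal(unname(imf[, "TP53*MDM2"]), 1)
  # 2^k - 1 sizes for general k
  for (k in 1:5) {
    vars <- setNames(rep(list(c(0.2, 0.7)), k), paste0("v", seq_len(k)))
    expect_equal(ncol(interaction_products(vars)), 2^k - 1)
  }
  expect_error(build_imf_features(0.5, 1, 1), "required")
  expect_error(build_imf_features(0.5, 2, 1, 0), "binary")
})

test_that("GM construction merges blocks and drops constants", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4), g3 = c(9, 9, 9, 9),
                g4 = c(2, 1, 0, 5))
  colnames(expr) <- paste0("s", 1:4)
  mut <- rbind(m1 = c(0, 1, 0, 1), m2 = c(1, 1, 0, 0))
  colnames(mut) <- paste0("s", 1:4)
  gm <- build_gm_features(expression = expr, mutations = mut)
  expect_true(all(provenance(gm) == "GM"))
  expect_true("RNA:g1|RNA:g2" %in% colnames(gm))
  expect_false(any(grepl("g3", colnames(gm))))  # constant dropped
  expect_equal(ncol(gm), 4)  # g1|g2, g4, m1, m2
  # no duplicates, three genes + two mutations -> five features
  expr2 <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(0, 2, 0, 2))
  colnames(expr2) <- paste0("s", 1:4)
  expect_equal(ncol(build_gm_features(expression = expr2, mutations = mut)), 5)
  expect_error(build_gm_features(), "at least one")
  expect_error(build_gm_features(expression = expr[3, , drop = FALSE]),
               "non-constant")
})

test_that("optional GM interactions with molecular indicators are products only", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 1, 2, 8))
  colnames(expr) <- paste0("s", 1:4)
  gm <- build_gm_features(expression = expr,
                          interact_with = list(TP53 = c(1, 1, 0, 1)))
  expect_true("RNA:g1*TP53" %in% colnames(gm))
  expect_equal(unname(gm[, "RNA:g1*TP53"]), c(1, 2, 0, 4))
  # a zero-variance product (indicator all zero) is excluded
  gm0 <- build_gm_features(expression = expr,
                           interact_with = list(Z = c(0, 0, 0, 0)))
  expect_false(any(grepl("\\*Z$", colnames(gm0))))
})

test_that("response binarization is strict above the arm mean and shift-invariant", {
  expect_equal(unname(binarize_response(c(10, 20, 30))), c(0, 0, 1))
  expect_equal(unname(binarize_response(c(5, 5, 5))), c(0, 0, 0))
  expect_equal(unname(binarize_response(c(0, 0, 50, 50))), c(0, 0, 1, 1))
  set.seed(6)
  y <- runif(15, 0, 60)
  expect_identical(binarize_response(y), binarize_response(y + 7))
  expect_error(binarize_response(5), "at least 2")
})

test_that("pooling keeps provenance and rejects misaligned samples", {
  imf <- build_imf_features(c(a = .1, b = .9), c(1, 0), c(1, 1), c(0, 1),
                            sample_ids = c("a", "b"))
  gm <- feature_matrix(matrix(1:4, 2, 2, dimnames = list(c("a", "b"),
                                                         c("g1", "g2"))), "GM")
  pooled <- pool_features(imf, gm)
  expect_equal(ncol(pooled), 17)
  expect_equal(sum(provenance(pooled) == "IMF"), 15)
  bad <- gm[2:1, ]
  attr(bad, "provenance") <- provenance(gm)
  expect_error(pool_features(imf, bad), "same samples")
})
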