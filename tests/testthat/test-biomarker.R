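test_that("region AUC resolves separation, ties and matches pair counting", {
  perfect <- region_auc(c(3, 4, 5), c(1, 2))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$orientation, "case_high")
  allties <- region_auc(rep(2, 4), rep(2, 6))
  expect_equal(allties$auc, 0.5)
  set.seed(51)
  for (i in 1:50) {
    case <- sample(1:6, 7, TRUE)   # coarse grid forces ties
    control <- sample(1:6, 9, TRUE)
    got <- region_auc(case, control)
    expect_equal(got$auc, oracle_auc(case, control))
  }
})

test_that("region AUC is monotone-invariant and arm-swap symmetric", {
  set.seed(52)
  case <- rnorm(8); control <- rnorm(11)
  a <- region_auc(case, control)
  b <- region_auc(exp(case), exp(control))       # strictly monotone transform
  expect_equal(a$auc, b$auc)
  sw <- region_auc(control, case)
  expect_equal(sw$auc_raw, 1 - a$auc_raw, tolerance = 1e-12)
  expect_equal(sw$auc, a$auc)                    # oriented AUC is symmetric
  expect_error(region_auc(numeric(0), control), "non-empty")
})

test_that("biomarker selection applies all three thresholds strictly", {
  dmr <- data.frame(region_id = paste0("r", 1:4),
                    p_value = c(0.001, 0.001, 0.001, 0.5))
  auc <- data.frame(region_id = paste0("r", 1:4),
                    auc = c(0.66, 0.65, 0.80, 0.9))
  cpg <- setNames(c(5, 5, 4, 9), paste0("r", 1:4))
  out <- select_dmr_biomarkers(dmr, auc, cpg)
  expect_equal(out$region_id, "r1")  # r2 boundary AUC, r3 boundary CpG, r4 ns
  expect_equal(nrow(select_dmr_biomarkers(dmr[0, ], auc, cpg)), 0)
  expect_error(select_dmr_biomarkers(dmr, auc, cpg[-1]), "missing cpg_count")
})

test_that("biomarker selection equals a brute-force filter on random input", {
  set.seed(53)
  n <- 300
  dmr <- data.frame(region_id = paste0("r", 1:n), p_value = runif(n, 0, 0.05))
  auc <- data.frame(region_id = paste0("r", 1:n), auc = runif(n, 0.5, 1))
  cpg <- setNames(sample(0:12, n, TRUE), paste0("r", 1:n))
  out <- select_dmr_biomarkers(dmr, auc, cpg)
  manual <- sum(dmr$p_value < 0.01 & auc$auc > 0.65 & cpg > 4)
  expect_equal(nrow(out), manual)
})

test_that("contrast intersection follows the stated set algebra", {
  mk <- function(ids, aucs, cpg = 5)
    data.frame(region_id = ids, auc = aucs, cpg_count = cpg)
  A <- mk(c("r1", "r2"), c(.8, .7))
  B <- mk("r3", .9)
  C <- mk(c("r1", "r2", "r3", "r4"), c(.7, .8, .95, .99))
  panel <- intersect_contrasts(A, B, C)
  expect_setequal(panel$region_id[panel$class == "IIa_defining"], c("r1", "r2"))
  expect_equal(panel$region_id[panel$class == "IIb_defining"], "r3")
  expect_false("IIb_vs_IIa_top" %in% panel$class)   # triple intersection empty
  # disjoint inputs give an empty panel
  empty <- intersect_contrasts(mk("a", .7), mk("b", .7), mk("c", .7))
  expect_equal(nrow(empty), 0)
  # a triple-intersection member becomes the top marker by AUC
  A2 <- mk(c("r1", "r5"), c(.8, .7)); B2 <- mk(c("r3", "r5"), c(.9, .7))
  C2 <- mk(c("r1", "r3", "r5"), c(.7, .95, .85))
  panel2 <- intersect_contrasts(A2, B2, C2)
  expect_equal(panel2$region_id[panel2$class == "IIb_vs_IIa_top"], "r5")
  expect_equal(panel2$region_id[panel2$class == "IIa_defining"], "r1")
  expect_equal(panel2$region_id[panel2$class == "IIb_defining"], "r3")
  # classes are mutually exclusive
  expect_equal(anyDuplicated(panel2$region_id), 0)
})

test_that("intersection ties break by CpG count then region id", {
  mk <- function(ids, aucs, cpg) data.frame(region_id = ids, auc = aucs,
                                            cpg_count = cpg)
  shared <- c("rA", "rB")
  A <- mk(shared, c(.7, .7), c(5, 5)); B <- mk(shared, c(.7, .7), c(5, 5))
  C <- mk(shared, c(.9, .9), c(5, 9))
  expect_equal(
    intersect_contrasts(A, B, C)$region_id, "rB")  # higher cpg wins
  C2 <- mk(shared, c(.9, .9), c(5, 5))
  expect_equal(
    intersect_contrasts(A, B, C2)$region_id, "rA")  # lexicographic
})

test_that("stepwise AIC keeps true covariates and prunes pure noise", {
  set.seed(54)
  n <- 200
  cov <- data.frame(age = rnorm(n), gender = rbinom(n, 1, 0.5),
                    onset = rnorm(n), duration = rnorm(n))
  y <- rbinom(n, 1, plogis(cov$age + cov$gender))
  m <- stepwise_aic_logistic(y, cov)
  expect_true(all(c("age", "gender") %in% m$selected_covariates))
  # all-noise covariates: intercept-only model in the majority of replicates
  set.seed(55)
  noise_only <- replicate(20, {
    covn <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    yn <- rbinom(n, 1, 0.5)
    length(stepwise_aic_logistic(yn, covn)$selected_covariates) == 0
  })
  expect_gt(mean(noise_only), 0.5)
  # empty scope: intercept-only with AIC = null deviance + 2
  m0 <- stepwise_aic_logistic(y, cov, scope = character())
  expect_equal(length(m0$selected_covariates), 0)
  expect_equal(m0$aic, m0$model$deviance + 2, tolerance = 1e-8)
})

test_that("separated outcomes are handled with the ridge fallback", {
  cov <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c(0, 1), each = 20)
  expect_warning(m <- stepwise_aic_logistic(y, cov), "separation")
  expect_true(all(is.finite(m$coefficients)))
  expect_equal(m$selected_covariates, "x")
})

test_that("combinatorial enumeration has the exact closed-form size", {
  set.seed(56)
  X <- matrix(rnorm(16 * 13), 16, 13,
              dimnames = list(NULL, paste0("m", 1:13)))
  y <- rep(c(0, 1), each = 8)
  cf <- rnorm(16)
  combos <- combinatorial_roc(X, y, clinical_score = cf, max_subset_size = 3)
  expect_equal(nrow(combos), 754)  # 2 * (13 + 78 + 286)
  expect_equal(sum(combos$includes_clinical), 377)
  # without a clinical score, half the enumeration
  combos2 <- combinatorial_roc(X, y, max_subset_size = 3)
  expect_equal(nrow(combos2), 377)
  expect_error(
    combinatorial_roc(X, y, max_subset_size = 13, enumeration_cap = 100),
    "lower max_subset_size")
})

test_that("a feature identical to the outcome dominates the ranking", {
  set.seed(57)
  X <- cbind(perfect = rep(c(0, 1), each = 6), noise = rnorm(12))
  y <- rep(c(0, 1), each = 6)
  combos <- combinatorial_roc(X, y, max_subset_size = 2)
  expect_equal(combos$auc[1], 1)
  expect_true(grepl("perfect", combos$features[1]))
  expect_equal(combos$accuracy[1], 1)
})

test_that("ranking is reproduced by an independent re-scoring pass", {
  set.seed(58)
  n <- 20
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, plogis(X[, 1]))
  combos <- combinatorial_roc(X, y, max_subset_size = 2)
  # recompute each combination's AUC from scratch with glm + oracle AUC
  for (i in seq_len(nrow(combos))) {
    feats <- strsplit(combos$features[i], "+", fixed = TRUE)[[1]]
    d <- data.frame(y = y, X[, feats, drop = FALSE])
    sc <- as.numeric(predict(suppressWarnings(
      glm(y ~ ., data = d, family = binomial()))))
    expect_equal(combos$auc[i], oracle_auc(sc[y == 1], sc[y == 0]),
                 tolerance = 1e-10)
  }
  expect_true(all(diff(combos$auc) <= 1e-12))
})

test_that("permutation p-values are smoothed, bounded and calibrated", {
  set.seed(59)
  score <- c(rnorm(8, 3), rnorm(8, 0))
  y <- rep(c(1, 0), each = 8)
  res <- bootstrap_auc_pvalue(score, y, n_boot = 999, seed = 60)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$p_value, 0)
  expect_error(bootstrap_auc_pvalue(score, y, n_boot = 0), "at least 200")
  expect_error(bootstrap_auc_pvalue(score, rep(1, 16), n_boot = 500),
               "both classes")
  # null scores give dispersed p-values (no mass collapse onto 0 or 1)
  ps <- vapply(1:40, function(i) {
    s <- rnorm(16)
    bootstrap_auc_pvalue(s, y, n_boot = 249, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.2), 0.4)
  expect_true(all(ps > 0 & ps <= 1))
})
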