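# small helper: pure NB cohort with no nuisance covariate effects
nb_cohort <- function(n_a, n_b, n_regions, effect = 0, phi = 0.2, seed = 1,
                      n_dmr = 0, contrast = "IIb_vs_IIa") {
  cfg <- sim_config(n_subjects_per_group = c(IIa = n_a, IIb = n_b),
                    paired_fraction = 0, n_regions = n_regions,
                    n_marker_regions = 0, n_dmr_per_contrast = n_dmr,
                    dmr_log2_effect = effect, truth_contrasts = contrast,
                    dispersion = phi,
                    covariate_sd = c(tissue = 0, gender = 0, age = 0,
                                     combined_risk = 0))
  sam <- simulate_cohort(cfg, seed = seed)
  sc <- simulate_counts(sam, cfg, seed = seed)
  sc$samples$library_size <- sc$library_sizes
  sc
}

test_that("design construction subsets arms, standardizes and drops aliases", {
  sam <- simulate_cohort(sim_config(), seed = 41)
  sam$library_size <- 1e4
  des <- build_design(sam, list(case = "IIb", control = "IIa"))
  expect_equal(nrow(des$X), 16)  # 4 + 4 subjects, both tissues
  expect_equal(sum(des$group), 8)
  expect_equal(qr(des$X)$rank, ncol(des$X))
  expect_true("group" %in% colnames(des$X))
  expect_false("group" %in% colnames(des$X0))
  # an all-male subset aliases the gender column away
  sam2 <- sam
  sam2$gender <- "M"
  des2 <- build_design(sam2, list(case = "IIb", control = "IIa"))
  expect_false(any(grepl("gender", colnames(des2$X))))
  expect_true(any(grepl("constant:gender", des2$dropped)))
  expect_equal(qr(des2$X)$rank, ncol(des2$X))
})

test_that("contrasts with overlapping or empty arms are rejected", {
  sam <- simulate_cohort(sim_config(), seed = 42)
  sam$library_size <- 1e4
  expect_error(build_design(sam, list(case = "IIa", control = "IIa")),
               "overlap")
  expect_error(build_design(sam, list(case = character(), control = "IIa")),
               "non-empty")
  expect_error(
    build_design(sam[sam$classification != "IIb", ],
                 list(case = "IIb", control = "IIa")),
    "empty contrast arm")
})

test_that("NB GLM recovers group means and respects offsets", {
  X <- cbind("(Intercept)" = rep(1, 40), group = rep(c(0, 1), each = 20))
  set.seed(43)
  # null symmetry
  y0 <- rpois(40, 10)
  f0 <- fit_nbglm(y0, X, rep(0, 40), 0)
  expect_lt(abs(f0$coefficients[["group"]] / log(2)), 0.35)
  # closed-form group ratio at large counts
  y <- c(rpois(20, 1000), rpois(20, 4000))
  f <- fit_nbglm(y, X, rep(0, 40), 0)
  expect_equal(f$coefficients[["group"]] / log(2), 2, tolerance = 0.05)
  expect_true(f$converged)
  # doubling one sample's offset and its counts leaves coefficients unchanged
  off2 <- rep(0, 40); off2[1] <- log(2)
  y2 <- y; y2[1] <- y[1] * 2L
  f2 <- fit_nbglm(y2, X, off2, 0)
  expect_equal(f2$coefficients, f$coefficients, tolerance = 1e-3)
  # all-zero rows are flagged
  fz <- fit_nbglm(rep(0L, 40), X, rep(0, 40), 0.1)
  expect_true(fz$flagged)
})

test_that("dispersion estimation tracks the generative dispersion", {
  sc <- nb_cohort(8, 8, 120, phi = 0.2, seed = 44)
  des <- build_design(sc$samples, list(case = "IIb", control = "IIa"),
                      covariates = character())
  disp <- estimate_dispersions(sc$counts, des)
  expect_true(disp$common > 0.1 && disp$common < 0.3)
  expect_true(all(disp$tagwise_shrunk > 0, na.rm = TRUE))
  # Poisson data drives the estimates to the boundary
  scp <- nb_cohort(8, 8, 80, phi = 1e-8, seed = 45)
  desp <- build_design(scp$samples, list(case = "IIb", control = "IIa"),
                       covariates = character())
  dispp <- estimate_dispersions(scp$counts, desp)
  expect_lt(median(dispp$tagwise, na.rm = TRUE), 0.01)
  # a single region shrinks onto itself: tagwise equals common
  one <- subset_counts(scp$counts, 1)
  d1 <- estimate_dispersions(one, desp)
  expect_equal(d1$tagwise_shrunk[1], d1$common, tolerance = 1e-6)
})

test_that("likelihood-ratio test has the stated degenerate behaviour", {
  X <- cbind("(Intercept)" = rep(1, 10), group = rep(c(0, 1), each = 5))
  y <- rep(7L, 10)
  ff <- fit_nbglm(y, X, rep(0, 10), 0.1)
  fr <- fit_nbglm(y, X[, 1, drop = FALSE], rep(0, 10), 0.1)
  res <- test_contrast(ff, fr)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  # non-nested designs are rejected
  Xb <- X; colnames(Xb) <- c("(Intercept)", "other")
  fb <- fit_nbglm(y, Xb, rep(0, 10), 0.1)
  expect_error(test_contrast(fb, fr), "reduced model")
})

test_that("null p-values are calibrated and approximately uniform", {
  sc <- nb_cohort(8, 8, 600, phi = 0.2, seed = 46)
  tbl <- run_all_contrasts(sc$counts, sc$samples,
                           contrasts = list(IIb_vs_IIa = list(case = "IIb",
                                                              control = "IIa")),
                           covariates = character())
  frac <- mean(tbl$p_value < 0.01, na.rm = TRUE)
  expect_gte(frac, 0.001)
  expect_lte(frac, 0.03)
  ks <- suppressWarnings(ks.test(tbl$p_value, "punif")$statistic)
  expect_lt(unname(ks), 0.06)
})

test_that("injected effects are recovered with correct direction", {
  sc <- nb_cohort(10, 10, 300, effect = 2, phi = 0.1, seed = 47, n_dmr = 60)
  tbl <- run_all_contrasts(sc$counts, sc$samples,
                           contrasts = list(IIb_vs_IIa = list(case = "IIb",
                                                              control = "IIa")),
                           covariates = character())
  truth <- sc$truth
  idx <- match(truth$region_id, tbl$region_id)
  is_dmr <- truth$label == "IIb_vs_IIa"
  est <- tbl$log2_fold_change[idx][is_dmr] * truth$direction[is_dmr]
  expect_lt(abs(mean(est) - 2), 0.15)
  detected <- is_dmr & tbl$p_value[idx] < 0.01
  expect_gt(mean(detected[is_dmr]), 0.8)  # power at this effect size
  agree <- sign(tbl$log2_fold_change[idx][detected]) ==
    truth$direction[detected]
  expect_gt(mean(agree), 0.95)
  # direction always matches the sign of the fold change
  ok <- !tbl$flagged
  expect_true(all((tbl$direction[ok] == "increased") ==
                    (tbl$log2_fold_change[ok] > 0)))
  # increased + reduced = total DMRs at the threshold
  dc <- dmr_counts(tbl)
  expect_equal(dc$increased + dc$reduced, dc$total)
})

test_that("contrasts missing from the cohort are skipped with a warning", {
  sc <- nb_cohort(5, 5, 30, seed = 48)
  expect_warning(
    tbl <- run_all_contrasts(sc$counts, sc$samples,
                             contrasts = list(
                               IIb_vs_IIa = list(case = "IIb", control = "IIa"),
                               IIIa_vs_IIId = list(case = "IIIa", control = "IIId")),
                             covariates = character(), dispersion = 0.2),
    "skipping contrast IIIa_vs_IIId")
  expect_equal(unique(tbl$contrast), "IIb_vs_IIa")
})

test_that("fold changes agree with an independent edgeR fit", {
  skip_if_not_installed("edgeR")
  sc <- nb_cohort(8, 8, 150, effect = 1.5, phi = 0.15, seed = 49, n_dmr = 40)
  tbl <- run_all_contrasts(sc$counts, sc$samples,
                           contrasts = list(IIb_vs_IIa = list(case = "IIb",
                                                              control = "IIa")),
                           covariates = character())
  grp <- sc$samples$classification == "IIb"
  dge <- edgeR::DGEList(counts = sc$counts$methyl,
                        lib.size = sc$samples$library_size *
                          sc$samples$spike_enrichment_ratio)
  design <- model.matrix(~grp)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  r <- cor(tbl$log2_fold_change, lrt$table$logFC)
  expect_gt(r, 0.98)
  expect_equal(tbl$log2_fold_change, lrt$table$logFC, tolerance = 0.1)
  # significance calls largely agree
  both <- table(ours = tbl$p_value < 0.01, edger = lrt$table$PValue < 0.01)
  expect_gt(sum(diag(both)) / sum(both), 0.9)
})
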