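# Canned verification experiments.
#
# Each function runs one of the package's standard simulation studies under
# a caller-supplied seed and returns the measured quantities. The tests and
# the acceptance script call these rather than re-scripting the designs.

#' Type-I error calibration of the DMR caller
#'
#' Pure negative-binomial null (no DMRs, no nuisance covariate structure),
#' two arms of 8 samples, dispersion 0.2. Reports the fraction of regions
#' called at p < 0.01 and the Kolmogorov-Smirnov distance of the p-values
#' from uniform.
#'
#' @param n_regions number of null regions (default 2000).
#' @param seed integer seed.
#' @return List: `fraction_p01`, `ks_distance`, `n_regions`.
#' @export
null_calibration_experiment <- function(n_regions = 2000, seed = 1) {
  cfg <- sim_config(n_subjects_per_group = c(IIa = 8, IIb = 8),
                    paired_fraction = 0, n_regions = n_regions,
                    n_marker_regions = 0, n_dmr_per_contrast = 0,
                    dmr_log2_effect = 0, dispersion = 0.2,
                    covariate_sd = c(tissue = 0, gender = 0, age = 0,
                                     combined_risk = 0))
  sam <- simulate_cohort(cfg, seed = seed)
  sc <- simulate_counts(sam, cfg, seed = seed)
  sc$samples$library_size <- sc$library_sizes
  tbl <- run_all_contrasts(sc$counts, sc$samples,
                           contrasts = list(IIb_vs_IIa = list(case = "IIb",
                                                              control = "IIa")),
                           covariates = character())
  p <- tbl$p_value[!tbl$flagged]
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  list(fraction_p01 = mean(p < 0.01), ks_distance = unname(ks),
       n_regions = length(p))
}

#' Recovery of an injected differential-methylation effect
#'
#' Two arms of 20 samples, 200 truth DMRs at log2 effect 2, dispersion 0.2.
#' Reports the bias of the estimated log2 fold change over truth DMRs, the
#' power at p < 0.01, and the direction agreement among detected DMRs.
#'
#' @param n_regions total regions (default 1000, of which 200 are DMRs).
#' @param effect injected log2 effect (default 2).
#' @param n_per_arm samples per arm (default 20).
#' @param seed integer seed.
#' @return List: `bias`, `power`, `direction_agreement`, `mean_abs_l2fc_error`.
#' @export
effect_recovery_experiment <- function(n_regions = 1000, effect = 2,
                                       n_per_arm = 20, seed = 1) {
  cfg <- sim_config(n_subjects_per_group = c(IIa = n_per_arm, IIb = n_per_arm),
                    paired_fraction = 0, n_regions = n_regions,
                    n_marker_regions = 0, n_dmr_per_contrast = 200,
                    dmr_log2_effect = effect, truth_contrasts = "IIb_vs_IIa",
                    dispersion = 0.2,
                    covariate_sd = c(tissue = 0, gender = 0, age = 0,
                                     combined_risk = 0))
  sam <- simulate_cohort(cfg, seed = seed)
  sc <- simulate_counts(sam, cfg, seed = seed)
  sc$samples$library_size <- sc$library_sizes
  tbl <- run_all_contrasts(sc$counts, sc$samples,
                           contrasts = list(IIb_vs_IIa = list(case = "IIb",
                                                              control = "IIa")),
                           covariates = character())
  truth <- sc$truth
  idx <- match(truth$region_id, tbl$region_id)
  is_dmr <- truth$label == "IIb_vs_IIa"
  est <- tbl$log2_fold_change[idx][is_dmr] * truth$direction[is_dmr]
  detected <- is_dmr & !is.na(tbl$p_value[idx]) & tbl$p_value[idx] < 0.01
  agree <- sign(tbl$log2_fold_change[idx][detected]) == truth$direction[detected]
  list(bias = mean(est) - effect,
       power = mean(detected[is_dmr]),
       direction_agreement = mean(agree),
       mean_abs_l2fc_error = mean(abs(est - effect)))
}

#' Cell-proportion recovery under noise
#'
#' 50 markers, 3 cell types, 100 simulated mixtures, additive Gaussian noise
#' of sd `noise_sd` on the marker signal.
#'
#' @param n_markers,n_samples,noise_sd experiment dimensions.
#' @param seed integer seed.
#' @return List: `mean_absolute_error`, `max_absolute_error`.
#' @export
deconvolution_recovery_experiment <- function(n_markers = 50, n_samples = 100,
                                              noise_sd = 0.05, seed = 1) {
  with_seed(seed, {
    P <- matrix(runif(n_markers * 3, 0, 10), n_markers, 3)
    ref <- cell_type_reference(P)
    W0 <- t(sapply(seq_len(n_samples), function(i) {
      g <- rgamma(3, c(2, 5, 3)); g / sum(g)
    }))
    Y <- P %*% t(W0) + matrix(rnorm(n_markers * n_samples, 0, noise_sd),
                              n_markers, n_samples)
    colnames(Y) <- paste0("s", seq_len(n_samples))
    est <- estimate_proportions_matrix(Y, ref)
    err <- abs(as.matrix(est[, ref$cell_types]) - W0)
    list(mean_absolute_error = mean(err), max_absolute_error = max(err))
  })
}

#' End-to-end biomarker panel logic on planted subtype effects
#'
#' Simulates a cohort of FCD IIa, FCD IIb and other-pathology subjects with
#' four planted region classes: IIa-only effects, IIb-only effects, shared
#' type-II effects (equal in IIa and IIb), and graded type-II effects
#' (stronger in IIb). Runs the three panel contrasts, per-region ROC, the
#' AUC/CpG selection and the contrast intersection, then compares panel
#' classes to the planted truth. Every region carries an effect; null-region
#' calibration is a separate experiment.
#'
#' @param n_per_arm subjects per group (default 10).
#' @param n_per_class planted regions per class (default 50).
#' @param effect log2 effect (default 2.5); graded regions get `effect` in
#'   IIa and `2 * effect` in IIb.
#' @param seed integer seed.
#' @return List with the panel, the truth, and the comparison summary:
#'   `iia_exact`, `iib_exact` (defining classes equal the planted sets),
#'   `top_in_graded`, `misassigned` (count of regions in a wrong class).
#' @export
panel_logic_experiment <- function(n_per_arm = 10, n_per_class = 50,
                                   effect = 2.5, seed = 1) {
  cfg <- sim_config(
    n_subjects_per_group = c(IIa = n_per_arm, IIb = n_per_arm,
                             nonMCD = n_per_arm),
    paired_fraction = 0,
    n_regions = 3 * n_per_class + max(10, n_per_class %/% 2),
    n_marker_regions = 0, n_dmr_per_contrast = n_per_class,
    dmr_log2_effect = effect,
    truth_contrasts = c("IIa_vs_others", "IIb_vs_others",
                        "FCDII_vs_otherFCD"),
    n_graded_regions = max(10, n_per_class %/% 2),
    dispersion = 0.1,
    covariate_sd = c(tissue = 0, gender = 0, age = 0, combined_risk = 0))
  sam <- simulate_cohort(cfg, seed = seed)
  sc <- simulate_counts(sam, cfg, seed = seed)
  sc$samples$library_size <- sc$library_sizes
  contrasts <- list(
    IIa_vs_others = list(case = "IIa", control = OTHER_CLASSES),
    IIb_vs_others = list(case = "IIb", control = OTHER_CLASSES),
    IIb_vs_IIa = list(case = "IIb", control = "IIa"))
  tbl <- run_all_contrasts(sc$counts, sc$samples, contrasts = contrasts,
                           covariates = character())
  norm <- logcpm(sc$counts, sc$samples, library_sizes = sc$library_sizes)
  cpg <- setNames(rep(10L, nrow(sc$truth)), sc$truth$region_id)
  panels <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    keep <- sc$samples$classification %in% c(ct$case, ct$control)
    auc <- region_auc_matrix(norm$values[, keep, drop = FALSE],
                             sc$samples$classification[keep] %in% ct$case)
    select_dmr_biomarkers(tbl[tbl$contrast == nm, ], auc, cpg)
  })
  panel <- intersect_contrasts(panels[[1]], panels[[2]], panels[[3]])
  truth <- sc$truth
  sets <- split(truth$region_id, truth$label)
  iia_def <- panel$region_id[panel$class == "IIa_defining"]
  iib_def <- panel$region_id[panel$class == "IIb_defining"]
  top <- panel$region_id[panel$class == "IIb_vs_IIa_top"]
  misassigned <- sum(!iia_def %in% sets[["IIa_vs_others"]]) +
    sum(!iib_def %in% sets[["IIb_vs_others"]]) +
    sum(!top %in% sets[["graded_II"]])
  names(panels) <- names(contrasts)
  list(panel = panel, truth = truth, selections = panels,
       iia_exact = setequal(iia_def, sets[["IIa_vs_others"]]),
       iib_exact = setequal(iib_def, sets[["IIb_vs_others"]]),
       top_in_graded = length(top) == 1 && top %in% sets[["graded_II"]],
       misassigned = misassigned)
}

#' Methyl-qPCR round-trip recovery
#'
#' Simulates plates at true percent methylation 20/50/80 with Ct noise sd
#' 0.1 and recovers the percentages through the analysis pipeline.
#'
#' @param n_samples samples per truth level (default 12).
#' @param noise_sd per-well Ct noise (default 0.1).
#' @param seed integer seed.
#' @return List: `mean_abs_error`, `max_abs_error_by_level` (named by truth).
#' @export
qpcr_roundtrip_experiment <- function(n_samples = 12, noise_sd = 0.1, seed = 1) {
  sam <- data.frame(sample_id = sprintf("q%02d", seq_len(n_samples)),
                    tissue = "brain", classification = "IIa")
  levels <- c(20, 50, 80)
  truth <- matrix(rep(levels, each = n_samples), n_samples, 3)
  plate <- simulate_qpcr(paste0("target_", levels), sam, truth,
                         noise_sd = noise_sd, seed = seed)
  pct <- percent_methylation_table(plate)
  errs <- vapply(seq_along(levels), function(j) {
    est <- pct$percent[pct$target == paste0("target_", levels[j])]
    mean(abs(est - levels[j]))
  }, numeric(1))
  names(errs) <- levels
  list(mean_abs_error = mean(errs), mean_abs_error_by_level = errs)
}

#' Stepwise-AIC selection consistency
#'
#' Replicated logistic simulations where the outcome is driven by age and
#' gender (coefficients 1.0) while onset age, disease duration, prior
#' surgery and combined risk are pure noise. Reports how often the stepwise
#' search keeps exactly the true covariates, and how often it keeps at least
#' them.
#'
#' @param n_replicates number of replicates (default 100).
#' @param n samples per replicate (default 200).
#' @param seed integer seed.
#' @return List: `exact_rate`, `inclusion_rate`, `mean_selected`.
#' @export
stepwise_selection_experiment <- function(n_replicates = 100, n = 200,
                                          seed = 1) {
  with_seed(seed, {
    res <- vapply(seq_len(n_replicates), function(i) {
      cov <- data.frame(age = rnorm(n), gender = rbinom(n, 1, 0.5),
                        onset = rnorm(n), duration = rnorm(n),
                        prior_surgery = rbinom(n, 1, 0.3),
                        combined_risk = rbinom(n, 1, 0.3))
      y <- rbinom(n, 1, stats::plogis(cov$age + cov$gender))
      sel <- stepwise_aic_logistic(y, cov)$selected_covariates
      c(exact = setequal(sel, c("age", "gender")),
        incl = all(c("age", "gender") %in% sel),
        k = length(sel))
    }, numeric(3))
    list(exact_rate = mean(res["exact", ]),
         inclusion_rate = mean(res["incl", ]),
         mean_selected = mean(res["k", ]))
  })
}
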