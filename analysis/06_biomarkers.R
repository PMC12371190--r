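#!/usr/bin/env Rscript
# Stage 6: ROC-based biomarker panel and combinatorial classification.
#
# Per-region AUCs for the three subtype contrasts, AUC/CpG selection of
# biomarker candidates, the three-way intersection into IIa-defining,
# IIb-defining and top IIb-vs-IIa markers, a stepwise-AIC clinical-factor
# model, and combinatorial ROC ranking of marker subsets with and without
# the clinical score.

library(fcdmeth)

SEED <- 20260923 %% 100000
out <- "results/synthetic"
cfgp <- fcd_config()
sam <- read_sample_sheet(file.path(out, "sample_sheet.csv"))
cm <- read_counts(file.path(out, "methyl_counts.tsv"))
lib <- read.delim(file.path(out, "library_sizes.tsv"))
library_sizes <- setNames(lib$library_size, lib$sample_id)[cm$samples]
ann <- read.delim(file.path(out, "consensus_annotated.tsv"))
tbl <- read.delim(file.path(out, "dmr_table.tsv"))

norm <- logcpm(cm, sam, use_spike = TRUE, library_sizes = library_sizes)
# CpG counts for the simulated regions against the stage-2 reference
cpg <- setNames(count_cpg(cm$regions, file.path(out, "reference.fa")),
                cm$regions$region_id)

contrasts <- list(
  IIa_vs_others = list(case = "IIa", control = c("mMCD", "MOGHE", "PMG", "nonMCD")),
  IIb_vs_others = list(case = "IIb", control = c("mMCD", "MOGHE", "PMG", "nonMCD")),
  IIb_vs_IIa = list(case = "IIb", control = "IIa"))
panels <- lapply(names(contrasts), function(nm) {
  ct <- contrasts[[nm]]
  keep <- sam$classification %in% c(ct$case, ct$control)
  auc <- region_auc_matrix(norm$values[, keep, drop = FALSE],
                           sam$classification[keep] %in% ct$case)
  sel <- select_dmr_biomarkers(tbl[tbl$contrast == nm, ], auc, cpg,
                               auc_min = cfgp$auc_min, cpg_min = cfgp$cpg_min,
                               p_max = cfgp$dmr_p_max)
  cat(nm, ": ", nrow(sel), " candidates past AUC >", cfgp$auc_min,
      ", CpG >", cfgp$cpg_min, ", p <", cfgp$dmr_p_max, "\n")
  sel
})
panel <- intersect_contrasts(panels[[1]], panels[[2]], panels[[3]])
panel$nearest_gene <- ann$nearest_gene[match(panel$region_id,
                                             cm$regions$region_id)]
write.table(panel, file.path(out, "biomarker_panel.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nPanel:", sum(panel$class == "IIa_defining"), "IIa-defining,",
    sum(panel$class == "IIb_defining"), "IIb-defining,",
    sum(panel$class == "IIb_vs_IIa_top"), "top IIb-vs-IIa marker(s)\n")

## clinical-factor model (IIb vs IIa subjects, brain rows)
sub <- sam[sam$classification %in% c("IIa", "IIb") & sam$tissue == "brain", ]
covs <- data.frame(age = sub$age_years, gender = as.numeric(sub$gender == "M"),
                   onset = sub$onset_age_years, duration = sub$duration_years,
                   combined_risk = as.numeric(sub$combined_risk))
covs[] <- lapply(covs, function(x) ifelse(is.na(x), median(x, na.rm = TRUE), x))
y <- as.numeric(sub$classification == "IIb")
cf <- suppressWarnings(stepwise_aic_logistic(y, covs))
cat("\nClinical-factor model keeps:",
    if (length(cf$selected_covariates)) paste(cf$selected_covariates,
                                              collapse = ", ")
    else "(intercept only)", " AIC:", round(cf$aic, 1), "\n")
cf_roc <- region_auc(cf$linear_predictor[y == 1], cf$linear_predictor[y == 0])
cat("Clinical-factor AUC for IIb vs IIa:", round(cf_roc$auc, 2), "\n")

## combinatorial ROC over the top panel markers (both subject tissues)
top_ids <- head(panel$region_id[order(-panel$auc_IIb_vs_IIa)], 8)
keep <- sam$classification %in% c("IIa", "IIb") & sam$tissue == "brain"
X <- t(norm$values[top_ids, keep, drop = FALSE])
yk <- as.numeric(sam$classification[keep] == "IIb")
combos <- combinatorial_roc(X, yk, clinical_score = cf$linear_predictor,
                            max_subset_size = 3)
write.table(combos, file.path(out, "combinatorial_roc.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nCombinatorial ROC:", nrow(combos), "combinations of", ncol(X),
    "markers (subset size <= 3, with/without clinical score)\n")
best <- combos[1, ]
cat("Best combination:", best$features,
    if (best$includes_clinical) "+ clinical score" else "",
    " AUC", round(best$auc, 3), " accuracy", round(best$accuracy, 3), "\n")
score <- fcdmeth:::fit_combo_score(
  cbind(X[, strsplit(best$features, "+", fixed = TRUE)[[1]], drop = FALSE],
        if (best$includes_clinical) cf$linear_predictor else NULL), yk)
bp <- bootstrap_auc_pvalue(score, yk, n_boot = 999, seed = SEED)
cat("Permutation p for the best combination:", signif(bp$p_value, 3), "\n")
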