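#!/usr/bin/env Rscript
# Stage 3: normalization, PCA and covariate diagnostics.
#
# Places counts on the spike-adjusted log2-CPM scale, asks which clinical
# covariates drive the leading principal components, and shows that
# residualizing the nuisance covariates removes the tissue axis -- the
# rationale for covariate adjustment in the differential model.

library(fcdmeth)

out <- "results/synthetic"
sam <- read_sample_sheet(file.path(out, "sample_sheet.csv"))
cm <- read_counts(file.path(out, "methyl_counts.tsv"),
                  sample_ids = sam$sample_id)
lib <- read.delim(file.path(out, "library_sizes.tsv"))
library_sizes <- setNames(lib$library_size, lib$sample_id)[cm$samples]

norm <- logcpm(cm, sam, use_spike = TRUE, library_sizes = library_sizes)
p <- meth_pca(norm, n_components = 6)
covs <- data.frame(tissue = sam$tissue, classification = sam$classification,
                   gender = sam$gender, age = sam$age_years,
                   duration = sam$duration_years,
                   combined_risk = sam$combined_risk)
assoc <- pc_covariate_correlation(p, covs, n_pcs = 6)

write.table(cbind(sample_id = rownames(p$scores), as.data.frame(p$scores)),
            file.path(out, "pca_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cbind(covariate = rownames(assoc), round(as.data.frame(assoc), 4)),
            file.path(out, "pc_covariate_association.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Variance captured by PC1-6 (%):",
    paste(round(100 * p$variance_fraction, 1), collapse = ", "), "\n")
cat("PC1 associations:\n")
print(round(assoc[, "PC1"], 3))

adj <- residualize(norm, data.frame(tissue = sam$tissue,
                                    gender = sam$gender,
                                    age = ifelse(is.na(sam$age_years), 0,
                                                 sam$age_years)))
p_adj <- meth_pca(adj, n_components = 6)
assoc_adj <- pc_covariate_correlation(p_adj, covs, n_pcs = 6)
cat("\nAfter residualizing tissue/gender/age, PC1 tissue association drops",
    sprintf("from %.3f to %.3f\n", assoc["tissue", "PC1"],
            assoc_adj["tissue", "PC1"]))
write.table(cbind(covariate = rownames(assoc_adj),
                  round(as.data.frame(assoc_adj), 4)),
            file.path(out, "pc_covariate_association_adjusted.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
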