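#!/usr/bin/env Rscript
# Stage 1: generate the synthetic discovery cohort.
#
# Mirrors the discovery study design (21 subjects across five FCD subtypes
# and four other pathologies, paired brain/blood) and writes a
# self-contained data directory: sample sheet, per-sample peak calls,
# methyl/input count matrices and the ground-truth region labels that later
# stages are scored against.

library(fcdmeth)

SEED <- 20260923 %% 100000
out <- "results/synthetic"
dir.create(file.path(out, "peaks"), recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_regions = 600, n_dmr_per_contrast = 60)
sam <- simulate_cohort(cfg, seed = SEED)
write_sample_sheet(sam, file.path(out, "sample_sheet.csv"))

pk <- simulate_peak_calls(sam, cfg, seed = SEED + 1)
for (sid in names(pk$calls))
  write_intervals(pk$calls[[sid]][, c("chrom", "start", "end",
                                      "fold_enrichment", "p_value")],
                  file.path(out, "peaks", paste0(sid, ".bed")))
write_intervals(pk$regions, file.path(out, "true_regions.bed"))

sc <- simulate_counts(sam, cfg, seed = SEED + 2)
write_counts(sc$counts, file.path(out, "methyl_counts.tsv"),
             file.path(out, "input_counts.tsv"))
write.table(sc$truth, file.path(out, "truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(sample_id = names(sc$library_sizes),
                       library_size = sc$library_sizes),
            file.path(out, "library_sizes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cbind(marker = rownames(sc$cell_reference), sc$cell_reference),
            file.path(out, "cell_reference.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cbind(sample_id = rownames(sc$cell_proportions_truth),
                  sc$cell_proportions_truth),
            file.path(out, "cell_proportions_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cs <- cohort_summary(sam)
print(cs)
cat("\nWrote", nrow(sam), "samples,", nrow(sc$counts$methyl), "regions, and",
    length(pk$calls), "peak files to", out, "\n")
cat("Truth:", sum(sc$truth$label != "null" & sc$truth$label != "marker"),
    "DMR regions across", length(cfg$truth_contrasts), "contrasts;",
    sum(sc$truth$label == "marker"), "leukocyte marker regions\n")
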