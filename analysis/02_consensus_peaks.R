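#!/usr/bin/env Rscript
# Stage 2: consensus methylated regions from per-sample peak calls.
#
# Filters each sample's calls (fold enrichment > 4, p < 0.01), fragments the
# genome at all peak breakpoints, keeps fragments supported by more than two
# samples, merges and blacklist-filters them, and annotates the survivors
# with CpG counts, genomic features and nearest genes against a small
# synthetic reference.

library(fcdmeth)

SEED <- 20260923 %% 100000
out <- "results/synthetic"
cfg <- fcd_config()

peak_files <- list.files(file.path(out, "peaks"), full.names = TRUE)
calls <- lapply(peak_files, read_intervals,
                col_names = c("fold_enrichment", "p_value"))
names(calls) <- sub("\\.bed$", "", basename(peak_files))
n_raw <- sum(vapply(calls, nrow, integer(1)))

filt <- lapply(calls, filter_peak_calls,
               fe_min = cfg$fold_enrichment_min, p_max = cfg$peak_p_max)
n_filt <- sum(vapply(filt, nrow, integer(1)))

# a decoy blacklist region over the first true region
truth_regions <- read_intervals(file.path(out, "true_regions.bed"))
blacklist <- truth_regions[1, c("chrom", "start", "end")]

cons <- build_consensus(filt, blacklist = blacklist,
                        min_support = cfg$min_support_samples)

# synthetic reference sequence and gene models spanning every region this
# pipeline touches (consensus fragments and the count-matrix regions)
set.seed(SEED)
count_regions <- read_counts(file.path(out, "methyl_counts.tsv"))$regions
chroms <- union(unique(cons$chrom), unique(count_regions$chrom))
fa_path <- file.path(out, "reference.fa")
con <- file(fa_path, "w")
gene_rows <- list()
for (ch in chroms) {
  L <- max(c(cons$end[cons$chrom == ch],
             truth_regions$end[truth_regions$chrom == ch],
             count_regions$end[count_regions$chrom == ch])) + 1000
  writeLines(paste0(">", ch), con)
  writeLines(paste(sample(c("A", "C", "G", "T"), L, TRUE,
                          prob = c(.27, .23, .23, .27)), collapse = ""), con)
  starts <- seq(1000, L - 20000, by = 25000)
  for (s in starts)
    gene_rows[[length(gene_rows) + 1]] <- data.frame(
      gene_id = sprintf("%s_G%04d", ch, s %/% 25000),
      chrom = ch, start = s, end = s + 15000,
      strand = sample(c("+", "-"), 1),
      exon_starts = paste(s + c(0, 8000), collapse = ","),
      exon_ends = paste(s + c(2000, 10000), collapse = ","))
}
close(con)
gm_path <- file.path(out, "gene_models.tsv")
write.table(do.call(rbind, gene_rows), gm_path, sep = "\t",
            row.names = FALSE, quote = FALSE)
gm <- read_gene_models(gm_path)
islands <- data.frame(chrom = gm$chrom, start = gm$tss - 300,
                      end = gm$tss + 300)

ann <- annotate_consensus(cons, fa_path, gm, islands, config = cfg)
write.table(ann, file.path(out, "consensus_annotated.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Raw peak calls:", n_raw, "-> after enrichment/p filter:", n_filt, "\n")
cat("Consensus regions (support >", cfg$min_support_samples - 1, "):",
    nrow(cons), "  (blacklist removed the decoy region:",
    !any(cons$start < blacklist$end & cons$end > blacklist$start &
           cons$chrom == blacklist$chrom), ")\n")
cat("Feature distribution:\n")
print(table(ann$feature))
cat("Island status:\n")
print(table(ann$island_status))
cat("Median CpG count per region:", median(ann$cpg_count), "\n")
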