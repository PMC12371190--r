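test_that("peak filter applies both thresholds strictly", {
  calls <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                      end = c(50, 150, 250),
                      fold_enrichment = c(5, 4, 5),
                      p_value = c(0.001, 0.001, 0.01))
  kept <- filter_peak_calls(calls)
  expect_equal(kept$start, 0)  # FE = 4 and p = 0.01 are boundary drops
  expect_equal(nrow(filter_peak_calls(calls[0, ])), 0)
})

test_that("peak filter matches a brute-force filter on random calls", {
  set.seed(101)
  calls <- data.frame(chrom = "chr1", start = 1:500, end = 2:501,
                      fold_enrichment = runif(500, 0, 10),
                      p_value = runif(500, 0, 0.05))
  kept <- filter_peak_calls(calls, fe_min = 4, p_max = 0.01)
  manual <- sum(calls$fold_enrichment > 4 & calls$p_value < 0.01)
  expect_equal(nrow(kept), manual)
})

test_that("consensus building resolves the worked three-sample example", {
  peaks <- list(s1 = data.frame(chrom = "chr1", start = 100, end = 200),
                s2 = data.frame(chrom = "chr1", start = 150, end = 250),
                s3 = data.frame(chrom = "chr1", start = 180, end = 220))
  cons <- build_consensus(peaks, min_support = 3)
  expect_equal(cons$start, 180)
  expect_equal(cons$end, 200)
  expect_equal(cons$support, 3L)
})

test_that("support counts distinct samples and single-sample input yields nothing", {
  # two overlapping calls in one sample must count once
  peaks <- list(s1 = data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 260)),
                s2 = data.frame(chrom = "chr1", start = 120, end = 240))
  expect_equal(nrow(build_consensus(peaks, min_support = 3)), 0)
  expect_equal(nrow(build_consensus(peaks["s1"], min_support = 3)), 0)
  cons2 <- build_consensus(peaks, min_support = 2)
  expect_equal(cons2$support, 2L)
})

test_that("blacklisted regions are removed by any overlap", {
  peaks <- list(s1 = data.frame(chrom = "chr1", start = 100, end = 200),
                s2 = data.frame(chrom = "chr1", start = 100, end = 200),
                s3 = data.frame(chrom = "chr1", start = 100, end = 200))
  bl <- data.frame(chrom = "chr1", start = 190, end = 195)
  expect_equal(nrow(build_consensus(peaks, blacklist = bl)), 0)
  bl_far <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(nrow(build_consensus(peaks, blacklist = bl_far)), 1)
})

test_that("mixed chromosome naming is rejected", {
  peaks <- list(s1 = data.frame(chrom = "chr1", start = 1, end = 10),
                s2 = data.frame(chrom = "1", start = 1, end = 10))
  expect_error(build_consensus(peaks), "mixed chromosome naming")
})

test_that("consensus equals the per-base counting oracle on random genomes", {
  set.seed(202)
  for (rep in 1:25) {
    n_s <- sample(2:8, 1)
    peaks <- random_peak_samples(n_s, n_peaks = sample(5:30, 1))
    names(peaks) <- paste0("s", seq_len(n_s))
    bl <- if (rep %% 3 == 0) {
      st <- sample.int(9e4, 3)
      data.frame(chrom = "chr1", start = st, end = st + 300)
    } else NULL
    ms <- sample(2:4, 1)
    got <- build_consensus(peaks, blacklist = bl, min_support = ms)
    want <- oracle_consensus(peaks, blacklist = bl, min_support = ms)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$support, want$support)
  }
})

test_that("consensus output is disjoint, sorted and support-monotone", {
  set.seed(303)
  peaks <- random_peak_samples(6, 40)
  names(peaks) <- paste0("s", 1:6)
  cons <- build_consensus(peaks, min_support = 3)
  expect_true(all(diff(cons$start) > 0))
  expect_true(all(cons$end[-nrow(cons)] < cons$start[-1]))  # strictly disjoint
  # an empty extra sample never changes the consensus
  peaks$empty <- data.frame(chrom = character(), start = integer(),
                            end = integer())
  expect_identical(build_consensus(peaks, min_support = 3), cons)
})

test_that("CpG counting follows the C-position rule", {
  fa <- toy_fasta(list(chrA = "ACGCGT", chrB = "CCCC"))
  expect_equal(count_cpg(data.frame(chrom = "chrA", start = 0, end = 6), fa), 2L)
  expect_equal(count_cpg(data.frame(chrom = "chrB", start = 0, end = 4), fa), 0L)
  # lower case and ambiguity codes
  fa2 <- toy_fasta(list(c1 = "acgNcgtCg"))
  expect_equal(count_cpg(data.frame(chrom = "c1", start = 0, end = 9), fa2), 3L)
  expect_error(count_cpg(data.frame(chrom = "c1", start = 0, end = 10), fa2),
               "beyond contig end")
})

test_that("CpG counts are additive over any partition and match a regex oracle", {
  set.seed(404)
  seq_str <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE,
                          prob = c(.2, .3, .3, .2)), collapse = "")
  fa <- toy_fasta(list(chr1 = seq_str))
  whole <- count_cpg(data.frame(chrom = "chr1", start = 0, end = 3000), fa)
  expect_equal(whole, oracle_cpg(seq_str, 0, 3000))
  for (k in 1:10) {
    cuts <- sort(c(0, sample(1:2999, sample(2:6, 1)), 3000))
    parts <- data.frame(chrom = "chr1", start = cuts[-length(cuts)],
                        end = cuts[-1])
    expect_equal(sum(count_cpg(parts, fa)), whole)
  }
  st <- sample.int(2900, 100)
  iv <- data.frame(chrom = "chr1", start = st, end = st + sample.int(100, 100, TRUE))
  got <- count_cpg(iv, fa)
  want <- vapply(seq_len(100), function(i) oracle_cpg(seq_str, iv$start[i], iv$end[i]),
                 integer(1))
  expect_equal(got, want)
})

test_that("feature classification follows promoter > exon > intron precedence", {
  gm <- toy_gene_models(data.frame(
    gene_id = "G1", chrom = "chr1", start = 10000, end = 20000, strand = "+",
    exon_starts = "10000,15000", exon_ends = "11000,16000"))
  isl <- data.frame(chrom = "chr1", start = 30000, end = 31000)
  # overlaps TSS +/- 1kb and the first exon: promoter wins
  r1 <- classify_feature(data.frame(chrom = "chr1", start = 10500, end = 10800),
                         gm, isl)
  expect_equal(r1$feature, "promoter")
  r2 <- classify_feature(data.frame(chrom = "chr1", start = 15200, end = 15300),
                         gm, isl)
  expect_equal(r2$feature, "exon")
  r3 <- classify_feature(data.frame(chrom = "chr1", start = 13000, end = 13100),
                         gm, isl)
  expect_equal(r3$feature, "intron")
  # 500 bp downstream of the island end: shore
  r4 <- classify_feature(data.frame(chrom = "chr1", start = 31500, end = 31600),
                         gm, isl)
  expect_equal(r4$island_status, "shore")
  expect_equal(r4$feature, "intergenic")
  # a chromosome with no genes or islands
  r5 <- classify_feature(data.frame(chrom = "chr9", start = 0, end = 100), gm, isl)
  expect_equal(r5$feature, "intergenic")
  expect_equal(r5$island_status, "open_sea")
})

test_that("promoter windows are strand-aware", {
  gm <- toy_gene_models(data.frame(
    gene_id = "G2", chrom = "chr1", start = 10000, end = 20000, strand = "-",
    exon_starts = "", exon_ends = ""))
  # on the minus strand the TSS sits at the gene-body end
  r <- classify_feature(data.frame(chrom = "chr1", start = 20300, end = 20400), gm)
  expect_equal(r$feature, "promoter")
  r2 <- classify_feature(data.frame(chrom = "chr1", start = 8900, end = 9000), gm)
  expect_equal(r2$feature, "intergenic")
})

test_that("nearest gene assignment respects the distance window", {
  gm <- toy_gene_models(data.frame(
    gene_id = "G1", chrom = "chr1", start = 500000, end = 510000, strand = "+",
    exon_starts = "", exon_ends = ""))
  inside <- assign_nearest_gene(data.frame(chrom = "chr1", start = 505000,
                                           end = 505500), gm)
  expect_equal(inside$nearest_gene, "G1")
  expect_equal(inside$distance_to_gene, 0L)
  # exactly 100001 bp away: outside the window
  far <- assign_nearest_gene(data.frame(chrom = "chr1", start = 610001 + 100000,
                                        end = 710002 + 100000), gm)
  expect_equal(far$nearest_gene, "intergenic")
  at_edge <- assign_nearest_gene(data.frame(chrom = "chr1", start = 610000,
                                            end = 610100), gm)
  expect_equal(at_edge$nearest_gene, "G1")
  expect_equal(at_edge$distance_to_gene, 100000L)
})

test_that("nearest gene matches a brute-force all-pairs scan", {
  set.seed(505)
  gm <- toy_gene_models(data.frame(
    gene_id = sprintf("G%02d", 1:20), chrom = "chr1",
    start = st <- sort(sample.int(2e6, 20)), end = st + 5000,
    strand = sample(c("+", "-"), 20, TRUE),
    exon_starts = "", exon_ends = ""))
  qs <- sample.int(2e6, 200)
  q <- data.frame(chrom = "chr1", start = qs, end = qs + 200)
  got <- assign_nearest_gene(q, gm, window = 1e5)
  for (i in seq_len(200)) {
    gaps <- pmax(0, pmax(gm$start - q$end[i], q$start[i] - gm$end))
    ord <- order(gaps, gm$gene_id)
    expected <- if (gaps[ord[1]] <= 1e5) gm$gene_id[ord[1]] else "intergenic"
    expect_equal(got$nearest_gene[i], expected)
  }
})

test_that("mean-coverage filter is strict at the boundary", {
  regions <- data.frame(chrom = "chr1", start = c(0, 10, 20),
                        end = c(5, 15, 25), region_id = c("a", "b", "c"))
  m <- rbind(c(10, 10, 10), c(11, 11, 11), c(0, 0, 40))
  colnames(m) <- paste0("s", 1:3)
  cm <- count_matrix(regions, m)
  out <- filter_mean_coverage(cm, 10)
  expect_equal(out$regions$region_id, c("b", "c"))
  set.seed(606)
  big <- matrix(rpois(5000, 11), 500, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
  cmb <- count_matrix(data.frame(chrom = "chr1", start = 1:500 * 10,
                                 end = 1:500 * 10 + 5,
                                 region_id = paste0("r", 1:500)), big)
  out2 <- filter_mean_coverage(cmb, 10)
  expect_equal(nrow(out2$methyl), sum(rowMeans(big) > 10))
})

test_that("simulated peak calls survive filtering and consensus as designed", {
  cfg <- sim_config(n_regions = 40, n_dmr_per_contrast = 5,
                    peak_emit_prob = 0.9)
  sam <- simulate_cohort(sim_config(n_subjects_per_group = c(IIa = 4)), seed = 2)
  pk <- simulate_peak_calls(sam, cfg, seed = 2)
  filt <- lapply(pk$calls, filter_peak_calls)
  # decoys fail the thresholds by construction
  expect_true(all(vapply(filt, function(d)
    all(d$fold_enrichment > 4 & d$p_value < 0.01), logical(1))))
  cons <- build_consensus(filt, min_support = 3)
  # most true regions emitted in >= 3 samples should be recovered
  gr_true <- pk$regions
  hit <- vapply(seq_len(nrow(gr_true)), function(i)
    any(cons$chrom == gr_true$chrom[i] &
          cons$start < gr_true$end[i] & cons$end > gr_true$start[i]),
    logical(1))
  expect_gt(mean(hit), 0.8)
})
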