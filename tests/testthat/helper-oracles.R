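# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# per-base consensus oracle: distinct-sample coverage counting on a small
# genome, run-length merging of qualifying bases, max support per run,
# any-overlap blacklist removal
oracle_consensus <- function(peaks_by_sample, blacklist = NULL,
                             min_support = 3, genome_len = 1e5) {
  chroms <- unique(unlist(lapply(peaks_by_sample, function(d) d$chrom)))
  out <- list()
  for (ch in sort(chroms)) {
    cov <- matrix(FALSE, length(peaks_by_sample), genome_len)
    for (s in seq_along(peaks_by_sample)) {
      d <- peaks_by_sample[[s]]
      d <- d[d$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(d)))
        cov[s, (d$start[i] + 1):d$end[i]] <- TRUE
    }
    support <- colSums(cov)
    keep <- support >= min_support
    if (!is.null(blacklist)) {
      bl <- blacklist[blacklist$chrom == ch, , drop = FALSE]
      blmask <- rep(FALSE, genome_len)
      for (i in seq_len(nrow(bl)))
        blmask[(bl$start[i] + 1):bl$end[i]] <- TRUE
    } else blmask <- rep(FALSE, genome_len)
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      span <- starts[k]:ends[k]
      if (any(blmask[span])) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = starts[k] - 1L, end = ends[k],
        support = max(support[span]))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer()))
  do.call(rbind, out)
}

# exhaustive pairwise AUC with half-credit for ties
oracle_auc <- function(case, control) {
  wins <- 0
  for (a in case) for (b in control)
    wins <- wins + (a > b) + 0.5 * (a == b)
  a_raw <- wins / (length(case) * length(control))
  max(a_raw, 1 - a_raw)
}

# exact two-sided Mann-Whitney p by enumerating all labelings
oracle_mw_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- combn(length(vals), n1)
  u_all <- apply(combos, 2, u_of)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# random peak tables on one small chromosome
random_peak_samples <- function(n_samples, n_peaks, genome_len = 1e5,
                                chrom = "chr1") {
  lapply(seq_len(n_samples), function(s) {
    st <- sample.int(genome_len - 600, n_peaks)
    data.frame(chrom = chrom, start = st,
               end = st + sample(50:500, n_peaks, replace = TRUE))
  })
}

# tiny FASTA reference on disk; returns the path
toy_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

# regex CpG counting oracle (C-position rule with one-base lookahead)
oracle_cpg <- function(seq_str, start, end) {
  sub <- toupper(substr(seq_str, start + 1, min(end + 1, nchar(seq_str))))
  length(gregexpr("(?=CG)", sub, perl = TRUE)[[1]][
    gregexpr("(?=CG)", sub, perl = TRUE)[[1]] > 0])
}

# gene-model table written to disk; returns the parsed models
toy_gene_models <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  read_gene_models(path)
}

# sample sheet for n subjects of one classification, all paired
flat_cohort <- function(n_per_group, seed = 1) {
  simulate_cohort(sim_config(n_subjects_per_group = n_per_group), seed = seed)
}
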