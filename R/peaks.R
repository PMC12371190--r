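# Consensus methylated-region construction and annotation.
#
# Per-sample MACS-style peak calls are filtered on fold enrichment and
# p-value, fragmented at the union of all interval breakpoints, scored by
# distinct-sample support, merged and blacklist-filtered; surviving regions
# are annotated with CpG counts, genomic feature class, CpG-island status
# and nearest gene.

as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Filter raw peak calls on enrichment and significance
#'
#' Keeps calls with fold enrichment strictly greater than `fe_min` and
#' p-value strictly less than `p_max` (defaults: > 4 and < 0.01). Boundary
#' values are dropped.
#'
#' @param calls `data.frame` with `fold_enrichment` and `p_value` columns.
#' @param fe_min minimum fold enrichment (exclusive).
#' @param p_max maximum p-value (exclusive).
#' @return The surviving rows of `calls`.
#' @export
filter_peak_calls <- function(calls, fe_min = 4, p_max = 0.01) {
  stopifnot(fe_min > 0, p_max > 0)
  if (nrow(calls) == 0) return(calls)
  calls[calls$fold_enrichment > fe_min & calls$p_value < p_max, , drop = FALSE]
}

#' Build the consensus methylated-region set
#'
#' Intervals are first merged within each sample (so support counts distinct
#' samples, not peak instances), the genome is fragmented at the union of all
#' breakpoints, each fragment's support is the number of distinct samples
#' covering it, fragments with support at least `min_support` (default 3,
#' i.e. "more than two samples") are kept, adjacent kept fragments are merged
#' with support equal to the maximum over merged fragments, and any merged
#' region overlapping a blacklist interval by one or more bases is removed.
#'
#' @param peaks_by_sample named list of interval `data.frame`s (`chrom`,
#'   `start`, `end`), one per sample, 0-based half-open.
#' @param blacklist optional interval `data.frame` of regions to exclude.
#' @param min_support minimum number of distinct covering samples.
#' @return `data.frame` with `chrom`, `start`, `end`, `support`, sorted and
#'   disjoint.
#' @export
build_consensus <- function(peaks_by_sample, blacklist = NULL,
                            min_support = 3) {
  stopifnot(min_support >= 1)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer())
  nonempty <- Filter(function(d) !is.null(d) && nrow(d) > 0, peaks_by_sample)
  if (length(nonempty) == 0) return(empty)

  chroms <- unique(unlist(lapply(nonempty, function(d) unique(d$chrom))))
  has_prefix <- grepl("^chr", chroms)
  if (any(has_prefix) && any(!has_prefix))
    stop("mixed chromosome naming schemes (chr-prefixed and bare)")

  merged <- lapply(nonempty, function(d) GenomicRanges::reduce(as_granges(d)))
  all_gr <- do.call(c, unname(merged))
  frags <- GenomicRanges::disjoin(all_gr)
  support <- GenomicRanges::countOverlaps(frags, GenomicRanges::GRangesList(merged))
  keep <- frags[support >= min_support]
  sup <- support[support >= min_support]
  if (length(keep) == 0) return(empty)

  out <- GenomicRanges::reduce(keep, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(out)$revmap
  out_sup <- vapply(revmap, function(ix) max(sup[ix]), numeric(1))

  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hit <- GenomicRanges::countOverlaps(out, as_granges(blacklist)) > 0
    out <- out[!hit]
    out_sup <- out_sup[!hit]
  }
  res <- granges_to_df(out)
  res$support <- as.integer(out_sup)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Count CpG dinucleotides in regions
#'
#' Counts `CG` dinucleotides whose cytosine position falls inside the
#' 0-based half-open interval, reading one base past the interval end so that
#' a CpG straddling a window boundary is counted exactly once by the window
#' containing its C. Matching is case-insensitive; ambiguous bases never
#' match.
#'
#' @param intervals interval `data.frame` (`chrom`, `start`, `end`).
#' @param reference a named `Biostrings::DNAStringSet` or a FASTA file path.
#' @return Integer vector of CpG counts, one per interval.
#' @export
count_cpg <- function(intervals, reference) {
  if (is.character(reference) && length(reference) == 1)
    reference <- Biostrings::readDNAStringSet(reference)
  nm <- names(reference)
  names(reference) <- sub("\\s.*$", "", nm)
  out <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[i]
    if (!chrom %in% names(reference)) stop("contig not in reference: ", chrom)
    L <- length(reference[[chrom]])
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 0 || e > L) stop("interval beyond contig end: ", chrom, ":", s, "-", e)
    # C in [s, e): scan bases s..min(e, L-1) plus the following base
    sub <- Biostrings::subseq(reference[[chrom]], s + 1, min(e + 1, L))
    out[i] <- Biostrings::countPattern("CG",
                                       Biostrings::DNAString(toupper(as.character(sub))))
  }
  out
}

#' Read a gene-model table
#'
#' TSV with header columns `gene_id, chrom, start, end, strand, exon_starts,
#' exon_ends`; exon columns are comma-separated 0-based coordinates lying
#' within the gene body.
#'
#' @param path gene model TSV path.
#' @return `data.frame` with list-columns `exon_starts`, `exon_ends` and a
#'   computed `tss` (gene-body start on `+`, end on `-`).
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model table missing: ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  parse_list <- function(x) lapply(strsplit(as.character(x), ","), function(v) {
    out <- suppressWarnings(as.integer(v[nzchar(v)]))
    out[!is.na(out)]
  })
  df$exon_starts <- if ("exon_starts" %in% names(df))
    parse_list(df$exon_starts) else replicate(nrow(df), integer(), FALSE)
  df$exon_ends <- if ("exon_ends" %in% names(df))
    parse_list(df$exon_ends) else replicate(nrow(df), integer(), FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df
}

#' Classify regions by genomic feature and CpG-island status
#'
#' Feature precedence is promoter > exon > intron > intergenic, decided by
#' any overlap. The promoter is the window of `promoter_window` bp either
#' side of the strand-aware TSS. Island status is `cpg_island` when the
#' region overlaps an island, `shore` when it lies within `shore_window` bp
#' of one, otherwise `open_sea`; it is assigned independently of the feature.
#'
#' @param intervals interval `data.frame`.
#' @param gene_models from [read_gene_models()].
#' @param cpg_islands optional island interval `data.frame`.
#' @param promoter_window half-width of the promoter window (bp).
#' @param shore_window shore distance from an island (bp).
#' @return `data.frame` with `feature` and `island_status`.
#' @export
classify_feature <- function(intervals, gene_models, cpg_islands = NULL,
                             promoter_window = 1000, shore_window = 1000) {
  q <- as_granges(intervals)
  n <- length(q)
  feature <- rep("intergenic", n)
  if (nrow(gene_models) > 0) {
    prom <- GenomicRanges::GRanges(
      gene_models$chrom,
      IRanges::IRanges(start = pmax(1, gene_models$tss - promoter_window + 1),
                       end = gene_models$tss + promoter_window))
    body <- as_granges(gene_models)
    ex_n <- lengths(gene_models$exon_starts)
    exons <- if (sum(ex_n) > 0) GenomicRanges::GRanges(
      rep(gene_models$chrom, ex_n),
      IRanges::IRanges(start = unlist(gene_models$exon_starts) + 1,
                       end = unlist(gene_models$exon_ends)))
    else GenomicRanges::GRanges()
    # queries may sit on chromosomes without genes; that is not a warning
    in_body <- suppressWarnings(GenomicRanges::countOverlaps(q, body) > 0)
    in_exon <- if (length(exons))
      suppressWarnings(GenomicRanges::countOverlaps(q, exons) > 0)
      else rep(FALSE, n)
    in_prom <- suppressWarnings(GenomicRanges::countOverlaps(q, prom) > 0)
    feature[in_body] <- "intron"
    feature[in_body & in_exon] <- "exon"
    feature[in_prom] <- "promoter"
  }
  island_status <- rep("open_sea", n)
  if (!is.null(cpg_islands) && nrow(cpg_islands) > 0) {
    isl <- as_granges(cpg_islands)
    on_isl <- suppressWarnings(GenomicRanges::countOverlaps(q, isl) > 0)
    near <- suppressWarnings(GenomicRanges::countOverlaps(
      q, GenomicRanges::resize(isl, GenomicRanges::width(isl) + 2 * shore_window,
                               fix = "center")) > 0)
    island_status[near] <- "shore"
    island_status[on_isl] <- "cpg_island"
  }
  data.frame(feature = feature, island_status = island_status,
             stringsAsFactors = FALSE)
}

#' Assign each region to its nearest gene body
#'
#' A region overlapping a gene body is assigned to that gene at distance 0
#' (ties broken by smallest gap, then lexicographic gene id); otherwise the
#' nearest gene body within `window` bp is used; regions farther than
#' `window` from every gene are labelled `intergenic` with missing distance.
#'
#' @param intervals interval `data.frame`.
#' @param gene_models from [read_gene_models()].
#' @param window maximum gap in bp (default 100000).
#' @return `data.frame` with `nearest_gene` and `distance_to_gene`.
#' @export
assign_nearest_gene <- function(intervals, gene_models, window = 100000) {
  stopifnot(window >= 0)
  n <- nrow(intervals)
  gene <- rep("intergenic", n)
  dist <- rep(NA_integer_, n)
  if (nrow(gene_models) == 0 || n == 0)
    return(data.frame(nearest_gene = gene, distance_to_gene = dist,
                      stringsAsFactors = FALSE))
  for (i in seq_len(n)) {
    same <- gene_models[gene_models$chrom == intervals$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) next
    # gap between [s1,e1) and [s2,e2): 0 if overlapping
    gaps <- pmax(0, pmax(same$start - intervals$end[i],
                         intervals$start[i] - same$end))
    ord <- order(gaps, same$gene_id)
    best <- ord[1]
    if (gaps[best] <= window) {
      gene[i] <- same$gene_id[best]
      dist[i] <- as.integer(gaps[best])
    }
  }
  data.frame(nearest_gene = gene, distance_to_gene = dist,
             stringsAsFactors = FALSE)
}

#' Filter regions on mean methyl-capture coverage
#'
#' Keeps regions whose mean methyl count across samples is strictly greater
#' than `threshold` (default 10), removing likely artefact regions.
#'
#' @param x a [count_matrix()].
#' @param threshold minimum mean coverage (exclusive).
#' @param fraction which fraction the rule applies to (`"methyl"` or
#'   `"input"`).
#' @return The filtered [count_matrix()].
#' @export
filter_mean_coverage <- function(x, threshold = 10, fraction = c("methyl", "input")) {
  stopifnot(threshold >= 0)
  fraction <- match.arg(fraction)
  m <- if (fraction == "methyl") x$methyl else {
    if (is.null(x$input)) stop("no input fraction in count matrix")
    x$input
  }
  keep <- rowMeans(m) > threshold
  subset_counts(x, which(keep))
}

#' Annotate a consensus region set
#'
#' Convenience wrapper combining [count_cpg()], [classify_feature()] and
#' [assign_nearest_gene()].
#'
#' @param consensus consensus `data.frame` from [build_consensus()].
#' @param reference FASTA path or `DNAStringSet`.
#' @param gene_models from [read_gene_models()].
#' @param cpg_islands optional island intervals.
#' @param config a [fcd_config()].
#' @return `consensus` with added `region_id`, `cpg_count`, `feature`,
#'   `island_status`, `nearest_gene`, `distance_to_gene`.
#' @export
annotate_consensus <- function(consensus, reference, gene_models,
                               cpg_islands = NULL, config = fcd_config()) {
  out <- consensus
  out$region_id <- sprintf("consensus_%05d", seq_len(nrow(out)))
  out$cpg_count <- count_cpg(out, reference)
  fc <- classify_feature(out, gene_models, cpg_islands,
                         promoter_window = config$promoter_window,
                         shore_window = config$shore_window)
  ng <- assign_nearest_gene(out, gene_models,
                            window = config$nearest_gene_window)
  cbind(out, fc, ng)
}
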