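# Methyl-qPCR analytics: spike-normalized bound/unbound quantification to
# percent methylation, replicate handling, Mann-Whitney group comparisons
# and replication-cohort ROC.

#' Read a long-format qPCR plate table
#'
#' CSV with columns `sample_id, target, fraction, replicate, ct`. `fraction`
#' is `bound`, `unbound` or `spike`; undetermined wells may be empty or the
#' literal `Undetermined` and become `NA` (never silently 40).
#'
#' @param path CSV path.
#' @return `data.frame` with numeric `ct` (NA = undetermined).
#' @export
read_qpcr <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "fraction", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qPCR table missing: ", paste(miss, collapse = ", "))
  raw <- as.character(df$ct)
  undet <- is.na(raw) | raw == "" | tolower(raw) == "undetermined"
  ct <- suppressWarnings(as.numeric(raw))
  bad <- !undet & is.na(ct)
  if (any(bad)) stop("unparseable ct at row ", which(bad)[1])
  if (any(!is.na(ct) & (ct <= 0 | ct > 40)))
    stop("ct outside (0, 40]")
  df$ct <- ifelse(undet, NA_real_, ct)
  df
}

#' Percent methylation from bound/unbound Ct values
#'
#' Replicate Cts are averaged on the Ct scale first; a replicate spread
#' above 1 cycle raises a `replicate_spread` QC flag. Each fraction is
#' quantified relative to the methylated spike-in control:
#' `Q_f = 2^(ct_spike_f - ct_target_f)`, and
#' `percent = 100 * Q_bound / (Q_bound + Q_unbound)`. An undetermined
#' fraction contributes zero quantity (flagged); when both fractions are
#' undetermined the percent is missing.
#'
#' @param ct_bound,ct_unbound numeric vectors of replicate Cts for the
#'   target in each fraction (NA = undetermined well).
#' @param ct_spike_bound,ct_spike_unbound replicate Cts of the spike-in
#'   control in each fraction.
#' @return List of class `methylation_percent`: `percent` (in `[0, 100]` or
#'   NA) and `qc_flags` (character vector).
#' @export
percent_methylation <- function(ct_bound, ct_unbound,
                                ct_spike_bound, ct_spike_unbound) {
  flags <- character()
  avg <- function(x, label) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    if (length(x) > 1 && (max(x) - min(x)) > 1)
      flags <<- c(flags, paste0("replicate_spread:", label))
    mean(x)
  }
  cb <- avg(ct_bound, "bound"); cu <- avg(ct_unbound, "unbound")
  sb <- avg(ct_spike_bound, "spike_bound")
  su <- avg(ct_spike_unbound, "spike_unbound")
  if (is.na(sb) || is.na(su)) stop("spike control undetermined")
  qb <- if (is.na(cb)) { flags <- c(flags, "undetermined:bound"); 0 }
        else 2^(sb - cb)
  qu <- if (is.na(cu)) { flags <- c(flags, "undetermined:unbound"); 0 }
        else 2^(su - cu)
  pct <- if (qb + qu == 0) { flags <- c(flags, "both_undetermined"); NA_real_ }
         else 100 * qb / (qb + qu)
  structure(list(percent = pct, qc_flags = unique(flags)),
            class = "methylation_percent")
}

#' Percent methylation for every sample and target of a plate
#'
#' @param wells long-format plate `data.frame` (see [read_qpcr()]); the
#'   spike-in control rows must use target `"spike_control"`.
#' @return `data.frame`: `sample_id`, `target`, `percent`, `qc_flags`
#'   (`;`-joined, empty when clean).
#' @export
percent_methylation_table <- function(wells) {
  targets <- setdiff(unique(wells$target), "spike_control")
  rows <- list()
  for (sid in unique(wells$sample_id)) {
    w <- wells[wells$sample_id == sid, ]
    spike <- w[w$target == "spike_control", ]
    for (tg in targets) {
      t_b <- w$ct[w$target == tg & w$fraction == "bound"]
      t_u <- w$ct[w$target == tg & w$fraction == "unbound"]
      if (length(t_b) == 0 && length(t_u) == 0) next
      pm <- percent_methylation(t_b, t_u,
                                spike$ct[spike$fraction == "bound"],
                                spike$ct[spike$fraction == "unbound"])
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, target = tg, percent = pm$percent,
        qc_flags = paste(pm$qc_flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Exact p-value by full enumeration when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' tie and continuity correction.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @return List: `U` (statistic for `group_a`), `p_value` (two-sided).
#' @export
mann_whitney <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  if (max(c(group_a, group_b)) == min(c(group_a, group_b)))
    return(list(U = length(group_a) * length(group_b) / 2, p_value = 1))
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b)) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Group summaries, pairwise tests and ROC for a validation cohort
#'
#' Per target and tissue: mean percent methylation with standard error by
#' group (other pathologies / FCD IIa / FCD IIb), Mann-Whitney tests for the
#' three pairwise comparisons, and a combined-panel ROC for IIb vs IIa from
#' an in-sample logistic fit over all targets.
#'
#' @param percents from [percent_methylation_table()].
#' @param sample_sheet sample sheet covering the plate's samples.
#' @param targets targets to include (default: all in `percents`).
#' @return List of class `validation_report`: `group_stats` (target, tissue,
#'   group, n, mean, sem), `tests` (target, tissue, comparison, U, p_value),
#'   `roc` (tissue, auc, n_case, n_control).
#' @export
validation_report <- function(percents, sample_sheet, targets = NULL) {
  if (is.null(targets)) targets <- unique(percents$target)
  df <- merge(percents[percents$target %in% targets, ],
              sample_sheet[, c("sample_id", "tissue", "classification")],
              by = "sample_id")
  df$group <- ifelse(df$classification == "IIa", "IIa",
                     ifelse(df$classification == "IIb", "IIb", "others"))
  stats_rows <- list(); test_rows <- list(); roc_rows <- list()
  for (tis in unique(df$tissue)) {
    for (tg in targets) {
      d <- df[df$tissue == tis & df$target == tg & !is.na(df$percent), ]
      for (g in c("others", "IIa", "IIb")) {
        v <- d$percent[d$group == g]
        stats_rows[[length(stats_rows) + 1]] <- data.frame(
          target = tg, tissue = tis, group = g, n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
          stringsAsFactors = FALSE)
      }
      prs <- list(c("others", "IIa"), c("others", "IIb"), c("IIa", "IIb"))
      for (pr in prs) {
        va <- d$percent[d$group == pr[1]]; vb <- d$percent[d$group == pr[2]]
        if (length(va) == 0 || length(vb) == 0) next
        mw <- mann_whitney(va, vb)
        test_rows[[length(test_rows) + 1]] <- data.frame(
          target = tg, tissue = tis,
          comparison = paste(pr, collapse = "_vs_"),
          U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
      }
    }
    # combined-panel ROC: IIb vs IIa on all targets jointly
    wide <- stats::reshape(
      df[df$tissue == tis & df$group %in% c("IIa", "IIb"),
         c("sample_id", "group", "target", "percent")],
      idvar = c("sample_id", "group"), timevar = "target",
      direction = "wide")
    wide <- wide[complete.cases(wide), , drop = FALSE]
    if (nrow(wide) >= 4 && length(unique(wide$group)) == 2) {
      y <- as.numeric(wide$group == "IIb")
      X <- as.matrix(wide[, -(1:2), drop = FALSE])
      score <- fit_combo_score(X, y)
      roc <- region_auc(score[y == 1], score[y == 0])
      roc_rows[[length(roc_rows) + 1]] <- data.frame(
        tissue = tis, auc = roc$auc, n_case = roc$n_case,
        n_control = roc$n_control, stringsAsFactors = FALSE)
    }
  }
  structure(list(group_stats = do.call(rbind, stats_rows),
                 tests = do.call(rbind, test_rows),
                 roc = if (length(roc_rows)) do.call(rbind, roc_rows) else NULL),
            class = "validation_report")
}
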