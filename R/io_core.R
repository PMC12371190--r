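#' @importFrom stats median model.matrix optimize pchisq lowess rnbinom runif
#'   rnorm rbinom rgamma setNames aov coef glm binomial sd var wilcox.test
#'   complete.cases quantile fitted
#' @importFrom utils combn read.csv write.csv read.delim write.table
NULL

# Recognised histopathological classifications: five FCD subtypes plus the
# four non-FCD ("other pathologies") categories.
FCD_CLASSES   <- c("Ia", "IIa", "IIb", "IIIa", "IIId")
OTHER_CLASSES <- c("mMCD", "MOGHE", "PMG", "nonMCD")
ALL_CLASSES   <- c(FCD_CLASSES, OTHER_CLASSES)

RISK_FACTOR_LEVELS <- c("family_history", "stroke", "tumour", "infection", "TBI")

#' Default pipeline configuration
#'
#' Central registry of the thresholds used across the pipeline. All printed
#' thresholds are applied as strict inequalities: a peak is retained when its
#' fold enrichment is strictly greater than `fold_enrichment_min`, a region is
#' a biomarker candidate when its AUC is strictly greater than `auc_min` and
#' its CpG count strictly greater than `cpg_min`, and so on.
#'
#' @param ... named overrides of any default value.
#' @return A named list of configuration values.
#' @details Defaults: fold_enrichment_min = 4, peak_p_max = 0.01,
#'   min_support_samples = 3 (a consensus fragment must be covered by more
#'   than two distinct samples), mean_coverage_min = 10, dmr_p_max = 0.01,
#'   auc_min = 0.65, cpg_min = 4 (kept iff cpg_count > 4, i.e. at least 5 CpG
#'   sites), nearest_gene_window = 100000, promoter_window = 1000,
#'   shore_window = 1000, pseudocount = 0.5, dispersion_shrinkage = 0.3,
#'   tissue_mode = "both".
#' @export
fcd_config <- function(...) {
  cfg <- list(
    fold_enrichment_min  = 4,
    peak_p_max           = 0.01,
    min_support_samples  = 3,
    mean_coverage_min    = 10,
    dmr_p_max            = 0.01,
    auc_min              = 0.65,
    cpg_min              = 4,
    nearest_gene_window  = 100000L,
    promoter_window      = 1000L,
    shore_window         = 1000L,
    pseudocount          = 0.5,
    dispersion_shrinkage = 0.3,
    tissue_mode          = "both"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a cohort sample sheet
#'
#' Parses a CSV sample sheet into one record per sample. Expected columns:
#' `sample_id, subject_id, tissue, classification, gender, age_years,
#' onset_age_years, duration_years, laterality, localisation, engel,
#' mri_positive, risk_factors, prior_surgery, spike_enrichment_ratio`.
#' `risk_factors` is a `;`-separated subset of
#' `family_history, stroke, tumour, infection, TBI`. Unknown extra columns are
#' carried through untouched. Missing values stay missing (`NA`); they are
#' never silently zeroed.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with one row per sample and an added logical
#'   `combined_risk` column (any risk factor present; `NA` when unknown).
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = c("NA", ""))
  required <- c("sample_id", "subject_id", "tissue", "classification")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(empty_sample_sheet(names(df)))

  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_cls <- !df$classification %in% ALL_CLASSES
  if (any(bad_cls))
    stop("unknown classification '", df$classification[which(bad_cls)[1]],
         "' at row ", which(bad_cls)[1])
  bad_tis <- !df$tissue %in% c("brain", "blood")
  if (any(bad_tis))
    stop("unknown tissue '", df$tissue[which(bad_tis)[1]],
         "' at row ", which(bad_tis)[1])

  for (col in c("age_years", "onset_age_years", "duration_years",
                "spike_enrichment_ratio")) {
    if (!col %in% names(df)) { df[[col]] <- NA_real_; next }
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad))
      stop("non-numeric ", col, " '", raw[which(bad)[1]], "' at row ", which(bad)[1])
    df[[col]] <- num
  }
  if (any(!is.na(df$spike_enrichment_ratio) & df$spike_enrichment_ratio <= 0))
    stop("spike_enrichment_ratio must be > 0")

  # the literal "none" records a known-empty risk set; an empty cell means
  # risk factors were not recorded (missing, not absent)
  if (!"risk_factors" %in% names(df)) df$risk_factors <- NA_character_
  known_none <- !is.na(df$risk_factors) & df$risk_factors == "none"
  df$risk_factors[known_none] <- NA_character_
  rf <- strsplit(ifelse(is.na(df$risk_factors), "", df$risk_factors), ";", fixed = TRUE)
  rf <- lapply(rf, function(x) trimws(x[nzchar(trimws(x))]))
  bad_rf <- vapply(rf, function(x) any(!x %in% RISK_FACTOR_LEVELS), logical(1))
  if (any(bad_rf))
    stop("unknown risk factor at row ", which(bad_rf)[1])
  df$combined_risk <- ifelse(known_none, FALSE,
                             ifelse(is.na(df$risk_factors), NA,
                                    lengths(rf) > 0))

  if (!"prior_surgery" %in% names(df)) df$prior_surgery <- NA
  df$prior_surgery <- as.logical(df$prior_surgery)
  if (!"mri_positive" %in% names(df)) df$mri_positive <- NA
  df$mri_positive <- as.logical(df$mri_positive)
  for (col in c("gender", "laterality", "localisation", "engel")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  rownames(df) <- NULL
  df
}

empty_sample_sheet <- function(cols = character()) {
  base <- c("sample_id", "subject_id", "tissue", "classification", "gender",
            "age_years", "onset_age_years", "duration_years", "laterality",
            "localisation", "engel", "mri_positive", "risk_factors",
            "prior_surgery", "spike_enrichment_ratio", "combined_risk")
  out <- as.data.frame(setNames(rep(list(character(0)), length(base)), base))
  out$age_years <- numeric(0); out$onset_age_years <- numeric(0)
  out$duration_years <- numeric(0); out$spike_enrichment_ratio <- numeric(0)
  out$mri_positive <- logical(0); out$prior_surgery <- logical(0)
  out$combined_risk <- logical(0)
  out
}

#' Write a sample sheet
#'
#' Inverse of [read_sample_sheet()]: `read_sample_sheet(write_sample_sheet(x))`
#' reproduces `x` field for field on valid input.
#'
#' @param records sample-sheet `data.frame`.
#' @param path output CSV path.
#' @export
write_sample_sheet <- function(records, path) {
  out <- records
  if ("combined_risk" %in% names(out)) {
    none <- !is.na(out$combined_risk) & !out$combined_risk &
      is.na(out$risk_factors)
    out$risk_factors[none] <- "none"
    out$combined_risk <- NULL
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Summarize a cohort
#'
#' Counts samples per classification and tissue, and counts subjects with
#' paired brain/blood samples versus unpaired single-tissue samples.
#'
#' @param records sample-sheet `data.frame` (possibly empty).
#' @return An object of class `cohort_summary`: a list with
#'   `classification_counts` (named integer vector over all nine
#'   classifications), `tissue_counts`, `n_paired`, `n_unpaired_brain`,
#'   `n_unpaired_blood`, `n_fcd`, `n_other`, `n_samples`.
#' @export
cohort_summary <- function(records) {
  cls <- factor(records$classification, levels = ALL_CLASSES)
  tis <- factor(records$tissue, levels = c("brain", "blood"))
  by_subject <- split(records$tissue, records$subject_id)
  paired <- vapply(by_subject, function(t) all(c("brain", "blood") %in% t), logical(1))
  unpaired_brain <- vapply(by_subject,
                           function(t) "brain" %in% t && !"blood" %in% t, logical(1))
  unpaired_blood <- vapply(by_subject,
                           function(t) "blood" %in% t && !"brain" %in% t, logical(1))
  out <- list(
    classification_counts = table(cls),
    tissue_counts   = table(tis),
    n_paired        = sum(paired),
    n_unpaired_brain = sum(unpaired_brain),
    n_unpaired_blood = sum(unpaired_blood),
    n_fcd   = sum(records$classification %in% FCD_CLASSES),
    n_other = sum(records$classification %in% OTHER_CLASSES),
    n_samples = nrow(records)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort:", x$n_samples, "samples (",
      x$tissue_counts[["brain"]], "brain /", x$tissue_counts[["blood"]], "blood )\n")
  cat("  paired subjects:", x$n_paired,
      " unpaired brain:", x$n_unpaired_brain,
      " unpaired blood:", x$n_unpaired_blood, "\n")
  cat("  FCD samples:", x$n_fcd, " other pathologies:", x$n_other, "\n")
  print(x$classification_counts)
  invisible(x)
}

#' Read genomic intervals (BED dialect)
#'
#' Reads a tab-separated interval file with at least three columns
#' (chrom, start, end), 0-based half-open. Any further columns are retained;
#' unnamed files get columns named `V4`, `V5`, ... unless a header is present.
#'
#' @param path path to a BED-like TSV.
#' @param col_names optional names for the extra columns (beyond the first 3).
#' @return A `data.frame` with columns `chrom`, `start`, `end` plus extras.
#' @export
read_intervals <- function(path, col_names = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("interval file needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(col_names)) {
    extra <- seq_len(min(length(col_names), ncol(df) - 3))
    names(df)[3 + extra] <- col_names[extra]
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) stop("non-integer interval coordinate")
  bad <- df$end <= df$start | df$start < 0
  if (any(bad)) stop("invalid interval (end <= start or start < 0) at line ",
                     which(bad)[1])
  df
}

#' Write genomic intervals
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` and optional
#'   extra columns, 0-based half-open.
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  write.table(intervals, path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a region-by-sample count matrix
#'
#' Container for methyl-capture (and optionally input-fraction) read counts
#' over a common set of regions.
#'
#' @param regions `data.frame` with `chrom`, `start`, `end`, `region_id`.
#' @param methyl integer matrix, regions x samples, column names = sample ids.
#' @param input optional matching matrix of input-fraction counts.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(regions, methyl, input = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "region_id") %in% names(regions)))
  methyl <- as.matrix(methyl)
  if (nrow(methyl) != nrow(regions))
    stop("methyl matrix rows != number of regions")
  if (anyDuplicated(regions$region_id)) stop("region_ids must be unique")
  if (any(methyl < 0)) stop("negative counts")
  if (!is.null(input)) {
    input <- as.matrix(input)
    if (!all(dim(input) == dim(methyl))) stop("input matrix shape mismatch")
    if (any(input < 0)) stop("negative counts")
  }
  rownames(methyl) <- regions$region_id
  if (!is.null(input)) rownames(input) <- regions$region_id
  structure(list(regions = regions, samples = colnames(methyl),
                 methyl = methyl, input = input),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$methyl), "regions x", ncol(x$methyl), "samples",
      if (!is.null(x$input)) "(+ input fraction)" else "", "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$methyl)

#' Subset a count matrix by regions and/or samples
#'
#' @param x `count_matrix`.
#' @param i region index (logical, integer or region_id character).
#' @param j sample index (logical, integer or sample_id character).
#' @export
subset_counts <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$methyl))
  if (is.character(i)) i <- match(i, x$regions$region_id)
  if (is.null(j)) j <- seq_len(ncol(x$methyl))
  if (is.character(j)) j <- match(j, x$samples)
  count_matrix(x$regions[i, , drop = FALSE],
               x$methyl[i, j, drop = FALSE],
               if (!is.null(x$input)) x$input[i, j, drop = FALSE])
}

#' Read a count matrix from TSV
#'
#' Layout: header row, first four columns `chrom, start, end, region_id`,
#' remaining columns one per sample. Column order defines sample order.
#'
#' @param path methyl-fraction TSV.
#' @param input_path optional input-fraction TSV with identical layout.
#' @param sample_ids optional vector of expected sample ids; columns not in it
#'   trigger a warning (or an error when `strict = TRUE`).
#' @param strict escalate unknown sample columns to an error.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, input_path = NULL, sample_ids = NULL,
                        strict = FALSE) {
  read_one <- function(p) {
    df <- read.delim(p, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (ncol(df) < 5) stop("count TSV needs chrom/start/end/region_id + samples")
    regions <- df[, 1:4]
    names(regions) <- c("chrom", "start", "end", "region_id")
    m <- as.matrix(df[, -(1:4), drop = FALSE])
    storage.mode(m) <- "integer"
    if (anyNA(m)) stop("non-integer count in ", p)
    if (any(m < 0)) stop("negative count in ", p)
    list(regions = regions, m = m)
  }
  me <- read_one(path)
  if (!is.null(sample_ids)) {
    unknown <- setdiff(colnames(me$m), sample_ids)
    if (length(unknown)) {
      msg <- paste("count columns not in sample sheet:",
                   paste(unknown, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
  }
  inp <- NULL
  if (!is.null(input_path)) {
    ii <- read_one(input_path)
    if (!identical(ii$regions$region_id, me$regions$region_id))
      stop("input matrix regions do not match methyl matrix")
    inp <- ii$m
  }
  count_matrix(me$regions, me$m, inp)
}

#' Write a count matrix to TSV
#'
#' @param x `count_matrix`.
#' @param path methyl-fraction output TSV.
#' @param input_path optional output TSV for the input fraction.
#' @export
write_counts <- function(x, path, input_path = NULL) {
  out <- cbind(x$regions[, c("chrom", "start", "end", "region_id")],
               as.data.frame(x$methyl))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(input_path) && !is.null(x$input)) {
    out2 <- cbind(x$regions[, c("chrom", "start", "end", "region_id")],
                  as.data.frame(x$input))
    write.table(out2, input_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Path to a packaged plain-text fixture
#'
#' @param file file name under `inst/extdata`.
#' @export
fcd_example <- function(file) {
  p <- system.file("extdata", file, package = "fcdmeth")
  if (p == "") stop("no packaged file '", file, "'")
  p
}
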