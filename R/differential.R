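# Negative-binomial differential methylation.
#
# Per consensus region, a log-link NB GLM with per-sample offsets
# log(library_size * spike_enrichment_ratio) and clinical/cell covariates is
# fitted by iteratively reweighted least squares; dispersions are estimated
# by Cox-Reid-style adjusted profile likelihood and shrunk toward a
# lowess mean-dispersion trend; contrasts are tested by likelihood-ratio
# chi-square with one degree of freedom.

#' The default differential contrasts
#'
#' The study's contrast family: all FCD versus other pathologies, the FCD
#' IIa and IIb subtype-versus-others panels, FCD Ia / II / III against the
#' remaining FCD subtypes, FCD IIb versus IIa, and FCD IIIa versus IIId.
#' ("Subtypes versus other pathologies" is expanded into the per-subtype
#' panels the biomarker stage consumes.)
#'
#' @return Named list; each element has `case` and `control` classification
#'   sets.
#' @export
default_contrasts <- function() {
  list(
    FCD_vs_others      = list(case = FCD_CLASSES, control = OTHER_CLASSES),
    IIa_vs_others      = list(case = "IIa", control = OTHER_CLASSES),
    IIb_vs_others      = list(case = "IIb", control = OTHER_CLASSES),
    Ia_vs_otherFCD     = list(case = "Ia", control = setdiff(FCD_CLASSES, "Ia")),
    FCDII_vs_otherFCD  = list(case = c("IIa", "IIb"),
                              control = setdiff(FCD_CLASSES, c("IIa", "IIb"))),
    FCDIII_vs_otherFCD = list(case = c("IIIa", "IIId"),
                              control = setdiff(FCD_CLASSES, c("IIIa", "IIId"))),
    IIb_vs_IIa         = list(case = "IIb", control = "IIa"),
    IIIa_vs_IIId       = list(case = "IIIa", control = "IIId")
  )
}

impute_median <- function(x) {
  if (all(is.na(x))) return(list(x = rep(0, length(x)), imputed = TRUE))
  m <- median(x, na.rm = TRUE)
  list(x = ifelse(is.na(x), m, x), imputed = anyNA(x))
}

#' Build the design matrix for one contrast
#'
#' Subsets the cohort to the contrast's case and control classifications
#' (optionally a single tissue), builds an intercept + group indicator +
#' standardized covariate design, resolves aliasing deterministically, and
#' attaches per-sample offsets `log(library_size * spike_enrichment_ratio)`.
#' Missing numeric covariates are median-imputed and categorical ones
#' modal-imputed, with a log entry; covariates constant within the subset are
#' dropped with a log entry.
#'
#' @param samples sample sheet; must carry `library_size` and
#'   `spike_enrichment_ratio` columns.
#' @param contrast list with `case` and `control` classification sets.
#' @param cell_proportions optional columns (e.g. `B_cell`, `T_cell`,
#'   `monocyte`) already attached to `samples` to include as covariates.
#' @param tissue_mode `"both"` (joint fit with a tissue covariate),
#'   `"brain"` or `"blood"`.
#' @param covariates which clinical covariates enter the design (default:
#'   the full adjustment set). Pass `character()` for a group-only model;
#'   with few samples per arm a lean design preserves the residual degrees
#'   of freedom the likelihood-ratio chi-square approximation needs.
#' @return List of class `design_matrix`: `X` (full design), `X0` (reduced
#'   design without the group column), `offsets`, `samples` (the subset
#'   used), `group` (logical case indicator), `dropped` (log of dropped or
#'   imputed columns).
#' @export
build_design <- function(samples, contrast, cell_proportions = NULL,
                         tissue_mode = c("both", "brain", "blood"),
                         covariates = c("age_years", "onset_age_years",
                                        "duration_years", "gender",
                                        "localisation", "tissue",
                                        "combined_risk", "prior_surgery")) {
  tissue_mode <- match.arg(tissue_mode)
  if (length(intersect(contrast$case, contrast$control)))
    stop("contrast case and control sets overlap")
  if (!length(contrast$case) || !length(contrast$control))
    stop("contrast arms must be non-empty")
  keep <- samples$classification %in% c(contrast$case, contrast$control)
  if (tissue_mode != "both") keep <- keep & samples$tissue == tissue_mode
  sub <- samples[keep, , drop = FALSE]
  if (!any(sub$classification %in% contrast$case) ||
      !any(sub$classification %in% contrast$control))
    stop("empty contrast arm in this cohort")
  if (!all(c("library_size", "spike_enrichment_ratio") %in% names(sub)))
    stop("samples need library_size and spike_enrichment_ratio")

  n <- nrow(sub)
  dropped <- character()
  group <- sub$classification %in% contrast$case

  cols <- list(`(Intercept)` = rep(1, n), group = as.numeric(group))
  std <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) x else (x - mean(x)) / s
  }
  for (cv in intersect(c("age_years", "onset_age_years", "duration_years"),
                       covariates)) {
    if (!cv %in% names(sub)) next
    imp <- impute_median(sub[[cv]])
    if (imp$imputed) dropped <- c(dropped, paste0("imputed:", cv))
    cols[[cv]] <- std(imp$x)
  }
  modal <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    if (length(tb) == 0) NA else names(tb)[1]
  }
  cat_cols <- list(
    gender = if ("gender" %in% covariates) sub$gender else NULL,
    localisation = if ("localisation" %in% covariates) sub$localisation else NULL,
    tissue = if (tissue_mode == "both" && "tissue" %in% covariates)
      sub$tissue else NULL
  )
  for (nm in names(cat_cols)) {
    x <- cat_cols[[nm]]
    if (is.null(x)) next
    if (anyNA(x)) {
      x[is.na(x)] <- modal(x[!is.na(x)])
      dropped <- c(dropped, paste0("imputed:", nm))
    }
    lev <- sort(unique(x))
    if (length(lev) < 2) {
      dropped <- c(dropped, paste0("constant:", nm))
      next
    }
    for (l in lev[-1]) cols[[paste0(nm, l)]] <- as.numeric(x == l)
  }
  for (cv in intersect(c("combined_risk", "prior_surgery"), covariates)) {
    if (!cv %in% names(sub)) next
    x <- sub[[cv]]
    if (anyNA(x)) {
      x[is.na(x)] <- FALSE
      dropped <- c(dropped, paste0("imputed:", cv))
    }
    cols[[cv]] <- as.numeric(x)
  }
  if (!is.null(cell_proportions)) {
    for (cc in cell_proportions)
      if (cc %in% names(sub)) cols[[cc]] <- std(sub[[cc]])
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  # drop constant columns (other than the intercept)
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  const["(Intercept)"] <- FALSE
  if (any(const)) {
    dropped <- c(dropped, paste0("constant:", colnames(X)[const]))
    X <- X[, !const, drop = FALSE]
  }
  # resolve remaining aliasing deterministically by QR pivoting
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- c(dropped, paste0("aliased:", colnames(X)[-keep_cols]))
    X <- X[, keep_cols, drop = FALSE]
  }
  if (!"group" %in% colnames(X)) stop("group column was aliased out of the design")
  offsets <- log(sub$library_size * sub$spike_enrichment_ratio)
  structure(list(X = X, X0 = X[, colnames(X) != "group", drop = FALSE],
                 offsets = offsets, samples = sub, group = group,
                 dropped = dropped),
            class = "design_matrix")
}

# NB (or Poisson at phi = 0) deviance
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi <= 0) return(2 * sum(t1 - (y - mu)))
  2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
}

#' Fit a negative-binomial GLM for one region
#'
#' Log-link NB regression with known dispersion and per-sample offsets,
#' fitted by iteratively reweighted least squares until the relative deviance
#' change falls below `tol` (default 1e-8) or `maxit` iterations.
#'
#' @param y integer count vector.
#' @param X design matrix (from [build_design()], `$X` or `$X0`).
#' @param offset per-sample log offset vector.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives a
#'   Poisson fit.
#' @param tol,maxit convergence controls.
#' @return List: `coefficients`, `deviance`, `mu`, `converged`, `flagged`
#'   (all-zero response).
#' @export
fit_nbglm <- function(y, X, offset, dispersion, tol = 1e-8, maxit = 100L) {
  stopifnot(dispersion >= 0, length(y) == nrow(X))
  if (all(y == 0))
    return(list(coefficients = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                deviance = NA_real_, mu = rep(0, length(y)),
                converged = FALSE, flagged = TRUE))
  phi <- dispersion
  eta <- log(pmax(y, 0.5)) # includes offset
  beta <- qr.solve(X, eta - offset)
  eta <- pmin(pmax(as.numeric(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  dev <- nb_deviance(y, mu, phi)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    fit <- qr(X * sw)
    beta <- qr.coef(fit, z * sw)
    beta[is.na(beta)] <- 0
    eta <- pmin(pmax(as.numeric(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    dev_new <- nb_deviance(y, mu, phi)
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(coefficients = setNames(as.numeric(beta), colnames(X)),
       deviance = dev, mu = mu, converged = converged, flagged = FALSE)
}

# Cox-Reid adjusted profile log-likelihood at a given dispersion
apl_at_phi <- function(y, X, offset, phi) {
  fit <- fit_nbglm(y, X, offset, phi, tol = 1e-6, maxit = 50L)
  if (fit$flagged) return(-Inf)
  mu <- pmax(fit$mu, 1e-10)
  ll <- if (phi <= 1e-12) sum(stats::dpois(y, mu, log = TRUE))
        else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  w <- mu / (1 + phi * mu)
  xtx <- crossprod(X * sqrt(w))
  d <- determinant(xtx, logarithm = TRUE)
  ll - 0.5 * as.numeric(d$modulus)
}

#' Estimate dispersions across regions
#'
#' Per region, the dispersion maximizing the Cox-Reid adjusted profile
#' likelihood; a common dispersion (log-scale mean of the per-region
#' estimates); a lowess mean-dispersion trend over log mean count; and
#' shrunken per-region values interpolated on the log scale between the raw
#' estimate (weight `1 - shrinkage`) and the trend (weight `shrinkage`,
#' default 0.3).
#'
#' @param x a [count_matrix()].
#' @param design a [build_design()] result (its `X` and `offsets` are used).
#' @param shrinkage weight on the trend in `[0, 1]`.
#' @param phi_range search range for the per-region estimate.
#' @return List of class `dispersion_estimates`: `common`, `trend`,
#'   `tagwise` (raw), `tagwise_shrunk`, `shrinkage_weight`.
#' @export
estimate_dispersions <- function(x, design, shrinkage = 0.3,
                                 phi_range = c(1e-6, 10)) {
  m <- x$methyl[, design$samples$sample_id, drop = FALSE]
  X <- design$X
  if (nrow(X) <= ncol(X))
    stop("fewer residual degrees of freedom than design columns")
  off <- design$offsets
  n_reg <- nrow(m)
  raw <- vapply(seq_len(n_reg), function(j) {
    y <- m[j, ]
    if (all(y == 0)) return(NA_real_)
    opt <- optimize(function(lp) -apl_at_phi(y, X, off, exp(lp)),
                    interval = log(phi_range), tol = 1e-3)
    exp(opt$minimum)
  }, numeric(1))
  ok <- !is.na(raw)
  common <- exp(mean(log(raw[ok])))
  log_mean <- log(rowMeans(m) + 0.5)
  trend <- raw
  if (sum(ok) >= 2) {
    lo <- lowess(log_mean[ok], log(raw[ok]), f = 0.5)
    trend[ok] <- exp(stats::approx(lo$x, lo$y, xout = log_mean[ok],
                                   rule = 2, ties = mean)$y)
  }
  shrunk <- exp((1 - shrinkage) * log(raw) + shrinkage * log(trend))
  structure(list(common = common, trend = trend, tagwise = raw,
                 tagwise_shrunk = shrunk, shrinkage_weight = shrinkage),
            class = "dispersion_estimates")
}

#' Likelihood-ratio test for one region
#'
#' LRT statistic = reduced deviance - full deviance, referred to chi-square
#' with one degree of freedom; direction of change from the sign of the
#' group coefficient.
#'
#' @param fit_full fit of the design including the group column.
#' @param fit_reduced fit of the same design without the group column.
#' @return List: `log2_fold_change`, `lrt_statistic`, `p_value`, `direction`
#'   (`"increased"` or `"reduced"`).
#' @export
test_contrast <- function(fit_full, fit_reduced) {
  full_names <- names(fit_full$coefficients)
  red_names <- names(fit_reduced$coefficients)
  if (!all(red_names %in% full_names) ||
      !identical(setdiff(full_names, red_names), "group"))
    stop("reduced model must be the full model with the group column removed")
  lrt <- max(fit_reduced$deviance - fit_full$deviance, 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  l2fc <- fit_full$coefficients[["group"]] / log(2)
  list(log2_fold_change = l2fc, lrt_statistic = lrt, p_value = p,
       direction = if (l2fc > 0) "increased" else "reduced")
}

#' Run the differential analysis for a set of contrasts
#'
#' For each contrast: builds the design, estimates (or reuses) dispersions,
#' fits full and reduced NB GLMs per region and performs the
#' likelihood-ratio test. Contrasts with an empty arm in the cohort are
#' skipped with a warning. All-zero regions are flagged and excluded from
#' testing. An optional Benjamini-Hochberg FDR column is appended for
#' reference; DMR calling uses the raw p-value threshold only.
#'
#' @param x a [count_matrix()]; library sizes are its methyl column sums
#'   unless `samples` already has a `library_size` column.
#' @param samples sample sheet (with `spike_enrichment_ratio`; cell
#'   proportion columns are picked up when `cell_proportions` names them).
#' @param contrasts named list as from [default_contrasts()].
#' @param config a [fcd_config()].
#' @param cell_proportions optional character vector of cell covariate
#'   column names in `samples`.
#' @param dispersion optional fixed dispersion (skips estimation).
#' @return `data.frame` of class `dmr_table`: `region_id`, `contrast`,
#'   `log2_fold_change`, `lrt_statistic`, `p_value`, `fdr`, `direction`,
#'   `flagged`.
#' @export
run_all_contrasts <- function(x, samples, contrasts = default_contrasts(),
                              config = fcd_config(), cell_proportions = NULL,
                              dispersion = NULL,
                              covariates = c("age_years", "onset_age_years",
                                             "duration_years", "gender",
                                             "localisation", "tissue",
                                             "combined_risk", "prior_surgery")) {
  if (!"library_size" %in% names(samples)) {
    samples$library_size <- colSums(x$methyl)[samples$sample_id]
  }
  out <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    des <- tryCatch(
      build_design(samples, ct, cell_proportions = cell_proportions,
                   tissue_mode = config$tissue_mode, covariates = covariates),
      error = function(e) e)
    if (inherits(des, "error")) {
      warning("skipping contrast ", nm, ": ", conditionMessage(des))
      next
    }
    m <- x$methyl[, des$samples$sample_id, drop = FALSE]
    phi <- if (is.null(dispersion)) {
      disp <- tryCatch(
        estimate_dispersions(x = subset_counts(x, j = des$samples$sample_id),
                             design = des,
                             shrinkage = config$dispersion_shrinkage),
        error = function(e) e)
      if (inherits(disp, "error")) {
        warning("skipping contrast ", nm, ": ", conditionMessage(disp))
        next
      }
      ifelse(is.na(disp$tagwise_shrunk), disp$common, disp$tagwise_shrunk)
    } else rep(dispersion, nrow(m))
    res <- lapply(seq_len(nrow(m)), function(j) {
      y <- m[j, ]
      if (all(y == 0))
        return(list(log2_fold_change = NA_real_, lrt_statistic = NA_real_,
                    p_value = NA_real_, direction = NA_character_,
                    flagged = TRUE))
      ff <- fit_nbglm(y, des$X, des$offsets, phi[j])
      fr <- fit_nbglm(y, des$X0, des$offsets, phi[j])
      c(test_contrast(ff, fr), flagged = FALSE)
    })
    out[[nm]] <- data.frame(
      region_id = x$regions$region_id,
      contrast = nm,
      log2_fold_change = vapply(res, `[[`, numeric(1), "log2_fold_change"),
      lrt_statistic = vapply(res, `[[`, numeric(1), "lrt_statistic"),
      p_value = vapply(res, `[[`, numeric(1), "p_value"),
      direction = vapply(res, `[[`, character(1), "direction"),
      flagged = vapply(res, `[[`, logical(1), "flagged"),
      stringsAsFactors = FALSE)
    out[[nm]]$fdr <- stats::p.adjust(out[[nm]]$p_value, method = "BH")
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  class(tbl) <- c("dmr_table", "data.frame")
  tbl
}

#' Count DMRs by direction per contrast
#'
#' @param dmr_table output of [run_all_contrasts()].
#' @param p_max DMR p-value threshold (strict; default 0.01).
#' @return `data.frame` with `contrast`, `increased`, `reduced`, `total`.
#' @export
dmr_counts <- function(dmr_table, p_max = 0.01) {
  sig <- dmr_table[!dmr_table$flagged & !is.na(dmr_table$p_value) &
                     dmr_table$p_value < p_max, ]
  ctr <- unique(dmr_table$contrast)
  data.frame(
    contrast = ctr,
    increased = vapply(ctr, function(ct)
      sum(sig$contrast == ct & sig$direction == "increased"), numeric(1)),
    reduced = vapply(ctr, function(ct)
      sum(sig$contrast == ct & sig$direction == "reduced"), numeric(1)),
    total = vapply(ctr, function(ct) sum(sig$contrast == ct), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
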