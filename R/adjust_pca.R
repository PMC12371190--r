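# Normalization, covariate residualization and PCA diagnostics.
#
# Counts are placed on a log2 counts-per-million scale with spike-adjusted
# effective library sizes; nuisance covariates are removed by per-region
# ordinary least squares (the linear surrogate, on the normalized scale, of
# the GLM adjustment used for testing); principal components and
# PC-covariate association strengths summarize what drives the variance.

#' Log2 counts-per-million with spike-adjusted library sizes
#'
#' `value = log2((count + pseudocount) / (library_size * spike_ratio) * 1e6)`.
#' With `use_spike = FALSE` the spike ratio is taken as 1 for every sample.
#'
#' @param x a [count_matrix()].
#' @param samples sample sheet carrying `spike_enrichment_ratio` (matched by
#'   sample id); only needed when `use_spike = TRUE`.
#' @param use_spike divide library sizes by the per-sample spike enrichment
#'   ratio (technical-efficiency adjustment).
#' @param pseudocount added to every count (default 0.5).
#' @param library_sizes optional vector; defaults to methyl column sums.
#' @return List of class `normalized_matrix`: `values` (regions x samples),
#'   `library_sizes`, `spike_adjusted`.
#' @export
logcpm <- function(x, samples = NULL, use_spike = TRUE, pseudocount = 0.5,
                   library_sizes = NULL) {
  if (is.null(library_sizes)) library_sizes <- colSums(x$methyl)
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  spike <- rep(1, ncol(x$methyl))
  if (use_spike) {
    if (is.null(samples)) stop("samples needed for spike adjustment")
    idx <- match(colnames(x$methyl), samples$sample_id)
    if (anyNA(idx)) stop("sample ids missing from sample sheet")
    spike <- samples$spike_enrichment_ratio[idx]
    if (anyNA(spike) || any(spike <= 0)) stop("invalid spike_enrichment_ratio")
  }
  eff <- library_sizes * spike
  vals <- log2(sweep(x$methyl + pseudocount, 2, eff, "/") * 1e6)
  structure(list(values = vals, library_sizes = library_sizes,
                 spike_adjusted = use_spike),
            class = "normalized_matrix")
}

covariate_model_matrix <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  cols <- list(`(Intercept)` = rep(1, nrow(covariates)))
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.numeric(x) || is.logical(x)) {
      x <- as.numeric(x)
      if (anyNA(x)) x[is.na(x)] <- median(x, na.rm = TRUE)
      cols[[nm]] <- x
    } else {
      x <- as.character(x)
      if (anyNA(x)) {
        tb <- sort(table(x[!is.na(x)]), decreasing = TRUE)
        x[is.na(x)] <- names(tb)[1]
      }
      for (l in sort(unique(x))[-1])
        cols[[paste0(nm, l)]] <- as.numeric(x == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Remove nuisance covariates from a normalized matrix
#'
#' Per region, fits an ordinary least-squares model on all covariates except
#' those in `keep` and returns residuals plus the region's grand mean.
#' Aliased nuisance columns are dropped (QR pivoting) with a message. The
#' operation is idempotent.
#'
#' @param norm a [logcpm()] result.
#' @param covariates `data.frame`, rows aligned to the matrix's samples.
#' @param keep covariate names to leave untouched (excluded from the
#'   nuisance design).
#' @return A `normalized_matrix` of residualized values.
#' @export
residualize <- function(norm, covariates, keep = character()) {
  V <- norm$values
  stopifnot(nrow(covariates) == ncol(V))
  nuisance <- covariates[, setdiff(names(covariates), keep), drop = FALSE]
  if (ncol(nuisance) == 0) return(norm)
  X <- covariate_model_matrix(nuisance)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[-sort(qx$pivot[seq_len(qx$rank)])]
    message("residualize: dropping aliased columns: ",
            paste(drop_cols, collapse = ", "))
    X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
    qx <- qr(X)
  }
  # project each region (row of V) off the column space of X
  fitted <- t(qr.fitted(qx, t(V)))
  res <- V - fitted + rowMeans(V)
  structure(list(values = res, library_sizes = norm$library_sizes,
                 spike_adjusted = norm$spike_adjusted),
            class = "normalized_matrix")
}

#' Principal component analysis of a normalized matrix
#'
#' Regions (rows) are centered and by default scaled to unit variance;
#' samples are the observations. Deterministic sign convention: within each
#' component the loading with the largest magnitude is positive.
#'
#' @param norm a [logcpm()] (or [residualize()]) result, or a bare matrix.
#' @param n_components number of components to keep (clipped with a warning
#'   when larger than the matrix allows).
#' @param scale scale regions to unit variance before decomposition.
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `loadings` (regions x components), `variance_fraction`.
#' @export
meth_pca <- function(norm, n_components = 6, scale = TRUE) {
  V <- if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
  if (ncol(V) < 2) stop("need at least 2 samples")
  Vc <- V - rowMeans(V)
  if (scale) {
    s <- apply(Vc, 1, sd)
    s[s == 0 | is.na(s)] <- 1
    Vc <- Vc / s
  }
  X <- t(Vc)  # samples x regions
  sv <- svd(X)
  kmax <- max(1, sum(sv$d > sv$d[1] * 1e-12))  # keep >= 1 even when degenerate
  if (n_components > kmax) {
    warning("n_components clipped to ", kmax)
    n_components <- kmax
  }
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, k, drop = FALSE] %*% diag(sv$d[k], length(k)),
                  2, flip, "*")
  loadings <- sweep(sv$v[, k, drop = FALSE], 2, flip, "*")
  rownames(scores) <- colnames(V)
  rownames(loadings) <- rownames(V)
  colnames(scores) <- colnames(loadings) <- paste0("PC", k)
  total_var <- sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = if (total_var > 0) sv$d[k]^2 / total_var
                                     else rep(0, length(k)),
                 singular_values = sv$d),
            class = "pca_result")
}

#' Association between principal components and covariates
#'
#' Numeric covariates: absolute Pearson correlation with each PC score.
#' Categorical covariates: the correlation ratio (square root of the
#' between-group variance fraction from a one-way ANOVA). All values lie in
#' `[0, 1]`; constant covariates get 0 with a warning.
#'
#' @param pca a [meth_pca()] result.
#' @param covariates `data.frame`, rows aligned to the score rows.
#' @param n_pcs number of leading components to report (default 6).
#' @return Numeric matrix, covariates x components.
#' @export
pc_covariate_correlation <- function(pca, covariates, n_pcs = 6) {
  n_pcs <- min(n_pcs, ncol(pca$scores))
  S <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  out <- matrix(NA_real_, ncol(covariates), n_pcs,
                dimnames = list(names(covariates), colnames(S)))
  for (i in seq_along(covariates)) {
    x <- covariates[[i]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      warning("constant covariate: ", names(covariates)[i])
      out[i, ] <- 0
      next
    }
    for (j in seq_len(n_pcs)) {
      s <- S[ok, j]
      if (is.numeric(x)) {
        out[i, j] <- abs(stats::cor(x[ok], s))
      } else {
        g <- factor(x[ok])
        ss_tot <- sum((s - mean(s))^2)
        gm <- tapply(s, g, mean)
        ss_between <- sum(tabulate(g) * (gm - mean(s))^2)
        out[i, j] <- if (ss_tot > 0) sqrt(ss_between / ss_tot) else 0
      }
    }
  }
  out
}
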