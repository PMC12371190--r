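# Reference-based leukocyte deconvolution: project each blood sample's
# marker-region signal onto a cell-type reference under non-negativity and
# sum-to-at-most-one constraints. The quadratic program is solved exactly by
# enumerating active sets over the k + 1 inequality constraints and checking
# the Karush-Kuhn-Tucker conditions, which is cheap for the handful of cell
# types this assay resolves.

#' Construct a cell-type reference
#'
#' @param profile numeric matrix, marker regions x cell types, of expected
#'   normalized signal (counts-per-million scale) in each pure cell type.
#' @param cell_types optional cell type names (default: column names, or
#'   B_cell/T_cell/monocyte for a three-column profile, tagged by the
#'   canonical markers CD19, CD3D and CD14).
#' @param marker_regions optional marker region ids (default: row names).
#' @return Object of class `cell_type_reference`.
#' @export
cell_type_reference <- function(profile, cell_types = NULL,
                                marker_regions = NULL) {
  profile <- as.matrix(profile)
  if (is.null(cell_types)) {
    cell_types <- colnames(profile)
    if (is.null(cell_types) && ncol(profile) == 3)
      cell_types <- c("B_cell", "T_cell", "monocyte")
    if (is.null(cell_types)) cell_types <- paste0("cell_type_", seq_len(ncol(profile)))
  }
  if (is.null(marker_regions)) {
    marker_regions <- rownames(profile)
    if (is.null(marker_regions))
      marker_regions <- paste0("marker_", seq_len(nrow(profile)))
  }
  stopifnot(length(cell_types) == ncol(profile),
            length(marker_regions) == nrow(profile))
  if (nrow(profile) < ncol(profile))
    stop("need at least as many marker regions as cell types")
  if (qr(profile)$rank < ncol(profile))
    stop("reference profile is rank-deficient; estimation refused")
  dimnames(profile) <- list(marker_regions, cell_types)
  structure(list(profile = profile, cell_types = cell_types,
                 marker_regions = marker_regions),
            class = "cell_type_reference")
}

# exact QP: minimize ||y - P w||^2 s.t. w >= 0, sum(w) <= 1.
# Enumerate subsets of active constraints; for each, solve the
# equality-constrained normal equations and keep KKT-feasible solutions.
solve_simplex_ls <- function(P, y) {
  # normalize the problem scale so the KKT tolerances are meaningful for
  # signals of any magnitude (the solution is scale-invariant)
  s <- max(abs(P))
  if (s > 0) { P <- P / s; y <- y / s }
  k <- ncol(P)
  Q <- crossprod(P)          # k x k
  c0 <- crossprod(P, y)      # gradient of 1/2||y-Pw||^2 is Qw - c0
  ones <- rep(1, k)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^k - 1)) {
    zero_set <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    for (sum_active in c(FALSE, TRUE)) {
      free <- setdiff(seq_len(k), zero_set)
      w <- numeric(k)
      lam_sum <- 0
      if (length(free) == 0) {
        if (sum_active) next  # sum(w)=1 impossible with all w = 0
      } else if (!sum_active) {
        w[free] <- tryCatch(solve(Q[free, free, drop = FALSE], c0[free]),
                            error = function(e) rep(NA_real_, length(free)))
      } else {
        # KKT: [Q_ff 1; 1' 0] [w_f; lam] = [c0_f; 1]
        A <- rbind(cbind(Q[free, free, drop = FALSE], 1), c(rep(1, length(free)), 0))
        sol <- tryCatch(solve(A, c(c0[free], 1)),
                        error = function(e) rep(NA_real_, length(free) + 1))
        w[free] <- sol[seq_along(free)]
        lam_sum <- sol[length(free) + 1]
      }
      if (anyNA(w)) next
      # primal feasibility
      if (any(w[free] < -1e-8) || sum(w) > 1 + 1e-8) next
      # dual feasibility: multipliers for active w_i = 0 constraints
      grad <- as.numeric(Q %*% w - c0) + lam_sum
      if (length(zero_set) && any(grad[zero_set] < -1e-8)) next
      if (sum_active && lam_sum < -1e-8) next
      obj <- sum((y - P %*% w)^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- pmax(w, 0)
      }
    }
  }
  if (is.null(best)) stop("constrained projection failed to find a KKT point")
  best
}

#' Estimate cell-type proportions for one sample
#'
#' Solves `argmin || y - P w ||^2` subject to `w >= 0` and `sum(w) <= 1`,
#' where `P` is the reference profile. The inequality in the sum constraint
#' leaves room for cell types absent from the reference.
#'
#' @param y numeric marker-signal vector aligned to the reference marker
#'   order (counts-per-million scale).
#' @param reference a [cell_type_reference()].
#' @return List of class `cell_proportions`: `weights` (named, non-negative,
#'   summing to at most 1) and `residual_norm`.
#' @export
estimate_proportions <- function(y, reference) {
  stopifnot(inherits(reference, "cell_type_reference"))
  P <- reference$profile
  if (length(y) != nrow(P))
    stop("marker mismatch: y has ", length(y), " values, reference has ",
         nrow(P), " markers")
  if (!is.null(names(y)) &&
      !identical(names(y), reference$marker_regions))
    stop("marker mismatch: names of y do not match reference marker order")
  w <- solve_simplex_ls(P, as.numeric(y))
  names(w) <- reference$cell_types
  structure(list(weights = w,
                 residual_norm = sqrt(sum((y - P %*% w)^2))),
            class = "cell_proportions")
}

#' Estimate proportions for every blood sample in a matrix
#'
#' @param Y numeric matrix, markers x samples.
#' @param reference a [cell_type_reference()].
#' @return `data.frame` with `sample_id`, one column per cell type, and
#'   `residual_norm`.
#' @export
estimate_proportions_matrix <- function(Y, reference) {
  Y <- as.matrix(Y)
  res <- lapply(seq_len(ncol(Y)), function(j)
    estimate_proportions(Y[, j], reference))
  W <- do.call(rbind, lapply(res, function(r) r$weights))
  out <- data.frame(sample_id = colnames(Y), W,
                    residual_norm = vapply(res, function(r) r$residual_norm,
                                           numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach cell proportions to a sample table as model covariates
#'
#' Every blood sample must have an estimate; brain samples receive the fixed
#' reference level (all-zero cell covariates) so that the joint brain/blood
#' model has complete rows while the correction acts on blood only.
#'
#' @param samples sample-sheet `data.frame`.
#' @param proportions output of [estimate_proportions_matrix()].
#' @return `samples` with one numeric column per cell type appended.
#' @export
attach_proportions <- function(samples, proportions) {
  cell_cols <- setdiff(names(proportions), c("sample_id", "residual_norm"))
  blood <- samples$sample_id[samples$tissue == "blood"]
  missing <- setdiff(blood, proportions$sample_id)
  if (length(missing))
    stop("no cell-proportion estimate for blood sample(s): ",
         paste(missing, collapse = ", "))
  out <- samples
  for (cc in cell_cols) out[[cc]] <- 0
  idx <- match(samples$sample_id, proportions$sample_id)
  is_blood <- samples$tissue == "blood"
  for (cc in cell_cols)
    out[[cc]][is_blood] <- proportions[[cc]][idx[is_blood]]
  out
}
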