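# ROC-based biomarker selection.
#
# Per-region AUCs by Mann-Whitney pair counting, AUC/CpG filtering of DMRs,
# the three-contrast intersection that defines the subtype panel, a
# stepwise-AIC clinical-factor model, exhaustive combinatorial ROC ranking
# of marker subsets with and without the clinical score, and permutation
# p-values for AUCs.

#' Area under the ROC curve for one region
#'
#' `A = (number of case > control pairs + 0.5 * ties) / (n_case * n_control)`,
#' computed by midranks. The reported AUC is `max(A, 1 - A)` with an
#' orientation flag recording which direction achieved it.
#'
#' @param values_case,values_control numeric vectors (both non-empty).
#' @return List of class `roc_result`: `auc` (in `[0.5, 1]`), `orientation`
#'   (`"case_high"` or `"case_low"`), `auc_raw` (the unoriented `A`),
#'   `n_case`, `n_control`.
#' @export
region_auc <- function(values_case, values_control) {
  n1 <- length(values_case); n2 <- length(values_control)
  if (n1 == 0 || n2 == 0) stop("both arms must be non-empty")
  r <- rank(c(values_case, values_control))
  a <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  structure(list(auc = max(a, 1 - a),
                 orientation = if (a >= 0.5) "case_high" else "case_low",
                 auc_raw = a, n_case = n1, n_control = n2),
            class = "roc_result")
}

#' AUC for every region of a value matrix
#'
#' @param values regions x samples numeric matrix.
#' @param is_case logical vector over samples.
#' @return `data.frame`: `region_id`, `auc`, `orientation`.
#' @export
region_auc_matrix <- function(values, is_case) {
  res <- lapply(seq_len(nrow(values)), function(j)
    region_auc(values[j, is_case], values[j, !is_case]))
  data.frame(region_id = rownames(values),
             auc = vapply(res, `[[`, numeric(1), "auc"),
             orientation = vapply(res, `[[`, character(1), "orientation"),
             stringsAsFactors = FALSE)
}

#' Filter DMRs into biomarker candidates
#'
#' Keeps regions that are significant in the contrast (`p < p_max`), have
#' AUC strictly greater than `auc_min` and CpG count strictly greater than
#' `cpg_min` (defaults 0.65 and 4, i.e. at least five CpG sites).
#'
#' @param dmr_table DMR rows for one contrast (`region_id`, `p_value`).
#' @param auc_table from [region_auc_matrix()] for the same contrast.
#' @param cpg_counts named vector of CpG counts per region id; every
#'   candidate must have one (annotation precedes selection).
#' @param auc_min,cpg_min,p_max thresholds (all strict).
#' @return Filtered `data.frame` with `region_id`, `p_value`, `auc`,
#'   `cpg_count`.
#' @export
select_dmr_biomarkers <- function(dmr_table, auc_table, cpg_counts,
                                  auc_min = 0.65, cpg_min = 4, p_max = 0.01) {
  tbl <- merge(dmr_table[, c("region_id", "p_value")],
               auc_table[, c("region_id", "auc")], by = "region_id")
  if (any(!tbl$region_id %in% names(cpg_counts)))
    stop("missing cpg_count for some regions; annotate before selection")
  tbl$cpg_count <- cpg_counts[tbl$region_id]
  keep <- !is.na(tbl$p_value) & tbl$p_value < p_max &
    tbl$auc > auc_min & tbl$cpg_count > cpg_min
  out <- tbl[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect the three subtype contrasts into a biomarker panel
#'
#' Given candidate sets from FCD IIa vs others (A), FCD IIb vs others (B)
#' and FCD IIb vs IIa (C): `IIa_defining = (A intersect C) minus B`,
#' `IIb_defining = (B intersect C) minus A`, and `IIb_vs_IIa_top` is the
#' single region of `A intersect B intersect C` with the highest
#' IIb-vs-IIa AUC (ties broken by CpG count, then region id); when the
#' triple intersection is empty the top class is absent.
#'
#' @param panel_iia,panel_iib,panel_iib_iia `data.frame`s from
#'   [select_dmr_biomarkers()] (must have `region_id`, `auc`; `cpg_count`
#'   used for tie-breaks).
#' @return `data.frame` of class `biomarker_panel`: `region_id`, `class`
#'   (IIa_defining / IIb_defining / IIb_vs_IIa_top), plus per-contrast AUCs
#'   where available.
#' @export
intersect_contrasts <- function(panel_iia, panel_iib, panel_iib_iia) {
  A <- panel_iia$region_id; B <- panel_iib$region_id; C <- panel_iib_iia$region_id
  iia_def <- setdiff(intersect(A, C), B)
  iib_def <- setdiff(intersect(B, C), A)
  triple <- Reduce(intersect, list(A, B, C))
  top <- character()
  if (length(triple)) {
    cand <- panel_iib_iia[panel_iib_iia$region_id %in% triple, , drop = FALSE]
    cpg <- if ("cpg_count" %in% names(cand)) cand$cpg_count else rep(0, nrow(cand))
    ord <- order(-cand$auc, -cpg, cand$region_id)
    top <- cand$region_id[ord[1]]
  }
  ids <- c(iia_def, iib_def, top)
  cls <- c(rep("IIa_defining", length(iia_def)),
           rep("IIb_defining", length(iib_def)),
           rep("IIb_vs_IIa_top", length(top)))
  out <- data.frame(region_id = ids, class = cls, stringsAsFactors = FALSE)
  add_auc <- function(out, panel, nm) {
    out[[nm]] <- panel$auc[match(out$region_id, panel$region_id)]
    out
  }
  out <- add_auc(out, panel_iia, "auc_IIa_vs_others")
  out <- add_auc(out, panel_iib, "auc_IIb_vs_others")
  out <- add_auc(out, panel_iib_iia, "auc_IIb_vs_IIa")
  class(out) <- c("biomarker_panel", "data.frame")
  out
}

# ridge-penalized logistic IRLS, used when glm meets perfect separation
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- pmin(pmax(as.numeric(X %*% beta), -30), 30)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
    beta_new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' Stepwise-AIC logistic model of clinical factors
#'
#' Bidirectional stepwise search (one add or drop per step) from the full
#' logistic model over `scope`, minimizing AIC, deterministic given input
#' order. On perfect separation the final coefficients are refitted with a
#' ridge penalty of 1e-6 and a warning is logged.
#'
#' @param outcome binary (0/1 or logical) vector.
#' @param covariates `data.frame` of candidate covariates.
#' @param scope covariate names to search over (default: all columns).
#' @return List of class `clinical_model`: `selected_covariates`,
#'   `coefficients`, `aic`, `linear_predictor`, `model` (the glm fit).
#' @export
stepwise_aic_logistic <- function(outcome, covariates, scope = names(covariates)) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  dat <- cbind(data.frame(.y = y), covariates[, scope, drop = FALSE])
  if (length(scope) == 0) {
    fit <- glm(.y ~ 1, data = dat, family = binomial())
    return(structure(list(selected_covariates = character(),
                          coefficients = coef(fit), aic = fit$aic,
                          linear_predictor = predict(fit), model = fit),
                     class = "clinical_model"))
  }
  full <- suppressWarnings(
    glm(stats::reformulate(scope, ".y"), data = dat, family = binomial()))
  sel <- suppressWarnings(
    MASS::stepAIC(full, direction = "both", trace = 0,
                  scope = list(lower = .y ~ 1,
                               upper = stats::reformulate(scope, ".y"))))
  separated <- any(fitted(sel) > 1 - 1e-8) || any(fitted(sel) < 1e-8)
  coefs <- coef(sel)
  lp <- as.numeric(predict(sel))
  if (separated) {
    warning("perfect separation; coefficients refitted with ridge penalty 1e-6")
    X <- model.matrix(sel)
    coefs <- setNames(ridge_logistic(X, y), colnames(X))
    lp <- as.numeric(X %*% coefs)
  }
  vars <- attr(stats::terms(sel), "term.labels")
  structure(list(selected_covariates = vars, coefficients = coefs,
                 aic = sel$aic, linear_predictor = lp, model = sel),
            class = "clinical_model")
}

youden_accuracy <- function(score, y) {
  thr <- sort(unique(score))
  cuts <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  best_j <- -Inf; best_acc <- NA_real_
  for (cu in cuts) {
    pred <- score > cu
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_acc <- mean((pred & y == 1) | (!pred & y == 0))
    }
  }
  best_acc
}

fit_combo_score <- function(X, y) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  fit <- suppressWarnings(glm(y ~ ., data = cbind(data.frame(y = y), df),
                              family = binomial()))
  as.numeric(predict(fit))
}

#' Combinatorial ROC ranking of biomarker subsets
#'
#' Enumerates every non-empty subset of the panel features up to
#' `max_subset_size`, each evaluated with and without the clinical score as
#' an extra feature. Each combination is scored by an in-sample logistic
#' fit; AUC comes from [region_auc()] on the fitted score and accuracy from
#' the Youden-optimal threshold. Results are ranked by AUC, ties by
#' accuracy.
#'
#' @param features_matrix samples x features numeric matrix (panel members).
#' @param outcome binary vector (1 = case).
#' @param clinical_score optional per-sample clinical linear predictor; when
#'   `NULL` only the without-clinical combinations are produced.
#' @param max_subset_size largest subset enumerated (default 3).
#' @param enumeration_cap hard cap on the number of combinations; exceeding
#'   it is an error instructing to lower `max_subset_size`.
#' @return `data.frame` ranked by AUC: `combo_id`, `features`,
#'   `includes_clinical`, `n_features`, `auc`, `accuracy`.
#' @export
combinatorial_roc <- function(features_matrix, outcome, clinical_score = NULL,
                              max_subset_size = 3, enumeration_cap = 20000) {
  X <- as.matrix(features_matrix)
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  m <- ncol(X)
  if (m == 0) stop("empty panel")
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(m))
  kmax <- min(max_subset_size, m)
  n_subsets <- sum(choose(m, seq_len(kmax)))
  n_total <- n_subsets * (if (is.null(clinical_score)) 1 else 2)
  if (n_total > enumeration_cap)
    stop(n_total, " combinations exceed the cap (", enumeration_cap,
         "); lower max_subset_size")
  rows <- vector("list", n_total)
  i <- 0
  for (k in seq_len(kmax)) {
    sets <- combn(m, k, simplify = FALSE)
    for (s in sets) {
      for (with_cf in (if (is.null(clinical_score)) FALSE else c(FALSE, TRUE))) {
        Xs <- X[, s, drop = FALSE]
        if (with_cf) Xs <- cbind(Xs, clinical = clinical_score)
        score <- fit_combo_score(Xs, y)
        roc <- region_auc(score[y == 1], score[y == 0])
        i <- i + 1
        rows[[i]] <- data.frame(
          features = paste(colnames(X)[s], collapse = "+"),
          includes_clinical = with_cf,
          n_features = k,
          auc = roc$auc,
          accuracy = youden_accuracy(score, y),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, -out$accuracy), ]
  out$combo_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("combo_id", "features", "includes_clinical", "n_features",
          "auc", "accuracy")]
}

#' Permutation p-value for an observed AUC
#'
#' Null distribution by label permutation: `p = (k + 1) / (n_boot + 1)`
#' where `k` counts permuted (oriented) AUCs at least as large as the
#' observed one. The +1 smoothing keeps p strictly inside (0, 1].
#'
#' @param score numeric classifier score.
#' @param outcome binary vector with both classes present.
#' @param n_boot number of permutations (>= 200).
#' @param seed integer seed.
#' @return List: `p_value`, `auc_observed`, `n_boot`.
#' @export
bootstrap_auc_pvalue <- function(score, outcome, n_boot = 999, seed = 1) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (n_boot < 200) stop("n_boot must be at least 200")
  obs <- region_auc(score[y == 1], score[y == 0])$auc
  k <- with_seed(seed, {
    sum(vapply(seq_len(n_boot), function(b) {
      yp <- sample(y)
      region_auc(score[yp == 1], score[yp == 0])$auc >= obs
    }, logical(1)))
  })
  list(p_value = (k + 1) / (n_boot + 1), auc_observed = obs, n_boot = n_boot)
}
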