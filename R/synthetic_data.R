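# Synthetic cohorts with the statistical structure the analysis assumes:
# NB-distributed region counts under a log-link covariate model with
# spike-in/library-size offsets, subtype-specific DMR effects, leukocyte
# mixtures in blood, per-sample peak calls, and Methyl-qPCR plates.

#' Simulation configuration
#'
#' Defaults mirror the discovery study design: group sizes from the
#' 21-patient clinical table (Ia 1, IIa 4, IIb 4, IIIa 3, IIId 1, mMCD 2,
#' MOGHE 3, PMG 1, non-MCD 2), every subject paired brain/blood, library
#' sizes log-normal around a median depth of 83 million reads scaled down by
#' `depth_scale` (default 1e4) so desk-scale runs keep the relative count
#' structure, negative-binomial dispersion 0.2 (variance = mu + phi * mu^2),
#' and a DMR effect of 1 on the log2 scale. Covariate effects are drawn
#' per region from mean-zero normals with the standard deviations in
#' `covariate_sd` (log2 scale); tissue is deliberately the dominant nuisance
#' axis, as in real brain/blood methylomes.
#'
#' @param ... named overrides.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_subjects_per_group = c(Ia = 1, IIa = 4, IIb = 4, IIIa = 3, IIId = 1,
                             mMCD = 2, MOGHE = 3, PMG = 1, nonMCD = 2),
    paired_fraction = 1,
    n_regions = 2000L,
    n_marker_regions = 50L,
    n_dmr_per_contrast = 100L,
    truth_contrasts = c("IIa_vs_others", "IIb_vs_others", "IIb_vs_IIa"),
    dmr_log2_effect = 1.0,
    baseline_log_mean_range = c(log(20), log(200)),
    dispersion = 0.2,
    covariate_sd = c(tissue = 0.35, gender = 0.07, age = 0.003,
                     combined_risk = 0.07),
    cell_types = c("B_cell", "T_cell", "monocyte"),
    cell_alpha = c(2, 5, 3),
    marker_high = 8,
    marker_low = 0.5,
    n_graded_regions = 0L,
    spike_ratio_range = c(0.8, 1.25),
    depth_scale = 1e4,
    library_size_sdlog = 0.25,
    input_attenuation = 5,
    region_width_range = c(200L, 1000L),
    n_chromosomes = 3L,
    peak_emit_prob = 0.7,
    peak_jitter = 50L,
    n_decoy_peaks = 200L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim_config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (cfg$n_regions < cfg$n_dmr_per_contrast)
    stop("n_regions must be >= n_dmr_per_contrast")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# run expr under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Simulate a cohort sample sheet
#'
#' Draws subjects per classification group, pairs brain and blood samples at
#' `paired_fraction`, and fills clinical covariates from documented
#' distributions: onset age gamma(1.5, scale 8) years, epilepsy duration
#' gamma(3, scale 9) years, age at surgery = onset + duration, 62% female,
#' each of the five risk factors independently at 12%, prior surgery at 15%,
#' spike-in enrichment ratio uniform over `spike_ratio_range`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A sample-sheet `data.frame` as from [read_sample_sheet()].
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    groups <- config$n_subjects_per_group
    groups <- groups[groups > 0]
    rows <- list()
    sidx <- 0
    for (g in names(groups)) {
      for (k in seq_len(groups[[g]])) {
        sidx <- sidx + 1
        sid <- sprintf("S%03d", sidx)
        paired <- runif(1) < config$paired_fraction
        tissues <- if (paired) c("brain", "blood") else
          sample(c("brain", "blood"), 1)
        onset <- round(rgamma(1, shape = 1.5, scale = 8), 1)
        duration <- round(rgamma(1, shape = 3, scale = 9), 1)
        rf <- RISK_FACTOR_LEVELS[runif(5) < 0.12]
        for (t in tissues) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = paste0(sid, "_", t),
            subject_id = sid,
            tissue = t,
            classification = g,
            gender = if (runif(1) < 0.62) "F" else "M",
            age_years = onset + duration,
            onset_age_years = onset,
            duration_years = duration,
            laterality = sample(c("L", "R"), 1),
            localisation = sample(c("F", "T", "P", "TPO", "PO"), 1,
                                  prob = c(.45, .33, .1, .06, .06)),
            engel = sample(c("1A", "1B", "2", "3", "4"), 1,
                           prob = c(.55, .1, .15, .1, .1)),
            mri_positive = runif(1) < 0.75,
            risk_factors = if (length(rf)) paste(rf, collapse = ";") else NA,
            prior_surgery = runif(1) < 0.15,
            spike_enrichment_ratio = runif(1, config$spike_ratio_range[1],
                                           config$spike_ratio_range[2]),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    # gender is a subject property: copy the brain draw to the blood row
    df <- do.call(rbind, rows)
    first <- !duplicated(df$subject_id)
    df$gender <- df$gender[match(df$subject_id, df$subject_id[first])]
    df$combined_risk <- !is.na(df$risk_factors)
    rownames(df) <- NULL
    df
  })
}

#' Simulate consensus-region coordinates
#'
#' Non-overlapping regions laid left to right across `n_chromosomes`
#' chromosomes with widths uniform over `region_width_range` and random gaps.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return `data.frame` with `chrom`, `start`, `end`, `region_id`.
#' @export
simulate_regions <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    n <- config$n_regions
    chrom <- sort(sample(paste0("chr", seq_len(config$n_chromosomes)), n,
                         replace = TRUE))
    widths <- sample(config$region_width_range[1]:config$region_width_range[2],
                     n, replace = TRUE)
    gaps <- sample(500:5000, n, replace = TRUE)
    start <- integer(n)
    pos <- 0
    for (i in seq_len(n)) {
      if (i > 1 && chrom[i] != chrom[i - 1]) pos <- 0
      pos <- pos + gaps[i]
      start[i] <- pos
      pos <- pos + widths[i]
    }
    data.frame(chrom = chrom, start = start, end = start + widths,
               region_id = sprintf("region_%04d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

# case classifications for the named truth contrasts
contrast_case_set <- function(name) {
  switch(name,
    FCD_vs_others    = FCD_CLASSES,
    IIa_vs_others    = "IIa",
    IIb_vs_others    = "IIb",
    IIb_vs_IIa       = "IIb",
    Ia_vs_otherFCD   = "Ia",
    FCDII_vs_otherFCD  = c("IIa", "IIb"),
    FCDIII_vs_otherFCD = c("IIIa", "IIId"),
    IIIa_vs_IIId     = "IIIa",
    stop("unknown truth contrast: ", name))
}

#' Simulate region-by-sample counts with ground truth
#'
#' The generative model mirrors the differential model the pipeline fits:
#' methyl count for region j in sample i is negative binomial with
#' log mu_ij = b0_j + log2-scale covariate effects + DMR effect (if region j
#' is a truth DMR for a contrast whose case set contains sample i's
#' classification) + log(library_size_i * spike_enrichment_ratio_i / L0),
#' variance mu + phi * mu^2. The first `n_marker_regions` regions are
#' leukocyte marker loci: in blood samples their rate is additionally scaled
#' by the sample's true cell-type mixture applied to a cell-type profile, so
#' the deconvolution module can recover the mixture. Input-fraction counts
#' are simulated without group or cell effects at `1/input_attenuation` of
#' the baseline rate.
#'
#' @param samples sample sheet from [simulate_cohort()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `simulated_cohort`: `samples`, `counts`
#'   ([count_matrix()]), `truth` (`region_id`, `label` = "marker", "null"
#'   or a contrast name, `direction` = +1/-1/0, `log2_effect`),
#'   `cell_proportions_truth` (blood samples x cell types),
#'   `cell_reference` (markers x cell types, expected counts-per-million),
#'   `library_sizes`.
#' @export
simulate_counts <- function(samples, config = sim_config(), seed = 1) {
  stopifnot(nrow(samples) > 0)
  with_seed(seed, {
    n_reg <- config$n_regions
    n_s <- nrow(samples)
    regions <- simulate_regions(config, seed = seed + 1)

    # truth labels: markers first, then disjoint DMR blocks per contrast
    label <- rep("null", n_reg)
    direction <- rep(0L, n_reg)
    n_mark <- config$n_marker_regions
    if (n_mark > 0) label[seq_len(n_mark)] <- "marker"
    free <- setdiff(seq_len(n_reg), seq_len(n_mark))
    eff <- config$dmr_log2_effect
    if (eff != 0 && config$n_dmr_per_contrast > 0) {
      for (ct in config$truth_contrasts) {
        if (length(free) < config$n_dmr_per_contrast)
          stop("not enough regions for the requested truth DMRs")
        pick <- free[seq_len(config$n_dmr_per_contrast)]
        free <- setdiff(free, pick)
        label[pick] <- ct
        direction[pick] <- sample(c(-1L, 1L), length(pick), replace = TRUE)
      }
    }
    # graded regions: methylation gained in both type II subtypes, twice as
    # strongly in IIb, so they separate IIa and IIb from others AND IIb from
    # IIa (the triple-intersection "top marker" situation)
    if (eff != 0 && config$n_graded_regions > 0) {
      if (length(free) < config$n_graded_regions)
        stop("not enough regions for the requested graded truth regions")
      pick <- free[seq_len(config$n_graded_regions)]
      free <- setdiff(free, pick)
      label[pick] <- "graded_II"
      direction[pick] <- 1L
    }

    L0 <- 83e6 / config$depth_scale
    lib <- exp(rnorm(n_s, log(L0), config$library_size_sdlog))
    spike <- samples$spike_enrichment_ratio
    if (anyNA(spike)) stop("samples need spike_enrichment_ratio")

    b0 <- runif(n_reg, config$baseline_log_mean_range[1],
                config$baseline_log_mean_range[2])
    # per-region nuisance coefficients, log2 scale
    bt <- rnorm(n_reg, 0, config$covariate_sd[["tissue"]])
    bg <- rnorm(n_reg, 0, config$covariate_sd[["gender"]])
    ba <- rnorm(n_reg, 0, config$covariate_sd[["age"]])
    br <- rnorm(n_reg, 0, config$covariate_sd[["combined_risk"]])

    x_tis <- as.numeric(samples$tissue == "brain")
    x_gen <- as.numeric(samples$gender == "M")
    x_age <- ifelse(is.na(samples$age_years), 0, samples$age_years - 30)
    x_rsk <- as.numeric(isTRUE_vec(samples$combined_risk))

    log2mu <- outer(bt, x_tis) + outer(bg, x_gen) + outer(ba, x_age) +
      outer(br, x_rsk)
    for (j in which(direction != 0)) {
      if (label[j] == "graded_II") {
        log2mu[j, samples$classification == "IIa"] <-
          log2mu[j, samples$classification == "IIa"] + eff
        log2mu[j, samples$classification == "IIb"] <-
          log2mu[j, samples$classification == "IIb"] + 2 * eff
      } else {
        in_case <- samples$classification %in% contrast_case_set(label[j])
        log2mu[j, in_case] <- log2mu[j, in_case] + eff * direction[j]
      }
    }

    # leukocyte mixtures at marker loci in blood
    cell_types <- config$cell_types
    k <- length(cell_types)
    blood <- which(samples$tissue == "blood")
    W <- matrix(0, length(blood), k,
                dimnames = list(samples$sample_id[blood], cell_types))
    P <- NULL
    if (n_mark > 0 && k > 0) {
      assign_ct <- rep_len(seq_len(k), n_mark)
      P <- matrix(config$marker_low, n_mark, k,
                  dimnames = list(regions$region_id[seq_len(n_mark)], cell_types))
      P[cbind(seq_len(n_mark), assign_ct)] <- config$marker_high
      if (length(blood)) {
        a <- config$cell_alpha
        g <- matrix(rgamma(length(blood) * k, shape = rep(a, each = length(blood))),
                    length(blood), k)
        W <- g / rowSums(g)
        dimnames(W) <- list(samples$sample_id[blood], cell_types)
      }
    }

    mu <- exp(b0 + log(2) * log2mu) %*% diag(lib * spike / L0, n_s)
    if (n_mark > 0 && length(blood)) {
      mix <- P %*% t(W)  # markers x blood samples
      mu[seq_len(n_mark), blood] <- mu[seq_len(n_mark), blood] * mix
    }
    phi <- config$dispersion
    draw_nb <- function(m) {
      if (phi <= 0) matrix(stats::rpois(length(m), m), nrow(m), ncol(m))
      else matrix(rnbinom(length(m), mu = m, size = 1 / phi), nrow(m), ncol(m))
    }
    methyl <- draw_nb(mu)
    colnames(methyl) <- samples$sample_id

    mu_in <- exp(b0) %*% t(lib / L0) / config$input_attenuation
    input <- draw_nb(mu_in)
    colnames(input) <- samples$sample_id

    cm <- count_matrix(regions, methyl, input)
    ref_cpm <- if (!is.null(P)) {
      sweep(P, 1, exp(b0[seq_len(n_mark)]) * 1e6 / L0, "*")
    } else NULL
    structure(list(
      samples = samples, counts = cm,
      truth = data.frame(region_id = regions$region_id, label = label,
                         direction = direction,
                         log2_effect = ifelse(direction != 0,
                                              eff * direction, 0),
                         stringsAsFactors = FALSE),
      cell_proportions_truth = W,
      cell_reference = ref_cpm,
      library_sizes = setNames(lib, samples$sample_id)
    ), class = "simulated_cohort")
  })
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Simulate per-sample peak calls
#'
#' Each true region is emitted in a random subset of samples (inclusion
#' probability `peak_emit_prob`) with boundaries jittered by up to
#' `peak_jitter` bp, fold enrichment above the retention threshold and small
#' p-values. Decoy peaks carry sub-threshold enrichment or large p-values so
#' that the upstream filter removes them.
#'
#' @param samples sample sheet.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with `calls` (named list, one `data.frame` of
#'   chrom/start/end/fold_enrichment/p_value per sample) and `regions` (the
#'   true region coordinates).
#' @export
simulate_peak_calls <- function(samples, config = sim_config(), seed = 1) {
  with_seed(seed, {
    regions <- simulate_regions(config, seed = seed + 1)
    n_s <- nrow(samples)
    calls <- vector("list", n_s)
    names(calls) <- samples$sample_id
    for (i in seq_len(n_s)) {
      emit <- runif(nrow(regions)) < config$peak_emit_prob
      r <- regions[emit, , drop = FALSE]
      if (nrow(r)) {
        j1 <- sample(-config$peak_jitter:config$peak_jitter, nrow(r), TRUE)
        j2 <- sample(-config$peak_jitter:config$peak_jitter, nrow(r), TRUE)
        r$start <- pmax(0L, r$start + j1)
        r$end <- pmax(r$start + 50L, r$end + j2)
        r$fold_enrichment <- runif(nrow(r), 4.5, 30)
        r$p_value <- 10^-runif(nrow(r), 2.5, 6)
      }
      # decoys: half fail the enrichment threshold, half the p threshold
      nd <- config$n_decoy_peaks
      if (nd > 0) {
        dstart <- sample(1:2e6, nd)
        d <- data.frame(chrom = sample(paste0("chr", seq_len(config$n_chromosomes)),
                                       nd, TRUE),
                        start = dstart, end = dstart + sample(200:800, nd, TRUE),
                        region_id = NA_character_,
                        fold_enrichment = runif(nd, 0.5, 3.9),
                        p_value = 10^-runif(nd, 2.5, 6))
        flip <- seq_len(nd) %% 2 == 0
        d$fold_enrichment[flip] <- runif(sum(flip), 4.5, 30)
        d$p_value[flip] <- runif(sum(flip), 0.02, 0.5)
        r <- rbind(r[, names(d)], d)
      }
      calls[[i]] <- r[order(r$chrom, r$start), ]
    }
    list(calls = calls, regions = regions)
  })
}

#' Simulate a Methyl-qPCR plate
#'
#' Generates threshold-cycle (Ct) values for bound (methylated) and unbound
#' (unmethylated) fractions plus the methylated spike-in control, in
#' duplicate wells, such that with equal spike Cts
#' `ct_unbound - ct_bound = log2(p / (1 - p))` for true percent methylation
#' `100 p`, up to well noise. Per-sample machine offsets shift all four Cts
#' jointly and cancel in the percent-methylation formula.
#'
#' @param targets character vector of assay target names.
#' @param samples sample sheet.
#' @param true_percent matrix (samples x targets) of true percent methylation
#'   in `[0, 100]`; values outside `(1, 99)` are clipped with a warning.
#' @param noise_sd per-well Ct noise standard deviation (cycles).
#' @param n_replicates wells per reaction.
#' @param seed integer seed.
#' @return Long `data.frame`: `sample_id`, `target`, `fraction`
#'   (bound/unbound; spike rows use target `"spike_control"`), `replicate`,
#'   `ct`.
#' @export
simulate_qpcr <- function(targets, samples, true_percent, noise_sd = 0.1,
                          n_replicates = 2, seed = 1) {
  true_percent <- as.matrix(true_percent)
  stopifnot(nrow(true_percent) == nrow(samples),
            ncol(true_percent) == length(targets))
  if (any(true_percent < 1 | true_percent > 99)) {
    warning("true percent methylation clipped to [1, 99]")
    true_percent <- pmin(pmax(true_percent, 1), 99)
  }
  with_seed(seed, {
    rows <- list()
    base_quant_log2 <- -4  # total target quantity relative to spike
    for (i in seq_len(nrow(samples))) {
      offs <- rnorm(1, 0, 1)  # machine/plate offset, cancels in analysis
      for (f in c("bound", "unbound")) {
        for (rep_k in seq_len(n_replicates)) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = samples$sample_id[i], target = "spike_control",
            fraction = f, replicate = rep_k,
            ct = 20 + offs + rnorm(1, 0, noise_sd))
        }
      }
      for (t in seq_along(targets)) {
        p <- true_percent[i, t] / 100
        for (f in c("bound", "unbound")) {
          q <- if (f == "bound") p else 1 - p
          ct0 <- 20 + offs - (base_quant_log2 + log2(q))
          for (rep_k in seq_len(n_replicates)) {
            rows[[length(rows) + 1]] <- data.frame(
              sample_id = samples$sample_id[i], target = targets[t],
              fraction = f, replicate = rep_k,
              ct = ct0 + rnorm(1, 0, noise_sd))
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
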