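---
title: "Models and methods behind fcdmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fcdmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdmeth)
```

## The scientific problem

Focal cortical dysplasia (FCD) is a malformation of cortical development and
a leading cause of drug-resistant epilepsy. Its histopathological subtypes
(Ia, IIa, IIb, IIIa, IIId) differ in prognosis and management, but
distinguishing them — especially IIa from IIb — is hard before surgery.
`fcdmeth` implements an analysis pipeline for methyl-binding-domain (MBD)
capture sequencing of paired surgical brain tissue and blood: DNA
methylation is measured as enrichment read counts over genomic regions
(not per-base bisulfite calls), compared across subtypes, and distilled
into small methylation biomarker panels that can be assayed in blood by
Methyl-qPCR.

The pipeline has seven stages, each a module with a matching numbered
driver under `analysis/`:

1. **Synthetic cohort generation** (`sim_config`, `simulate_cohort`,
   `simulate_counts`, `simulate_peak_calls`, `simulate_qpcr`)
2. **Consensus methylated regions** (`filter_peak_calls`,
   `build_consensus`, `count_cpg`, `classify_feature`,
   `assign_nearest_gene`, `filter_mean_coverage`)
3. **Normalization and PCA diagnostics** (`logcpm`, `residualize`,
   `meth_pca`, `pc_covariate_correlation`)
4. **Leukocyte deconvolution** (`cell_type_reference`,
   `estimate_proportions`, `attach_proportions`)
5. **Differential methylation** (`build_design`, `estimate_dispersions`,
   `fit_nbglm`, `test_contrast`, `run_all_contrasts`)
6. **Biomarker panels** (`region_auc`, `select_dmr_biomarkers`,
   `intersect_contrasts`, `stepwise_aic_logistic`, `combinatorial_roc`,
   `bootstrap_auc_pvalue`)
7. **Methyl-qPCR validation** (`percent_methylation`, `mann_whitney`,
   `validation_report`)

## Consensus regions and annotation

Per-sample MACS-style peak calls are the input. Calls are kept when fold
enrichment is **strictly** greater than 4 and the p-value **strictly** below
0.01; all printed thresholds in this package (coverage > 10, AUC > 0.65,
CpG sites > 4) are implemented as strict inequalities, reading the wording
literally. Intervals are merged within each sample first, so that support
counts **distinct samples** rather than peak instances. The genome is then
fragmented at the union of all breakpoints; fragments covered by at least
three samples ("more than two") survive; adjacent surviving fragments merge
with the maximum support; any merged region touching a blacklist interval by
one or more bases is discarded. Coordinates are 0-based half-open (BED
convention) everywhere.

CpG counting uses the **C-position rule**: a CpG belongs to the window
containing its cytosine, and the matcher reads one base past the window end.
This makes CpG counts additive over any partition of a contig — a property
the test suite verifies — at the cost of looking a single base beyond the
interval. Feature classification applies the precedence promoter > exon >
intron > intergenic by any-overlap, with the promoter defined as ±1 kb
around the strand-aware TSS; CpG-island status (island / shore within
±1 kb / open sea) is assigned independently. Nearest-gene assignment
prefers gene-body overlap (distance 0), then the closest gene body within
100 kb, with deterministic ties (smallest gap, then lexicographic id);
anything farther is "intergenic".

## The generative model and the differential model are mirrors

The synthetic cohort generator exists so that every downstream stage is
testable without patient data, which the study could not deposit. Methyl
counts for region $j$ in sample $i$ are negative binomial with variance
$\mu + \phi\mu^2$ and

$$\log \mu_{ij} = \beta_{0j}
  + \log(2)\,x_i^\top\beta_j
  + \log(2)\,\Delta_j\,[i \in \text{case}(j)]
  + \log\!\frac{L_i s_i}{L_0},$$

where $x_i$ collects tissue, gender, age and combined-risk covariates with
region-specific coefficients drawn from mean-zero normals, $\Delta_j$ is the
planted log2 DMR effect, $L_i$ is the library size and $s_i$ the per-sample
spike-in enrichment ratio. Blood samples additionally mix marker-region
rates through a cell-type profile weighted by Dirichlet-distributed true
leukocyte proportions, so the deconvolution stage has a recoverable truth.
Input-fraction counts are generated without group or cell effects.

Defaults are the study conditions: group sizes from the 21-patient
discovery table, all subjects paired, library sizes log-normal around the
study's median depth of 83 million reads scaled down by $10^4$ (the scaling
preserves relative structure, not absolute depth; the problem sizes used in
tests — up to 2000 regions and 40 samples — are stated with each
experiment), dispersion $\phi = 0.2$, spike ratios uniform on
$[0.8, 1.25]$, covariate effects small ($|\log_2| \le 0.25$ for everything
but tissue) so group effects dominate, and tissue deliberately the dominant
nuisance axis, as in real brain/blood methylomes. What the generator does
**not** emulate: genomic autocorrelation between neighbouring regions,
GC/CpG-dependent capture bias, batch structure beyond the spike ratio, and
subtype-specific cell-composition shifts. Passing tests therefore certify
the statistical machinery under the stated model, not performance on real
cohorts.

The differential model fits exactly the mirrored regression: a log-link NB
GLM per region with offsets $\log(L_i s_i)$, an intercept, the group
indicator for the contrast at hand, standardized clinical covariates, and
the estimated cell proportions (brain rows carry zeros — the correction is
a blood phenomenon, but the joint model needs complete rows). Estimation is
iteratively reweighted least squares (relative deviance tolerance $10^{-8}$,
at most 100 iterations, linear predictors clamped to $\pm 30$). All-zero
regions are flagged and excluded. Aliased design columns are dropped
deterministically by QR pivoting and logged; missing covariates are
median-imputed (numeric) or modal-imputed (categorical) and logged.

Dispersion is estimated per region by maximizing the Cox–Reid-style
adjusted profile likelihood (the NB log-likelihood at the region's IRLS fit
minus half the log-determinant of the weighted information), then shrunk on
the log scale toward a lowess trend over log mean count with fixed weight
0.3. This is one defensible member of the empirical-Bayes family that
count-based differential packages use; with a single region the trend
degenerates to the region's own estimate, so tagwise equals common.

Contrasts are tested by the likelihood ratio: the reduced model drops only
the group column, the statistic is the deviance difference referred to
$\chi^2_1$, and the direction (increased/reduced methylation) is the sign
of the group coefficient. DMRs are called at raw $p < 0.01$ — the study's
threshold — with a Benjamini–Hochberg column emitted for reference but
never used as a gate. The contrast family is the study's seven, with
"subtypes versus other pathologies" expanded into the IIa- and IIb-specific
panels the biomarker stage consumes. With few samples and a rich design the
$\chi^2$ approximation degrades, so `run_all_contrasts` exposes a
`covariates` argument; the calibration experiments use the group-only
design, and contrasts whose design exhausts the residual degrees of freedom
are skipped with a warning rather than fitted badly. Both joint
(tissue-covariate) and per-tissue fits are supported via `tissue_mode`,
since the tissues are reported separately in places and jointly in others.

## Leukocyte deconvolution

Blood methylation reflects cell composition, so composition must be a
covariate. Following the reference-based tradition, each blood sample's
signal $y$ at marker regions (linear CPM scale — mixtures are linear in
proportions on the linear scale, not the log scale) is projected onto the
profile matrix $P$ of pure cell types (B cell, T cell, monocyte; CD19,
CD3D, CD14 loci):

$$\hat w = \arg\min_w \|y - Pw\|_2^2
  \quad\text{s.t.}\quad w \ge 0,\ \textstyle\sum_k w_k \le 1.$$

The inequality sum constraint leaves room for unmodelled cell types. The
quadratic program is solved **exactly** by enumerating all $2^{k+1}$
active-set configurations and checking the KKT conditions — enumeration is
trivially cheap for the handful of cell types this assay resolves, and the
tests verify the KKT certificate, scale invariance and zero residual inside
the feasible cone. Rank-deficient references are refused rather than
regularized.

## Biomarker panels and combinatorial ROC

Per-region discrimination is the Mann–Whitney AUC computed by midranks
(ties credited 0.5), reported as $\max(A, 1-A)$ with an orientation flag.
Candidates must pass $p < 0.01$ in the contrast, AUC $> 0.65$ and more
than 4 CpG sites. The panel logic intersects three contrasts — IIa vs
others ($A$), IIb vs others ($B$), IIb vs IIa ($C$):
IIa-defining $= (A \cap C) \setminus B$, IIb-defining
$= (B \cap C) \setminus A$, and the top IIb-vs-IIa marker is the single
highest-AUC member of $A \cap B \cap C$ (ties by CpG count, then id).

The clinical-factor score is a logistic model selected by bidirectional
stepwise AIC from age, gender, onset age, disease duration, localisation,
prior surgery and combined risk factors; perfect separation triggers a
ridge refit (penalty $10^{-6}$) with a warning. Combinatorial ROC
enumerates every marker subset up to size 3 (configurable; the published
combination count is not derivable from the stated panel size, so the
enumeration scope is explicit configuration), each with and without the
clinical score, scores each by an in-sample logistic fit, and ranks by AUC
then Youden-threshold accuracy. In-sample evaluation mirrors the original
procedure; it overstates transferable performance, which is a documented
limitation, and significance is assessed instead by a label-permutation
p-value with add-one smoothing, $p = (k+1)/(B+1)$, which can never be zero.

Two verification subtleties are worth recording. First, stepwise AIC keeps
a pure-noise covariate with asymptotic probability
$P(\chi^2_1 > 2) \approx 0.16$, so with several noise candidates the
probability of selecting *exactly* the true covariate set plateaus near
$0.84^k$ — about 0.4–0.5 in our six-covariate setting — even though the
true covariates are retained essentially always. The selection experiment
reports both rates. Second, at the raw $p < 0.01$ DMR threshold each
planted single-contrast region passes its null third contrast at the
calibrated ~1% chance rate, so panel classes match the planted truth up to
that leakage; the set algebra itself is verified exactly against an
independent oracle.

## Methyl-qPCR percent methylation

MBD capture splits DNA into bound (methylated) and unbound (unmethylated)
fractions, each quantified by qPCR alongside a methylated spike-in control.
With amplification efficiency fixed at 2 (perfect doubling), quantities are
$Q_f = 2^{\,\mathrm{Ct}^{spike}_f - \mathrm{Ct}_f}$ per fraction and

$$\%\,\text{methylation} = 100 \cdot \frac{Q_{bound}}{Q_{bound} + Q_{unbound}}.$$

Spike normalization cancels any machine offset (the tests assert invariance
to adding a constant to all four Cts). Replicates are averaged on the Ct
scale (geometric on the quantity scale); a replicate spread above one cycle
raises a QC flag. An undetermined Ct contributes zero quantity — bounded
and conservative — and is flagged, never imputed to cycle 40. Group
comparisons use the Mann–Whitney U test, exact by enumeration for small
tie-free samples and the tie-corrected normal approximation otherwise, and
the combined panel is evaluated by ROC per tissue.

## Numerical choices and degenerate inputs

* PCA is a region-centered (optionally unit-scaled) SVD with a fixed sign
  convention (largest-magnitude loading positive) for reproducibility;
  all-constant matrices yield one component with zero variance fraction.
* PC–covariate association is |Pearson r| for numeric covariates and the
  correlation ratio (root between-group variance fraction) for categorical
  ones; constant covariates report 0 with a warning.
* Visualization-level "GLM adjustment" is OLS residualization on log-CPM
  (idempotent, verified); the testing path adjusts inside the NB model
  itself.
* The mean-coverage filter defaults to the methyl fraction; the input
  fraction is selectable, since the published wording does not say which
  was filtered.
* Degenerate Mann–Whitney inputs (all values tied) return p = 1; empty
  ROC arms, overlapping contrast arms, mixed chromosome naming, negative
  counts and rank-deficient references are hard errors.
* Every generator is deterministic given its seed, and restores the
  caller's RNG state.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` reruns the cohort fixture
summaries and all simulation experiments (type-I calibration at 2000 null
regions, effect recovery at 200 truth DMRs and 20 samples per arm,
deconvolution recovery at 50 markers and 100 samples, the panel-logic
experiment, the 754-combination enumeration, the stepwise-selection
replicates and the qPCR round trip) from scratch and writes every measured
quantity as JSON. The testthat suite covers the same ground with
per-module oracles: brute-force per-base consensus counting, exhaustive
AUC pair counting, full-enumeration Mann–Whitney p-values, an independent
eigendecomposition for PCA, and an independent count-model implementation
(edgeR) as a cross-check of — never a stand-in for — the NB fitting code.
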