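---
title: "Discovering endothelial expression programs and their treatment associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering endothelial expression programs and their treatment associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecprograms)
```

# What this package computes

Tumor endothelial cells (ECs) are a small compartment of single-nucleus
RNA-seq datasets, yet their transcriptional states — capillary, arterial,
venous, lymphatic, and reactive/inflammatory phenotypes — carry information
about treatment response and prognosis. `ecprograms` implements the full
analysis chain for this problem:

1. **EC extraction** from a gene-by-nucleus count matrix, by curated labels
   or marker-score-annotated k-means clusters.
2. **Consensus non-negative matrix factorization (cNMF)** to discover gene
   expression programs: repeated NMF from random starts, outlier filtering of
   pooled components, k-means consensus clustering, and stability/error-based
   choice of the number of programs.
3. **Program annotation** by hypergeometric overlap of each program's
   top-weighted genes against reference signatures or GMT pathway sets.
4. **Differential expression** between a program's nuclei and all other ECs
   with a mixed-effects Poisson model (patient random intercept, library-size
   offset).
5. **Patient-level associations**: program proportions vs treatment strata
   (Mann-Whitney U + Benjamini-Hochberg at FDR 0.1), top-vs-bottom quartile
   microenvironment contrasts, stromal-to-EC ratios, and paired targeted-panel
   scoring (Wilcoxon signed-rank + Bonferroni).
6. **Bulk-cohort analysis**: marker-based cell-type deconvolution, summed
   top-gene program scores z-normalized within each cohort, multivariable Cox
   regression on survival endpoints, and program score vs nodal status.

Every stage has a synthetic-data generator with planted ground truth, so the
whole pipeline is testable without any external download.

# The factorization model

A prepared matrix $M$ (nuclei $\times$ genes, nonnegative) is approximated as
$M \approx WH$ with $W \ge 0$ (usages) and $H \ge 0$ (spectra). Each spectra
row is a *program*: a nonnegative gene-weight vector; each nucleus's usage row
says how much of each program it expresses.

**Preparation** (`prepare_matrix`). Counts are normalized to counts per 10k
per nucleus and log1p-transformed; the `n_hvg` highest-variance genes are
kept (zero-variance genes are excluded); each retained gene is scaled to unit
variance *without centering*, which keeps the matrix nonnegative by
construction (a `pmax(0)` guard backs the contract). Centering before
clipping would discard all below-mean signal, so it is deliberately avoided.

**Replicates** (`run_nmf_replicates`). NMF solutions depend on their random
start, so the factorization is repeated (default 50;
tests use 15–20 for desk-scale runtime) with seeds `base_seed + i - 1`. Each
replicate is solved by HALS block coordinate descent; only $W$ is randomly
seeded and $H$ receives the first update, which makes the whole trajectory
equivariant under gene permutation. Sweeps stop when the relative Frobenius
error decrease falls below `tol` (default `1e-4`, checked every 5 sweeps) or
after `max_iter = 200` sweeps; non-converged replicates are kept and flagged.
Spectra rows are renormalized onto the simplex with the scale absorbed into
$W$.

**Consensus** (`build_consensus`). All replicate spectra rows are pooled.
Rows whose mean distance to their nearest neighbours (30% of the pool by
default) exceeds the 0.9 quantile of that statistic are discarded as
outliers — the conventional consensus-factorization defaults. Retained rows are
clustered into $k$ groups by k-means with k-means++ seeding under a fixed
seed, and the component-wise **median** of each cluster (more robust than the
mean) is the consensus spectrum. *Stability* is the mean silhouette width of
that clustering (singleton clusters are excluded with a warning). Usages are
refit by nonnegative least squares of $M$ onto the consensus spectra and
row-normalized; the reconstruction error comes from this refit.

**Choosing k** (`select_k`). Across a grid of candidate $k$, stability and
error are min-max normalized and $k$ maximizes `stability - lambda * error`
(`lambda = 1`). The full diagnostics table is returned because on real data
the choice also weighs parsimony and biological coherence of the programs —
an automated score is a guide, not a verdict. Reconstruction error typically
decreases in $k$ and flattens past the true rank, but an individual consensus
at overspecified $k$ can occasionally degenerate — the component clustering
splits a real program and the median consensus reconstructs worse; such
solutions also show depressed stability, which is why selection uses both
terms rather than error alone.

**Classes and assignment.** The split of programs into *lineage* and *state*
classes is user-supplied annotation (`program_set`), not automatic: it
encodes biological judgment about what a program represents. Each nucleus is
then labeled with its top-usage lineage program and, separately, its
top-usage state program (`assign_nuclei`); exact ties go to the lowest
program index and are flagged.

# Statistical primitives

The overlap, rank, and multiplicity primitives are implemented in the package
from first principles so each is verifiable against brute-force enumeration
(the test suite does exactly that, and cross-checks against base R):

- **Two-sided hypergeometric** (`hypergeometric_overlap_test`): doubling the
  smaller tail, capped at 1. The doubling construction is simple,
  conservative, and oracle-checkable; the universe must contain both sets,
  and by default it is the set of genes present in the analyzed matrix —
  overlap probabilities must condition on testable genes, not the genome.
- **Mann-Whitney U** (`mann_whitney_u`): midranks for ties; exact p by
  enumeration of all group labelings when the pooled sample is at most 12
  without ties, otherwise a tie-corrected normal approximation with
  continuity correction. The exact/approximate switch at pooled $n = 12$
  keeps the exact branch enumerable in tests.
- **Wilcoxon signed-rank** (`wilcoxon_signed_rank`): pairing is by index and
  must be explicit. Zero differences are dropped (Wilcoxon's convention);
  all-zero input returns $p = 1$ with a flag rather than an error. Published paired panels
  sometimes list the two condition groups without an explicit pairing key;
  the package therefore requires the caller to supply the pairing rather
  than guessing one.
- **Multiplicity** (`adjust_pvalues`): Benjamini-Hochberg step-up (the
  pipeline's convention is FDR 0.1) and Bonferroni. Every reported family of
  tests carries its adjustment; no raw-p-only tables are produced.

# The differential-expression model

For each gene, counts $y_c$ of nucleus $c$ follow
$\log E[y_c] = x_c^\top\beta + b_{p(c)} + o_c$, with a patient random
intercept $b_p \sim N(0, \sigma^2)$ and offset
$o_c = \log(\mathrm{UMI}_c / \mathrm{median}\ \mathrm{UMI})$. Fixed effects
are the in-program indicator plus treatment arm, sex, and the first three
principal components of the normalized EC matrix (`compute_pcs`, computed on
ECs only, with a deterministic sign convention). The fit maximizes the
Laplace-approximate likelihood: an inner penalized IRLS solves jointly for
$(\beta, b)$ using the Schur complement of the diagonal random-effect block
(so each iteration is $O(n p)$), and a 1-D profile over $\log\sigma^2$
(`optimize`, with the $\sigma = 0$ boundary evaluated explicitly) selects the
variance. The group coefficient is reported with a Wald p-value and
Bonferroni adjustment across tested genes, matching the beta/adjusted-p
reporting convention of program-level volcano plots. Genes expressed in
fewer than 1% of nuclei are not tested (configurable); fits that degenerate
(e.g. the group perfectly aligned with a patient) are flagged with an
infinite standard error rather than dropped. The test suite cross-checks the
fitter against `lme4::glmer` and against the closed-form GLM limit; `s2_max` exposes the variance-profile
upper bound, and values near zero reproduce the plain GLM.

# Patient-level and bulk analyses

**Proportions and strata.** `program_proportions` computes, per patient, the
fraction of EC nuclei assigned to each program, separately within the lineage
and state families (each family is a simplex). `compare_strata` runs one
two-sided Mann-Whitney U test per (program, stratum pair) — arms, radiation
dose groups, or modalities — with BH control across the family at FDR 0.1.

**Quartile contrasts.** The patient-level expression of a program is the mean
usage weight across the patient's EC nuclei (`patient_program_expression`) —
the natural summary given that usages are the model's per-nucleus program
weights. `quartile_association` cuts patients at rank-based quartiles
(`floor(n/4)` per tail, ties broken by patient identifier, since no tie or
rounding convention is inherent to the method), compares each response
between top and bottom quartiles by MWU with BH control, and reports the
ratio of quartile means as the fold change (an NA sentinel with a warning
when the bottom mean is zero). `stromal_to_ec_ratio` feeds per-patient
cell-type-to-EC count ratios through the same machinery.

**Targeted panels.** `score_panel` scores each sample as the mean panel
expression of the genes overlapping each program's top-weighted list and
compares conditions with the paired signed-rank test, Bonferroni-adjusted
across signatures.

**Bulk cohorts.** `deconvolve` scores each cell type as the mean log1p
expression of its markers, z-scores each type across samples, shifts to
nonnegative, and normalizes per sample to the simplex. Marker-mean scoring
is the default because it is simple and oracle-checkable, with an NNLS
regression onto binary marker profiles available behind `method = "nnls"`.
`score_programs` sums the expression of each program's present top genes
(at least 10 required) and z-normalizes within each cohort label
independently, absorbing cohort-scale batch effects. "Endothelial
compartment expression" is operationalized as bulk expression of the
program's genes: the EC-attributed fraction of a bulk profile is not
separable without a reference expression model, and this approximation is
stated rather than hidden. `cox_regression` wraps the standard
partial-likelihood machinery (Efron tie handling, Wald inference; grade and
stage enter as ordinal integers; metastatic samples are excluded by the
clinical flag), and the test suite verifies the returned coefficient against
a brute-force grid search of a hand-written partial likelihood.
`node_association` compares program z-scores between node-positive and
node-negative samples with MWU + BH.

# What the simulators emulate — and what they do not

`simulate_snrnaseq` generates counts
$y_{cg} \sim \mathrm{Poisson}(L_c\, e^{b_{p(c)}} \sum_k u_{ck} h_{kg})$:
lognormal library sizes $L_c$ (median ~2,000 UMIs), Gaussian patient
log-rate effects, Dirichlet usages whose dominant component is drawn from an
arm-dependent program prevalence, and gamma-baseline spectra with per-program
blocks of elevated, program-specific marker genes. The default cohort
comprises 18 untreated, 14 chemoradiation (CRT), 5
chemoradiation+losartan (CRTL) patients; treated patients are deterministically
stratified into low/high dose and photon/proton modality in the cohort's
11:8 and 7:4 ratios, so stratified association tests are reproducible.

The default prevalence design plants one treatment-responsive program (index
5, prevalence 0.10 untreated vs 0.35 treated) and one *complementary*
program (index 1) that absorbs the shift, mirroring the depletion of the
capillary program alongside enrichment of the reactive program in treated
tumors. All remaining programs keep identical prevalence across arms — this
is what makes them genuinely null for treatment-association error-rate
checks; a bare simplex renormalization would leak the shift into every
program.

The emission is Poisson rather than negative binomial to match the DE
model's assumption, with the patient random effect supplying extra-Poisson
variation between patients — this keeps mixed-model recovery well-posed. The
generators deliberately do **not** model ambient RNA, doublets, batch
chemistry effects, gene-gene correlation beyond the program structure, or
zero inflation. Passing tests therefore demonstrate that the algorithms
recover what they are designed to recover under their own assumptions; they
do not certify behavior on real tissue data, where quality control and
annotation remain the analyst's responsibility.

`simulate_bulk_cohort` mixes marker-defined cell-type profiles with
Dirichlet proportions, modulates program signature genes multiplicatively by
latent per-sample z-scores, and draws exponential survival under a
proportional-hazards model on those z-scores with independent exponential
censoring calibrated to the target censoring fraction; two cohort labels with
different global scales exercise within-cohort z-normalization.
`simulate_huvec_panel` generates paired control/irradiated panel expression
with per-pair random intercepts and additive condition effects on designated
signatures. `simulate_pglmm_counts` is the dedicated GLMM benchmark
generator (planted group log-rate effect, patient intercepts, lognormal
library sizes).

# Numerical choices and degenerate inputs

- HALS sweeps use a relative-error stopping rule (`tol = 1e-4` per 5-sweep
  block) plus an absolute floor for exactly factorizable inputs; dead
  components are reseeded randomly.
- NNLS refits use cyclic coordinate descent on the normal equations
  (tolerance `1e-10`, 400 iterations); all-zero usage rows fall back to the
  uniform simplex point.
- k-means consensus uses k-means++ seeding under a fixed seed; if the
  outlier filter would leave fewer rows than clusters, filtering is
  disabled for that call.
- Exact branches of the rank tests switch to normal approximations at pooled
  size 12 (MWU) / 12 nonzero pairs (signed-rank) or in the presence of ties;
  fully tied inputs return p = 1.
- Program matching for validation (`match_programs`) solves the assignment
  problem exactly by bitmask dynamic programming (up to 16 programs),
  avoiding greedy-matching artifacts in recovery metrics. Recovery is scored
  against the planted spectra *projected into the prepared space*
  (`project_spectra`), because the factorization sees variance-scaled
  log-normalized data, not raw rates.
- The IRLS linear predictor is capped at 30 to prevent overflow; separation
  is reported via the `converged`/infinite-SE flags.

# Problem sizes used by the shipped studies

The packaged tests and the acceptance script run everything at desk scale,
chosen so the full suite completes on a single CPU: the planted-recovery
study uses ~3,000 nuclei x 1,500 genes with 7 planted programs, a k grid of
4–10 and 20 NMF replicates per k (5 seeds in the tests, 3 in the script);
the GLMM benchmark uses 40 patients x 200 nuclei with 50 effect genes
(plus 500 null genes in the tests, 300 in the script); the association study
uses 100 replicates (60 in the script) of 37-patient cohorts at 40 nuclei
per patient, refitting usages onto the planted spectra rather than
re-running program discovery per replicate — discovery quality is measured
once by the recovery study, and re-discovering programs inside every
replicate would only blur the error-rate question the study asks. The
robustness harness repeats the association analysis after removing the two
treated patients contributing the most nuclei, a standard influential-patient sensitivity check.

# Known limitations

- The cNMF consensus uses fixed conventional outlier parameters; they are
  exposed (`outlier_knn`, `outlier_quantile`) but not auto-tuned.
- The hypergeometric universe defaults to detected genes; analyses wanting a
  transcriptome-wide universe must pass it explicitly.
- Bulk program scores are not corrected for non-endothelial expression of
  program genes; interpretation on real cohorts should check marker
  specificity first.
- Ranked (running-sum) gene-set enrichment is intentionally out of scope;
  over-representation against user GMT collections is the provided
  alternative.
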