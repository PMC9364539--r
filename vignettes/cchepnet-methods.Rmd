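---
title: "Methods and design of the cchepnet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the cchepnet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cchepnet` implements a two-branch analysis of liver expression in a
recombinant-inbred two-diet design: a linear-model branch (per-gene
association, differential expression, heritability, variance partitioning)
and a network branch (weighted co-expression modules and module-level
statistics). This vignette is the package's own account of the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The data model

Every stage consumes an `ExpressionDataset`: a features x samples matrix of
log2-scale normalized intensities (upstream normalization such as RMA is out
of scope; a matrix is the entry point), per-feature transcript-cluster IDs
(TC-IDs) and gene symbols, and per-sample metadata with `strain`, `diet`
(`HP` or `HS`) and `week` (husbandry batch). Validation guarantees no
missing values, unique feature and sample identifiers, and metadata aligned
with expression columns; gene symbols are upper-cased once at load so that
all later symbol matching (including mouse-human GWAS matching) happens on
one normalized form. Phenotypes live in a separate table keyed by sample id
and may be missing per trait; all correlations use pairwise-complete
samples with that pair's own n.

## The synthetic-data generator

The generator is first-class, tested code: its role is to produce datasets
with the statistical structure of a 22-strain, two-diet, three-replicate
liver study (132 arrays) in which every downstream claim can be checked
against ground truth. Per gene g and sample i,

y_gi = mu_g + a_{g,strain(i)} + beta_g 1[diet(i) = HS]
      + c_{g,strain(i),diet(i)} + w_{g,week(i)} + lambda_g F_{m(g),i} + e_gi

with independent Gaussian strain, interaction, batch and residual effects of
per-gene variances sigma2_strain, sigma2_interaction, sigma2_batch,
sigma2_resid, and module factors F of unit variance.

Choices that matter, with their defaults and reasons:

* **Variance regime.** Defaults are strain-dominant: sigma2_strain = 0.069,
  sigma2_interaction = 0.004, sigma2_batch = 0.005, sigma2_resid = 0.148 on
  the log2 scale. This is the regime in which between-strain differences
  dwarf diet and interaction effects, as observed in strain-dominant liver
  expression panels.
* **Diet effects as fixed shifts.** Diet has two levels, so a variance is
  not its natural parameter; the generator plants a fixed per-gene shift
  beta_g = +/- sqrt(2 sigma2_diet). The factor two makes a one-way
  variance-component analysis recover sigma2_diet in expectation, because
  for a balanced two-level factor E[MSB] = sigma2_e + n Sum_j (d_j - dbar)^2
  / (J - 1) with J = 2. By default 15% of genes carry a shift with
  sigma2_diet = 0.045, so the all-gene average diet variance is about 0.007
  — an order of magnitude below strain — while individual affected genes
  have a detectable ~0.3 log2-unit effect.
* **Module factors carry a strain share.** Each module factor is
  F = sqrt(h) S_strain + sqrt(1-h) E with S one draw per strain (shared by
  both diets) and E sample-level, centered within strain and rescaled to
  unit variance. Co-expression modules in inbred panels are largely
  strain-driven; the strain share h (`modules$strain_cor`, default 0.5)
  reproduces that: module genes carry factor-driven strain variance
  lambda^2 h on top of their own sigma2_strain, and the ground-truth ICC
  accounts for it exactly. Centering the sample-level part within strain
  matters for correctness: an uncentered iid factor would inject *realized*
  between-strain variance shared by a whole module, silently biasing
  per-gene heritability for module genes.
* **Phenotype construction.** body_fat_pct = baseline + Sum_m gamma_m F_mi
  + delta 1[HS] + noise, with defaults baseline 25%, HS shift delta = 6
  percentage points, noise sd 3 — an adiposity gap and spread plausible for
  an 8-week high-fat high-sucrose challenge.
* **Data pathologies.** `inject_founder_nulls()` shifts selected genes down
  in a small subset of strains (a founder low/no-expression allele);
  `add_duplicate_tcids()` appends an attenuated, noisier second probe per
  selected gene. Both exist to exercise the filter rules against ground
  truth.
* **`cc_study_config()`** layers the full-study structure on the defaults:
  ten modules with sizes graded from 17% down to 1.7% of genes (about 60%
  coverage), within-module correlations 0.45-0.65, per-module
  diet-responsive fractions from 0.5 down to 0, three factors loading onto
  body fat %, 2% founder-null genes and 5% duplicate TC-IDs.

What the generator does **not** emulate: probe-level intensity models,
founder haplotype mosaics and eQTL architecture, non-Gaussian heavy-tailed
expression noise, hierarchical sub-module structure (each module is rank
one), and correlated phenotype batteries. Passing tests therefore show that
the estimators recover the structure they target under a faithful Gaussian
factor model at desk scale; they do not certify behaviour under array
artifacts or complex trans-regulation.

A single seeded generator with a documented draw order produces
bit-identical output for a given config on any platform.

## Array QC

Three per-array criteria, an array removed only when all three flag it:

* mean Euclidean distance to the other arrays, flagged above Q3 + 1.5 IQR;
* K_a, the sup distance between the array's intensity ECDF and the pooled
  ECDF over all arrays (the array under test included — the paper-side
  convention is not stated, and pooling everything keeps the reference
  identical for every array), same boxplot flag;
* Hoeffding's D between A = (x+m)/2 and M = x-m with m the per-gene median
  array, computed with the classical rank statistic with midranks for ties,
  flagged above a fixed threshold 0.15. A clean array has M independent of
  A; intensity-dependent distortion produces dependence.

The boxplot rule and the 0.15 threshold are conventions of the array-QC
tooling this stage mirrors; neither is data-fitted here.

## TC-ID filtering and probe selection

The keep rule is: median expression above the mean of all TC-ID medians,
*or* expression above that mean in strictly more than 12.5% of samples. The
12.5% reading is per-sample exceedance, because its justification — one of
eight founder strains may contribute a null allele — is about a fraction of
samples (strains), not about the median. "Highest expression" for best-probe
selection is interpreted as highest mean across samples (the statement does
not say mean, median or max; all three are available via the `selection`
argument), with ties broken by lexicographic TC-ID for determinism.

The mean-of-medians threshold is recomputed from whatever dataset the filter
sees, so re-running the filter on its own output is a fixed point only when
expressed and unexpressed genes form well-separated intensity populations —
which is the regime the rule was designed for; `mean_of_medians` can be
passed explicitly to re-apply a fitted threshold.

## Biweight midcorrelation

The MAD in the bicor weights is the raw median absolute deviation — no
1.4826 consistency factor — because the statistic's definition uses the
unscaled MAD (the 9 x mad window absorbs any scale convention). A vector
with zero MAD falls back to Pearson standardization for that vector alone;
a vector constant under both schemes is an error, not a silent NA. The
significance flag used for "correlated with body fat %" counting is nominal
p < 0.05 to match the screening convention; a BH-adjusted column is always
emitted alongside so either convention can be reported.

## Differential expression

One shared additive design — strain + diet + week, treatment coding, HP and
the first strain and week as references — serves both DEG families: the
diet DEG is the moderated t on the single diet coefficient (positive =
higher on HS), the strain DEG the moderated F over the S-1 strain columns.
Adjusting the diet contrast for strain is the default (the alternative
two-group comparison can be run by passing a design without strain columns);
with genetics this strong, not adjusting would push strain variance into
the diet residual.

Moderation fits a scaled inverse-chi-square prior (s0^2, d0) by moment
matching on e_g = log s_g^2 - digamma(d/2) + log(d/2):
trigamma(d0/2) = var(e) - trigamma(d/2), inverted by a monotone Newton
iteration, and log s0^2 = mean(e) + digamma(d0/2) - log(d0/2). When the
observed spread of log-variances is no larger than sampling noise the prior
df are infinite and the posterior variance is the pooled (arithmetic mean)
variance — the convention of the field's reference implementation, which
the test suite uses as an independent cross-check. No intensity trend is
put on the prior. BH adjustment is the standard step-up; the DEG flag is
adjusted p < 0.05.

Over-representation is a one-sided hypergeometric tail P(X >= k) on
user-supplied GMT gene sets restricted to the tested universe, with
"gene richness" k/K reported.

## Heritability and variance partitioning

Mean squares come from sequential (type I) sums of squares with covariates
entered before the grouping factor, so MSB is the covariate-adjusted
between-group mean square: full model (strain last, diet + week first,
both diets), HP-only and HS-only models (week first), and a diet-grouped
model for the diet ICC (strain + week first). Unbalanced group sizes enter
through the effective replicate count n0 = (N - Sum n_s^2 / N)/(S - 1) in
the ICC denominators; this moment-based correction is the package's stated
stand-in for the approximate df treatment the estimators are usually paired
with. Then

r_I = (MSB - MSW) / (MSB + (n0 - 1) MSW),
g^2 = (MSB - MSW) / (MSB + (2 n0 - 1) MSW),

g^2 doubling the additive genetic term for inbred panels, hence g^2 < r_I
whenever MSB > MSW. Negative values are legal and preserved — they say
within-strain variation exceeded between-strain variation. MSW = 0 returns
1 with a flag rather than an error.

The variance partition fits strain, diet and strain x diet all as random
effects by REML. The implementation profiles out the residual variance and
optimizes the three variance ratios gamma with box constraints (L-BFGS-B,
three starts: a method-of-moments start and two spread alternates,
convergence tolerance 1e-8, with a derivative-free polish when a line
search stalls on the boundary). Each evaluation works in the reduced
random-effects space via the Woodbury identity and the determinant lemma —
one m x m Cholesky (m = 68 for the full design) instead of an n x n one.
With one observation per cell the interaction is confounded with the
residual and the REML surface is flat along that trade-off; the fitted
point is then moved to the equivalent zero-interaction point (a parsimony
tie-break, applied only when the objective is within 1e-6). POV divides
each component by the sum of all four — residual included, which is why
reported POVs sum to 100 and the named components to well under 100.

On balanced designs with interior components this REML coincides with the
expected-mean-squares method-of-moments estimates; the test suite asserts
that, and independently cross-checks against a general mixed-model fitter.

## The network branch

Adjacency is unsigned, |Pearson r|^beta. The soft power is chosen as the
lowest power whose signed scale-free fit index reaches 0.9: connectivities
are binned into 10 equal-width bins, log10 mean frequency is regressed on
log10 mean connectivity, and the index is -sign(slope) R^2. Equal-width
binning is deliberate — with equal-count bins the frequency would be
constant by construction and the regression meaningless. If no power
crosses, the power of maximal fit is used with a warning.

The pipeline default pins beta = 5 rather than auto-selecting. On the
generator's mixture-of-modules covariance the scale-free index first
crosses 0.9 only at high powers, where |r|^beta has already washed out the
module structure; real liver data, with pervasive correlated variation,
crosses much earlier. beta = 5 is the study condition this pipeline
emulates, auto-selection remains available (`network_config(beta = NULL)`)
and is validated on synthetic data built to be scale-free (a single latent
factor with truncated-Pareto loadings, so connectivity at the design power
is power-law distributed).

TOM uses l_ij + a_ij over min(k_i, k_j) + 1 - a_ij; for a nonnegative
adjacency the signed and unsigned TOM formulas coincide, which is asserted
on every run along with symmetry, unit diagonal, the [0, 1] range and
numerator dominance.

Module detection is a dynamic hybrid tree cut in two stages on the
average-linkage dendrogram of 1 - TOM. Stage 1 cuts at a deepSplit-indexed
fraction of the *top* merge height (0.95 / 0.97 / 0.99 / 0.995 / 0.999 of
max for deepSplit 0-4; default 2) and keeps connected branches of at least
`min_module_size` (default 20) genes. Referencing the maximum rather than
the height range is a robustness choice: a few very tight branches (for
example a block of founder-null genes that are near-duplicates of each
other) would otherwise drag a range-relative cut far down and fragment real
modules. Stage 2 assigns each unlabeled gene to its nearest module when its
average dissimilarity to that module is below the module's radius (the
maximum member-to-module average dissimilarity); the rest stay grey. This
reproduces the published algorithm's structure — branch decomposition plus
a PAM-like assignment stage — without promising equality with the reference
implementation's micro-heuristics; planted-module recovery (adjusted Rand
index, grey specificity) is the behavioural contract, and the whole branch
is deterministic.

Eigengenes are unit-norm first left singular vectors of the per-gene
z-scored module submatrix, sign-oriented to correlate positively with the
module's average standardized expression (removing the PC sign ambiguity);
modules whose eigengenes cluster below dissimilarity 0.15 are merged
iteratively to a fixed point. minModuleSize 20, deepSplit 2 and merge
height 0.15 are the reference tool's defaults, all config-exposed, since
the emulated study names the functions but not the parameters. Module-trait
relations use Spearman correlations; diet and strain effects on eigengenes
use Wilcoxon rank-sum and Kruskal-Wallis tests.

## Integration and the pipeline

GWAS `MAPPED_GENE` fields are split on "," ";" " - " and " x ", tokens
whitespace-stripped and upper-cased, and intersected with the normalized
mouse symbols; unmatched tokens are reported, never silently matched. The
obesity-relevant catalog rows are selected by a user-supplied keyword list
— the exact list and catalog release define the input, not the method.
Venn regions for up to four gene sets are computed as disjoint membership
patterns whose counts must sum to the union. `run_pipeline()` chains all
stages, writes every report as TSV plus a JSON manifest (seed, config echo,
stage timings), and is bit-identical across reruns with the same config
aside from the wall-clock timings in the manifest. The package's interface
is its functions; the `scripts/acceptance.R` entry point wraps
`run_pipeline()` for an end-to-end run from the shell.

## Numerical choices and degenerate inputs

* Correlations are clamped to [-1, 1] after floating-point rounding;
  |r| = 1 yields p = 0 (flagged), not an error.
* `trigamma_inverse` uses Newton steps with closed-form seeds and relative
  tolerance 1e-10.
* Saturated designs (no residual df), single-diet or single-strain data,
  rank-deficient designs, empty universes and non-subset DEG lists are
  errors with named causes; a trait with fewer than three complete pairs
  yields NA rows with a reason string.
* TSVs are written with 17 significant digits so load -> write -> load round
  trips are bit exact.

## Problem sizes used in the tests

The suite exercises the estimators at sizes a reviewer can rerun at a desk:
oracle equivalence on hundreds of small random instances; heritability
recovery at 500 genes x 132 samples over true ICC 0 to 0.75; variance
partitioning at 1,000 genes under the strain-dominant profile; FDR control
and p-value uniformity at 5,000 genes; module recovery at 740 genes (three
planted blocks among noise); and the full pipeline, twice, at 2,000 genes
for bit-reproducibility. These sizes are the package's chosen trade-off
between statistical resolution and a test suite that runs in minutes.

## Known limitations

* Diet-specific heritability comparisons on module-bearing simulations
  inherit realization noise from the handful of shared latent factors: with
  ~10 factors, the per-diet realized within-strain factor variance
  fluctuates enough that two diets with identical generating parameters can
  show distribution-level differences in g^2 for some seeds. The diet-null
  property is therefore checked on the factor-free variance profile, where
  it is exact; real data, with effectively high-dimensional latent
  structure, averages this out.
* Module factors are rank one; hierarchical sub-modules and overlapping
  pathways are not modelled, so merge behaviour is only exercised on
  constructed eigengene geometries.
* The REML partition treats week as ignorable in the random-effects model
  (strain, diet, interaction only), matching the three-term partition it
  reports; batch variance, when present, loads onto the residual.
* The dynamic tree cut reproduces the published algorithm's core, not its
  reference implementation bit-for-bit; label agreement is guaranteed only
  at the level of partition quality (recovery contracts in the tests).
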