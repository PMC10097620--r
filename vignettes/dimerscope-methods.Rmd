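---
title: "Models and methods behind dimerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dimerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The experiment dimerscope analyses

RAF kinases (RAF1, BRAF) signal both as monomers and as dimers, and the two
states are suspected to assemble different protein interactomes. The
experimental system studied here controls dimerization chemically: RAF1 is
fused to FRB and BRAF (wild type or the oncogenic V600E mutant) to FKBP, so
that the A/C heterodimerizer forces RAF1-BRAF dimers on demand. Affinity
purification followed by label-free quantitative mass spectrometry (AP-MS
with MaxQuant LFQ) measures which prey proteins co-purify under each
condition. The design crosses four tag-only/empty controls with BRAF wild
type and BRAF V600E, each under no RAF inhibitor, Sorafenib, or Vemurafenib,
with and without the dimerizer: 16 conditions, 3 biological replicates, 2
technical replicates each, 96 runs. All four control conditions received the
dimerizer, so in the one-hot encoding the control rows carry
`dimerizer = 1` while both bait indicators are 0.

dimerscope implements everything downstream of the MaxQuant proteinGroups
table: category and valid-value filtering, missing-value imputation,
differential-interactor calling by two parallel routes, per-protein linear
regression on the one-hot design with contrasts, principal-component quality
control, and interactor overlap matrices. A synthetic-data generator with
known ground truth stands in for the deposited raw data so the entire
pipeline is testable end to end.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

Latent log2 intensity of protein $i$ in run $r$ is

$$y_{ir} = \mu_i + x_r^\top \beta_i + b_{i,c(r)} + \varepsilon_{ir},$$

with baseline $\mu_i \sim N(25, 2^2)$ (the usual log2 dynamic range of LFQ
pulldowns), $x_r$ the five 0/1 design variables of run $r$, a biological-
replicate effect $b \sim N(0, 0.5^2)$ shared by the two technical replicates
of a biological replicate, and technical noise
$\varepsilon \sim N(0, 0.3^2)$. About 15% of the 600 prey proteins carry a
nonzero $\beta$ on one or two variables, with magnitude drawn uniformly from
1-3 log2 units and positive sign with probability 0.7 (pulldown effects are
mostly enrichments; inhibitors can deplete). No numerical bait-enrichment
magnitudes are published for this system, so the effect scale is the
package's own choice,
fixed once so that differential calling has realistic, non-trivial power at
3 biological replicates; it is configurable but the defaults are never tuned
against test outcomes.

Missingness is generated as left censoring, the standard generative
counterpart of the downshift-imputation assumption: each cell is
independently missing with probability
$\mathrm{logit}^{-1}\{(m - y_{ir})/\max(s, 10^{-8})\}$ with midpoint
$m = 22$ and scale $s = 1$, i.e. detection fails preferentially for
low-abundance proteins (missing not at random). These defaults yield about
12% missing cells overall, concentrated in the lower intensity range, which
is typical for AP-MS LFQ. Setting $s = 0$ with $m$ below all latent values
switches censoring off exactly. Decoy rows (contaminant, reverse,
only-identified-by-site; 10 each) draw baselines from the same distribution
and exist only to exercise the category filter.

What the generator does *not* emulate: peptide-level quantification and
protein inference, correlated contamination across runs, batch drift,
shared-complex correlations between prey proteins (cells are independent
across proteins given the design), and bait-specific binding competition.
Passing tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to every pathology of real AP-MS
data.

# Filtering

* **Category filter** removes the union of rows flagged only-identified-by-
  site, reverse, or contaminant. Both the `Contaminant` and
  `Potential contaminant` header spellings are accepted (MaxQuant changed
  the header between versions).
* **Valid-value filter** keeps proteins with at least 3 observed values in
  at least one condition group. Groups are the 16 condition labels. (The
  source workflow's description of groups as time points is a template
  artefact of another workflow; this design has no time course.)
* **Max-missing filter**: the published rule ("more than 2 missing values in
  each condition were discarded" vs "less than 2 ... retained") is
  internally inconsistent about the exactly-2 case and about the quantifier.
  dimerscope implements the most permissive reading consistent with both
  sentences — discard only when *every* condition exceeds the threshold, and
  retain exactly-2 — with both the threshold and the every/any quantifier
  configurable (`filter_max_missing(quantifier = "any")` gives the strict
  reading).
* Technical replicates are kept as separate columns by default, matching the
  per-column treatment of the original workflow; an optional
  `collapse_technical_replicates()` stage averages observed values per
  biological replicate. Collapsing also removes the within-pair correlation
  induced by the biological-replicate effect, which matters for the
  calibration of any method that assumes independent columns (see the
  linear-model section).

All filters are idempotent, only ever remove rows, and never modify
surviving values.

# Imputation

Two schemes, mirroring the two parallel analyses of the workflow:

* **Downshifted Gaussian, separately per column** (`impute_downshift`,
  defaults width 0.3, downshift 1.8, both as multiples of the observed
  column sd): missing cells are drawn from
  $N(\bar{y}_j - 1.8\, s_j,\ (0.3\, s_j)^2)$. This feeds the
  permutation-FDR volcano branch.
* **Condition-wise log-normal** (`impute_lognormal`): each missing cell is
  drawn, on the log2 scale, around the protein's observed within-condition
  mean. The published description does not say how a spread is estimated
  from one or two observed replicates, so the spread follows a documented
  fallback hierarchy: per-protein within-condition sd when at least 3 values
  are observed; otherwise the condition's pooled within-protein sd;
  otherwise the whole-matrix pooled sd; floored at 0.01 log2 units. When a
  protein has no observed value in a condition, the location falls back to
  its observed mean across all runs. Whether the original parameters were
  per protein or per condition globally is not stated; both are available
  (`per_protein = FALSE` switches), per-protein being the default. This
  branch feeds the fold-change/BH differential calls, the regression and the
  PCA.

Numerical choices: observed cells are bit-identical before and after
imputation; each scheme consumes a stage-local seed derived from the master
seed so stages re-run independently and deterministically; columns with
fewer than two observed values fall back to pooled whole-matrix moments with
a warning.

**Known limitation (measured, not hidden).** Single imputation treats
imputed values as observed. Under MNAR censoring the within-condition
observed mean is selection-biased upward and the post-imputation group
variances are understated, so the log-normal branch is anti-conservative for
low-abundance, heavily censored proteins: on null synthetic data its
per-test false-positive rate at the full call rule is about 1% (well under
the nominal 5%, but about 25 times the downshift branch's rate), and on the
active synthetic study a substantial fraction of fold-change/BH calls land
on proteins with no true effect. `scripts/acceptance.R` recomputes and
reports exactly these rates; the package reports provenance
(`imputed_mask`) so downstream users can condition on it.

# Differential interactors

Right-tailed Welch t-test of each bait condition against its drug-matched
tag-only control (`diff = mean(condition) - mean(control)`, p = right-tail
probability). Welch is the default because nothing in the source states a
pooled-variance test and unequal variances are the safer assumption for
3-replicate AP-MS groups; `var_equal = TRUE` restores the pooled test. Two
call rules:

* **BH branch**: Benjamini-Hochberg adjustment per comparison; significant
  when the linear fold change exceeds 1.5 (the published rule does not state
  the scale; dimerscope interprets 1.5 as a linear ratio, i.e.
  `diff > log2(1.5) ≈ 0.585`) *and* q < 0.05.
* **Permutation branch**: the s0-modified statistic
  $d = \mathrm{diff}/(\mathrm{spread} + s_0)$ with $s_0 = 0.1$; group labels
  of the pooled columns are relabeled (250 randomisations by default, or all
  distinct relabelings exhaustively for small groups), and for each
  candidate threshold $c$ the FDR is estimated as the mean permuted
  exceedance count over the observed exceedance count. The threshold is the
  smallest candidate with estimated FDR at or below 0.1; points at or above
  it with positive difference are significant. Relabeling is across the two
  compared groups only (not whole-matrix), which preserves per-protein
  structure and matches the SAM-style approach. The cutoff curve is reported
  as the locus $d = c$ in (diff, $-\log_{10} p$) space — the exact analogue
  of a single (FDR, s0) curve — using the pooled degrees of freedom
  $n_1 + n_2 - 2$. The FDR estimator uses the mean permuted count; if no
  threshold reaches the target the threshold is $+\infty$ and the
  significant set empty.

Degenerate inputs: groups with fewer than 2 values are skipped with a
recorded reason; zero spread with $s_0 > 0$ is finite by construction; zero
spread with $s_0 = 0$ is undefined and skipped.

# The linear model

For each protein, ordinary least squares of log2 LFQ on the intercept plus
the five one-hot variables (BRAF wt, V600E, dimerizer, Sorafenib,
Vemurafenib), fitted by QR decomposition; coefficient covariance
$\hat\sigma^2 (X^\top X)^{-1}$ with $\hat\sigma^2 = RSS/(n - p)$.
Coefficient tests are two-sided ("different from zero" is a two-sided
question, unlike the right-sided enrichment tests), BH-adjusted across
proteins within each coefficient — each coefficient answers a distinct
question, so adjustment is not pooled across coefficients. Contrasts
$c^\top \hat\beta$ carry $se^2 = \hat\sigma^2\, c^\top (X^\top X)^{-1} c$,
with presets for the three published comparison families: `v600e-brafwt`,
`sorafenib-vemurafenib`, and `dimerizer` (monomer vs dimer). A positive
contrast sign means the first-named variable increases log-LFQ more. Plain
per-protein OLS is used rather than empirical-Bayes variance moderation so
the implemented mathematics is fully standard OLS theory; moderated tests
are deliberately out of scope.

A calibration note: with technical replicates as separate columns, the
shared biological-replicate effect correlates the 6 columns of a condition,
so per-column OLS standard errors (and t-test p-values) are optimistic. The
confidence-interval coverage checks in the test suite therefore collapse
technical replicates first — after collapsing, the generative model is
exactly the fitted model with iid errors, and 95% intervals demonstrably
cover at 0.95. On the uncollapsed layout the same intervals undercover;
users who want calibrated per-protein inference should enable the collapse
stage or model the hierarchy explicitly (out of scope here).

# Quality control and overlap

PCA (`run_pca`) centers proteins and projects samples; scores are
deterministic up to component sign. Outlier flagging uses a rule the source
does not specify (it reports only that a PCA identified two outliers): a
sample is flagged when its distance from its condition's componentwise
*median* centroid in PC1-2 exceeds the median distance by more than
`k_sd = 4` MADs. The median centroid keeps a corrupted replicate from
dragging the centroid toward itself and implicating its healthy
condition-mates. Samples are flagged, never auto-removed — removal is the
analyst's explicit decision, mirroring the manual judgement in the original
analysis.

Overlap matrices follow the published table semantics: entry (row i, column
j) is $|S_i \cap S_j| / |S_i|$, so the diagonal is n/n and numerators are
symmetric while denominators follow the row. The sets default to the BH
branch's significant interactors per condition (the published table does not
state which branch defined its sets; the source is configurable).
`compare_reference()` intersects against a local identifier file rather than
a live database, for reproducibility.

# Pipeline, determinism and problem sizes

`run_pipeline()` drives simulate/read, filter, impute (both branches),
differential (BH and/or permutation), regression with contrasts, QC and
overlap from one config (YAML or list), validating the config — including
that every referenced condition exists — before any computation. All
randomness derives stage-local seeds from one master seed, so identical
config + seed gives byte-identical output tables; the manifest records
parameters, counts per stage and the file list, and deliberately no
timestamps.

The test suite exercises the full 16 x 3 x 2 design at 600 proteins for the
null-calibration and coverage properties (200 simulated null datasets;
300-protein coverage checks), exhaustive 20-relabeling permutation
equivalence on 3-vs-3 toy matrices, and brute-force oracles (step-up BH,
`t.test`, normal equations, `lm`/`vcov`, exhaustive set intersection) at 100
random instances each — sizes chosen so the whole suite completes in well
under a minute while keeping Monte-Carlo error far below the tested
tolerances.

# Known limitations

* Single imputation (both schemes) understates uncertainty; see the
  imputation section. Multiple imputation with pooled inference is a
  non-goal.
* The one-hot model is purely additive — no drug x mutant interactions —
  and cannot distinguish the two dimerizer-treated tag-only controls from
  each other.
* The permutation branch needs enough columns to permute; with 3-vs-3
  groups only 20 distinct relabelings exist, bounding how fine the FDR
  estimate can be.
* Identifier mapping, network queries and peptide-level tables are out of
  scope.
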