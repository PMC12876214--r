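---
title: "Cross-kingdom co-dysbiosis networks: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom co-dysbiosis networks: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codysbiosis)
```

This vignette is the package's account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic cohort generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The scientific setting

Shotgun metagenomes of a small case-control cohort yield genus-level
relative abundance profiles for two kingdoms — bacteria and fungi — from
the same biological samples, alongside clinical covariates (total serum
IgE in IU/mL, allergen-specific IgE in kU~A~/L). The analysis asks three
questions. Does the fungal community differ between groups in diversity,
composition, or individual taxa? Do focal fungi track IgE sensitization?
And how is the *interaction structure* between kingdoms reorganized in
disease — specifically, is there a shift from an antagonism-rich network
(many negative bacterium–fungus correlations, read as competition) toward
an exclusively cooperative one? We call a network state dominated by
positive cross-kingdom edges with loss of negative ones *co-dysbiosis*,
and operationalize it as the positivity fraction of significant edges.

## Network inference

For one group's samples, every (bacterial genus, fungal genus) pair is
scored by Spearman's rank correlation with midranks for ties.
Within-kingdom pairs are never tested: relative abundances within a
kingdom are compositional (they sum to one), so within-kingdom
correlations are distorted by closure, whereas cross-kingdom pairs have
separate denominators. The two-sided p-value uses the t approximation
$t = |\rho|\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom — accurate
to the fourth decimal against printed anchor values at the cohort sizes
used here — and the Benjamini–Hochberg step-up is applied across all
cross-kingdom pairs tested within that group (the FDR family is the
group's network). Edges require both $|\rho| \ge$ `rho_min` (default 0.6)
and $q <$ `q_alpha` (default 0.05).

Parameters that matter:

* `rho_min = 0.6` — a deliberately stringent effect-size floor focusing
  the network on strong associations; at the default it is usually the
  *weaker* of the two filters, because BH with few discoveries demands
  p-values corresponding to $|\rho| \approx 0.65$–0.75 at $n \approx 19$.
* `q_alpha = 0.05` — BH false discovery rate. Note the arithmetic this
  implies: with $R$ discovered edges, about $0.05 \times R$ of them are
  expected to be false, of either sign. A network of 10–15 edges therefore
  carries roughly half a spurious edge on average; a topology summary of
  a *single* cohort can legitimately show a 100% positivity fraction, but
  an estimator of that fraction over replicate cohorts concentrates near
  95–98%, not exactly 100%. This is a property of FDR thresholding, not of
  the implementation.
* `prevalence_min = 0.25` — taxa observed in under a quarter of the
  group's samples are excluded before correlation, so edges are not driven
  by a handful of shared detections. Set 0 to disable.
* `n_perm = 9999` — permutations for PERMANOVA/PROTEST elsewhere in the
  workflow.

Constant taxa have undefined rank correlation; they are skipped per pair
and logged rather than failing the build. Hubs are ranked by degree with
deterministic tie-breaks (mean abundance, then name). Exports carry the
field's display conventions as attributes (bacteria: yellow circles;
fungi: green squares; positive edges red, negative blue) so Gephi renders
them directly.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
cohort data, and its defaults *are* the emulated study conditions: 19
cases (`ARFC`) versus 17 controls (`HC`); a control-network regime of 44
negative and 7 positive planted couplings against an exclusively positive
case regime of 17, at target Spearman 0.8 on disjoint pairs; fungal genera
Dentiscutata (3.70% vs 1.49% mean relative abundance) and Cenococcum
(1.74% vs 0.30%) depleted in cases; total IgE 285.6 ± 102.4 IU/mL in cases
versus 65.3 ± 28.7 in controls, with Spearman couplings of −0.39 to −0.43
between focal fungi and IgE.

Mechanically, each group draws a latent multivariate normal over
(bacteria, fungi, IgE) whose correlation matrix embeds every planted
coupling via the exact bivariate-normal inversion
$r = 2\sin(\pi\rho_s/6)$ and is the identity elsewhere. A Gaussian copula
is the right tool because all planted quantities are *rank* correlations:
they survive the lognormal margin transform, the zero-inflation step, and
total-sum scaling (any monotone transform), so the planted value is
exactly the quantity the pipeline later estimates. Margins are lognormal
(`lognormal_sigma = 1` by default — the data only constrain means and SDs
of selected taxa, so the dispersion is a modelling choice, exposed in the
spec); taxon mean weights are right-skewed so a few genera dominate, as in
real communities; depleted taxa have their weights solved so the expected
within-kingdom mean fraction hits the target; zero inflation
(`zero_inflation = 0.3`) injects structural absences, with taxa carrying
planted structure exempt by default so recovery studies isolate inference
behaviour from sparsity (set `zero_inflate_planted = TRUE` to study the
attenuation, which is monotone in the inflation rate). IgE is
moment-matched lognormal — positive and right-skewed, as an IgE
distribution should be — whose latent normal is the copula's IgE
dimension, making each IgE coupling an exact Spearman target. A requested
correlation structure that is not positive definite is rejected with
advice to use fewer or weaker planted edges.

What the generator does **not** emulate: read-level noise and coverage
variation, taxonomic misassignment, sequencing-depth differences between
samples, within-kingdom ecological dependence beyond closure, and
phylogenetic structure. Passing recovery tests therefore show that the
*inference machinery* behaves as specified on data whose generative truth
is known — they do not certify performance on real metagenomes, where
effect sizes and dependence structures are less tidy.

The KO-table generator follows the same philosophy: lognormal KO
abundances, disjoint pathway membership, and an optional group-mean shift
of a chosen number of pathways in units of the log-scale SD; shift zero
gives an exchangeable null whose per-KO Wilcoxon p-values are uniform.

## Diversity, ordination and permutation tests

Chao1 defaults to the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which stays finite when doubletons are
absent; the classic form is available for parity with other software. The
estimator is defined on integer counts, so `run_pipeline()` converts
simulated continuous fractions to pseudo-counts (rounded fraction × 10⁵)
before computing it — a display-scale choice that leaves Shannon and all
rank-based statistics untouched.

PCoA eigendecomposes the Gower-centred squared-distance matrix. Bray–
Curtis is not Euclidean-embeddable, so negative eigenvalues are expected;
they are *discarded and counted*, never silently corrected, and the count
is part of the result so the quality of the planar approximation is
visible. Proportions explained are relative to the positive inertia.

PERMANOVA is the one-way partition $SS_{total} = \frac{1}{N}\sum_{i<j}
d_{ij}^2$, within-group sums by the same formula per group, pseudo-F
$(SS_B/(a-1))/(SS_W/(N-a))$. The permutation p-value uses the add-one
correction $(1+b)/(1+n_{perm})$, which can never return 0; with two groups
and at most 10,000 distinct assignments, exact enumeration is available
and includes the observed assignment in the tally. Procrustes analysis
centres both configurations, scales each to unit sum of squares, takes the
optimal rotation from the SVD of the cross-product, and reports
$M^2 = 1 - (\sum\sigma_i)^2$ with concordance $R = \sqrt{1-M^2}$; the
PROTEST permutation test permutes rows of the *second* configuration — the
first is the reference — again with the add-one correction. Axes of
unequal count are zero-padded to a common dimension.

## Biomarker scoring

The LEfSe-style scorer is a faithful re-statement of the published
two-stage recipe rather than a wrapper around the original tool. Stage 1
screens each feature by Kruskal–Wallis (equivalent to the rank-sum test
for two classes); following the workflow this package accompanies, the
screening p-values are BH-adjusted and features pass at $q < 0.05$ —
stricter than the raw-p screening of canonical LEfSe. Stage 2 rescales
samples to a common sum of 10⁶ and, over 30 bootstrap rounds that
subsample two-thirds of each class, fits a two-class linear discriminant
with a small ridge term ($10^{-6}$ × mean covariance diagonal) so the
$n \approx 36$, collinear-feature setting cannot produce a singular
within-class covariance. The per-round, per-feature effect is the average
of (i) the absolute class-mean difference of the feature and (ii) the
absolute contribution of the feature's unit-normalized discriminant weight
to the projected class-mean difference; the LDA score is
$\mathrm{sign} \times \log_{10}(1 + \text{mean effect})$, positive when
enriched in the first class level (alphabetical, i.e. cases before
controls here). The default reporting threshold is |score| ≥ 2; a stricter
4 reproduces headline-biomarker displays. The subclass (within-class
Wilcoxon) stage of canonical LEfSe is omitted: this cohort design has no
subclasses. Because of the common-sum rescaling, scores are invariant to a
global rescaling of the raw abundances.

## Classification

The random forest follows the field-standard implementation
(`randomForest`), with stratified k-fold cross-validation (default 10
folds, reduced with a warning when the smallest class cannot populate
them). Out-of-fold probabilities are pooled into a single AUC — at
n = 36, per-fold AUCs on 3–4 held-out samples are too unstable to average,
though they are reported too — and a final all-data forest supplies the
OOB error and both importance measures. MeanDecreaseGini is non-negative
by construction; *negative* importances, which do occur for uninformative
features, are a property of permutation importance (MeanDecreaseAccuracy),
so both are always reported and plots rank by Gini. No transformation of
covariates such as IgE is offered or needed: trees are invariant to
monotone transforms of individual features, so log- or rank-transforming
them cannot change the model.

## Pathway reporter scores

Per KO, groups are compared with a two-sided Wilcoxon test (a t-test is
selectable), the p-value clamped to $[10^{-10}, 1-10^{-10}]$ and converted
to a signed z-score $z = \Phi^{-1}(1-p/2)\cdot\mathrm{sign}(\Delta\,
\text{median})$ — the signed two-sided form makes direction explicit; the
original reporter-feature literature uses the one-sided
$\Phi^{-1}(1-p)$, and the two differ only in how direction is encoded, not
in null calibration. The pathway score is $z_{raw} = \sum z/\sqrt{k}$ over
the $k$ observed member KOs, standardized against a size-matched
background: for each distinct $k$, 1000 random KO sets (drawn without
replacement within a set, from all observed KOs) estimate $\mu_k$ and
$\sigma_k$, and $z_{adj} = (z_{raw}-\mu_k)/\sigma_k$. Significance is
$|z_{adj}| > 1.5$. Under a fully null KO table the exceedance of that
threshold is ~0.13 (the standard-normal value), so a "no significant
pathways" outcome on null-like data is the calibrated expectation, not a
power failure. A degenerate background ($\sigma_k = 0$, e.g. constant z
over a tiny KO universe) is an error advising a larger universe. KEGG
Level-3 grouping comes entirely from the user's pathway map; no KEGG data
ships with the package.

## Numerical and calibration choices

* Spearman p-values: the t approximation was validated to 4 decimals
  against three printed (ρ, n, p) anchors; a perfect $|\rho| = 1$ returns
  the exact-permutation floor $2/n!$ with a warning. The exact null tail
  at n = 19 is ~30% heavier than the t approximation around
  $|\rho| = 0.7$, one reason replicate-cohort networks carry slightly more
  borderline edges than the nominal FDR suggests.
* All permutation p-values use add-one corrections; every stochastic stage
  records its seed in its result, and `run_pipeline()` derives per-stage
  seeds from the single config seed via fixed offsets, so a run is
  reproducible end-to-end.
* Normalization is per kingdom by default (each kingdom's fractions sum to
  1 within a sample) because both communities derive from one metagenome
  but are reported as kingdom-specific relative abundances; joint
  normalization is available (`joint = TRUE`). An all-zero kingdom in a
  sample yields zero fractions, not NaN.
* Test and acceptance problem sizes were chosen to estimate each
  calibration property with a Monte-Carlo error small against its bound:
  e.g. PERMANOVA type-I error over 500 null datasets of 12 samples at 999
  permutations; copula calibration at n = 2000; the reporter null over 60
  seeds × 30 pathways (standard error ≈ 0.009 against the 0.15 bound).

## Known limitations

* Spearman networks on relative abundances are not compositionality-aware;
  within-kingdom closure still perturbs cross-kingdom ranks slightly.
  SparCC-style estimators are out of scope and noted as future work.
* The cohort-scale results of any particular study (its exact edge lists,
  PERMANOVA R², biomarker taxa) require that study's raw data; this
  package reproduces the *procedures* and validates them on synthetic
  cohorts with known truth.
* At n ≈ 19 per group, the |ρ| ≥ 0.6 floor has limited power: roughly half
  of true ρ = 0.8 couplings survive both filters, and BH admits ~5% false
  edges among discoveries. Topology-level conclusions (sign composition,
  hub identity) are far more stable than individual edges, and that is the
  level at which results should be read.
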