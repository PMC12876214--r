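# codysbiosis

Cross-kingdom microbiome network analysis for case-control cohorts, with a
focus on the **co-dysbiosis** phenomenon: the shift of a gut
bacterial–fungal interaction network from a competition-rich state (many
negative correlations) to a simplified, exclusively cooperative state (all
positive correlations) in disease.

The package is aimed at microbiome researchers analysing paired bacterial
and fungal genus-level abundance profiles from shotgun metagenomes of small
case-control cohorts (tens of samples), together with clinical covariates
such as total and allergen-specific serum IgE.

## What it computes

The core procedure infers, separately per group, a signed cross-kingdom
correlation network: for every (bacterial genus *b*, fungal genus *f*)
pair, Spearman's rank correlation ρ(b, f) is computed across the group's
samples; its two-sided p-value comes from the t approximation
t = |ρ|·√((n−2)/(1−ρ²)) on n−2 degrees of freedom; p-values are adjusted by
the Benjamini–Hochberg step-up over all cross-kingdom pairs tested within
the group; and an edge is retained when |ρ| ≥ 0.6 and q < 0.05. The
**co-dysbiosis index** of a network is the positivity fraction
n₊/(n₊+n₋) of its significant edges.

Around this core the package provides the full workflow of such a study,
each stage a data-frame-in/tibble-out function that chains with the pipe:

* alpha diversity (bias-corrected and classic Chao1, Shannon) and
  Wilcoxon rank-sum comparison;
* Bray–Curtis beta diversity, principal coordinate analysis with explicit
  negative-eigenvalue accounting, one-way PERMANOVA (permutation or exact
  enumeration), and Procrustes/PROTEST comparison of ordinations with
  M² = 1 − (Σσ)² and R = √(1−M²);
* group-comparison tests from raw data (Wilcoxon) or summary statistics
  (unpaired t, 2×2 χ²);
* LEfSe-style biomarker discovery: Kruskal–Wallis screening with BH-FDR,
  then a bootstrapped, ridge-regularized linear-discriminant effect size
  reported as a log10 LDA score;
* cross-validated random-forest discrimination with MeanDecreaseGini and
  permutation importance, pooled cross-validation AUC and OOB error;
* ReporterScore pathway aggregation of per-KO group differences
  (z = Φ⁻¹(1−p/2)·sign(Δ), pathway score Σz/√k standardized against
  size-matched random KO sets);
* a Gaussian-copula synthetic cohort generator that plants cross-kingdom
  Spearman couplings (latent Pearson r = 2·sin(πρ/6)), group-wise depleted
  taxa, zero inflation, and IgE covariates rank-coupled to focal fungi —
  so every stage is testable without access to cohort data.

Results carry broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 graphics; networks export to
attribute-complete GraphML for Gephi.

## Worked example

Simulate the default two-group cohort (19 cases "ARFC", 17 controls "HC";
a control regime of 44 negative + 7 positive planted couplings against an
exclusively positive case regime of 17), then build and compare the two
networks:

```r
library(codysbiosis)
library(dplyr)

sim <- simulate_cohort(synthetic_spec(seed = 7))
rel <- to_relative_abundance(sim$abundance)

nets <- lapply(c(HC = "HC", ARFC = "ARFC"), function(g)
  build_cross_kingdom_network(rel, sim$metadata, g, pipeline_config()))

bind_rows(lapply(nets, glance))
#> # A tibble: 2 × 8
#>   group n_nodes n_edges n_positive n_negative positivity_fraction n_pairs_tested
#>   <chr>   <int>   <int>      <int>      <int>               <dbl>          <int>
#> 1 HC         48      24          1         23              0.0417           3600
#> 2 ARFC       18       9          9          0              1                3600

compare_networks(nets$HC, nets$ARFC)
#> # Network comparison: HC vs ARFC
#>   edges: 24 vs 9; positive: 1 vs 9; negative: 23 vs 0
#>   positivity fraction: 0.042 vs 1.000 (difference 0.958)
#>   shared pairs: 6 (6 sign flips); unique: 18 / 3; hub turnover: 0.60
```

At n = 19 the strong (ρ = 0.8) planted couplings are only partially
recovered — 9 of 17 case-group edges here survive both the |ρ| ≥ 0.6 floor
and BH-FDR — but every recovered case edge is positive, so the case
network's co-dysbiosis index is 1.0 versus 0.04 in the control network: the
complete sign reversal is recovered even where individual edges are not.

Single statistics work the same way from summary data, e.g. the total-IgE
group contrast and a printed-correlation p-value:

```r
t_test_from_summary(285.6, 102.4, 19, 65.3, 28.7, 17)
#> # A tibble: 1 × 5
#>       t    df      p_value variant degenerate
#>   <dbl> <dbl>        <dbl> <chr>   <lgl>
#> 1  8.99  21.1 0.0000000115 welch   FALSE

round(spearman_pvalue(-0.75, 17), 4)
#> [1] 5e-04
```

`run_pipeline(outdir)` executes the whole workflow (simulation or supplied
tables → diversity → ordination/PERMANOVA/Procrustes → biomarkers →
networks per group → comparison → classification → pathway reporter
scores) and writes per-stage TSV/JSON outputs plus a seeded manifest.

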