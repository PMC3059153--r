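# unifyexpr

Unified gene expression measures across platforms by single-factor
maximum-likelihood factor analysis.

## The problem

When the same samples are profiled on several expression platforms, each
platform reports a noisy, platform-specific rendering of the same
underlying transcript abundance. Averaging the platforms treats them as
equally trustworthy, so one platform with mis-annotated probes, background
signal or poor dynamic range corrupts the combined value. `unifyexpr` is
for analysts integrating such multi-platform data (e.g. tumor cohorts run
on two Affymetrix designs and an Agilent array) who want a per-gene,
per-sample expression estimate that automatically down-weights discordant
inputs — plus the diagnostics to know when that estimate should not be
trusted.

## The model

Per gene, the standardized log2 measurements y = (y₁, …, y_p)′ of a sample
follow the one-factor model

    y = λ f + e,   f ~ N(0, 1),   e ~ N(0, Ψ),   Σ = λλ′ + Ψ

with unit-diagonal constraint ψⱼ = 1 − λⱼ², so λⱼ is the correlation
between input j and the latent expression level f. Parameters are fitted
by maximum likelihood (EM with quasi-Newton refinement); the unified
expression is the Thomson (regression) factor score

    f̂ = λ′Σ⁻¹y = (1 + λ′Ψ⁻¹λ)⁻¹ λ′Ψ⁻¹ y,

a weighted average of the inputs whose weights grow with the loadings. In
gene-level mode p is the number of platforms (≥ 3 required); in probe-level
mode p is the total probe count across platforms. Fits with a uniqueness
at its floor are flagged as Heywood cases; weak or negative loadings, low
expression and low dynamic range are flagged by QC. Bootstrap standard
errors for λ, a simulation framework comparing the factor estimate with
plain averaging, and precision/accuracy statistics (pooled replicate
variance, squared distance to a reference technology, fold changes, ROC)
round out the toolkit.

## Worked example

A synthetic three-platform data set (the same generator the tests use;
`disc01` is a gene planted with loadings ≈ (0.9, 0.9, 0.1), i.e. a
misbehaving third platform):

```r
library(unifyexpr)

fx   <- generate_fixtures(file.path(tempdir(), "fx"), seed = 42,
                          n_samples = 120)
mats <- lapply(fx[c("u133", "exon", "agilent")], read_expression_tsv)
th   <- gene_qc_thresholds(min_median_expression = c(u133 = 4, exon = 4,
                                                     agilent = 0))
ue <- unify_gene_level(mats, thresholds = th)
ue
#> Unified expression (gene-level): 38 gene(s), 120 sample(s), 2 skipped

rec <- ue$genes[["disc01"]]
round(rec$loadings, 3)
#>    u133    exon agilent
#>   0.764   0.999   0.092
round(rec$weights, 3)
#>    u133    exon agilent
#>   0.002   0.998   0.000
head(ue$skipped)
#>   gene_id                              reason
#> 1  twop01 present on 2 platform(s), need >= 3
#> 2  twop02 present on 2 platform(s), need >= 3
```

The discordant agilent row gets loading 0.09 and essentially zero weight:
the unified scores are driven by the two concordant platforms. (The exon
loading sits at the Heywood boundary — `rec$heywood` is `TRUE` — which the
QC table reports so the gene can be treated with care.) Genes present on
fewer than three platforms are skipped with a reason, never dropped
silently. `write_unified_tsv(ue, "unified.tsv")` writes the score matrix
plus `unified_qc.tsv` (loadings, uniquenesses, Heywood/convergence flags,
QC flags per gene) and `unified_skipped.tsv`.

Uncertainty of the loadings for that gene:

```r
std <- standardize(do.call(rbind, lapply(mats, function(m) m["disc01", ])))
bootstrap_loading_se(std, n_boot = 100, seed = 1)
#> Bootstrap SE of loadings (100 replicates, 0 failed, seed 1)
#>           u133   exon agilent
#> loading 0.7641 0.9995  0.0922
#> se      0.1093 0.1081  0.1330
```

And the simulation comparison against plain averaging, under the
configuration where two platforms are strong (λ ∈ [0.90, 0.98]) and one is
weak (λ ∈ [0, 0.30]):

```r
res <- run_configuration(sim_config(rbind(c(.90, .98), c(.90, .98),
                                          c(.00, .30)),
                                    n_samples = 200, n_genes = 50, seed = 1))
summary(res)
#>  n_genes n_samples median_sse_fa median_sse_avg fa_win_rate n_nonconverged n_heywood
#>       50       200      20.36326       49.83851           1              0        28
```

The factor estimate halves the median squared error against the true
latent values and beats the average for every simulated gene in this
regime. `standard_sim_configs()` bundles the full set of twelve loading
configurations.

A command-line wrapper ships at `inst/cli/unifyexpr`
(`unifyexpr {fixtures, unify-gene, unify-probe, simulate, bootstrap,
evaluate-precision, evaluate-accuracy}`); every run writes a log and a
serialized copy of its configuration beside its outputs.

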