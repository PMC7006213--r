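# SurvCoC

Integration of clinical covariates and multi-omics data for cancer
prognosis with Cox proportional-hazards models, built for the common
colon-cancer setting: a few hundred patients with TNM stage and age, plus
gene-expression (FPKM), DNA-methylation (beta value) and miRNA (RPM)
matrices with thousands of features each.

The package is aimed at biostatisticians who want the full pipeline —
per-layer feature filtering, prognosis-driven hierarchical-clustering
dimension reduction, cluster-of-clusters integration, multi-covariate Cox
modelling, and a resampling-based discrimination-comparison framework —
as tested, reusable components rather than a one-off analysis script.

## The method

Each omics layer is reduced to one categorical covariate by clustering
patients hierarchically over a grid of 7 distance metrics × 8 linkages ×
cluster numbers 2–11 (every cluster ≥ 10 patients) and selecting the
combination whose Cox model has the best bias-corrected Harrell's
concordance. The per-layer labels can be integrated once more by
clustering the binary patient-by-cluster matrix (cluster-of-clusters).
Labels then enter the hazard model next to the clinical factors:

    h(t) = h0(t) · exp( Σ βn·zn + Σ βm·zm )

where `zn` are treatment-coded clinical covariates (T/N/M stage, age
quartile bins) and `zm` the cluster-label covariates. Models over all
covariate combinations (`CGMm`, `CGM`, …, `C`, `G`, `M`, `m`, `CA`) are
compared by bootstrap optimism-corrected Harrell's C and by 2/3/5-year
IPCW (Uno) concordance under repeated event-stratified cross-validation,
with paired Wilcoxon signed-rank tests and nested likelihood-ratio tests.

A synthetic-cohort generator with latent prognostic subtypes expressed in
all three layers provides ground truth for every stage; see the methods
vignette (`vignettes/survcoc-methods.Rmd`) for the model, parameter
defaults, numerical choices and limitations.

## Worked example

```r
library(SurvCoC)

coh <- generateCohort(cohortConfig(nSamples = 200, censorRate = 0.5, seed = 42))
sv  <- cohortSurvival(coh)
clinDesign <- encodeCovariates(cohortClinical(coh))

expr <- imputeMedian(selectFeatures(filterLowQuality(cohortLayers(coh)$expression),
                                    topFrac = 0.25))
search <- clusterGridSearch(expr, sv, companions = clinDesign,
                            grid = clusterGridSpec(c("manhattan", "canberra"),
                                                   c("ward_d", "average"),
                                                   kRange = 2:6),
                            evalCfg = evalConfig(searchB = 50, seed = 1),
                            labelPrefix = "G")
search
#> ClusterSearchResult: 20 candidates (9 feasible), score=bias-corrected Harrell's C (B=50), with companion covariates
#>   winner: canberra / ward_d / k=4 (score 0.7316)

adjustedRand(clusterAssignments(winningLabels(search)), trueSubtype(coh))
#> [1] 0.838368

design <- encodeCovariates(cohortClinical(coh),
                           clusters = list(G = winningLabels(search)))
fit <- fitCox(design, sv)

optimismCorrectedC(design, sv, B = 200, seed = 2)
#> BootstrapCResult: apparent C 0.7626, bias-corrected 0.7227 [0.6691, 0.7743], B=200 (17 redrawn)

cvUnoC(design, sv, taus = c(730, 1095, 1825), iters = 50, seed = 3)
#> CVConcordance: 50 iterations x 5-fold
#>   tau   730 days: mean C = 0.7139
#>   tau  1095 days: mean C = 0.7179
#>   tau  1825 days: mean C = 0.7121
```

The search table says that of the 20 clustering candidates, 9 satisfied
the 10-patient minimum cluster size and fitted; the winner (canberra
distance, Ward linkage, 4 clusters) recovers the planted 3-subtype
structure up to one extra split (adjusted Rand 0.84 against truth). The
fitted clinical+expression model's apparent concordance 0.763 shrinks to
0.723 after bootstrap optimism correction, and holds about 0.71–0.72
under cross-validated Uno's C at all three horizons — the discrimination
one would report for these patients.

The full 12-model comparison, including the cluster-of-clusters model and
the leave-one-covariate-out ablation, runs from a single configuration:

```r
res <- runPipeline(list(seed = 7,
                        cohort = list(simulate = list(nSamples = 344)),
                        models = list(includeCoc = TRUE, ablation = TRUE),
                        outdir = "run1"))
res$comparison          # CGMm against every other model
```

A thin command-line dispatcher over the same functions ships at
`inst/cli/survcoc.R` with subcommands `simulate`, `run`, `metrics` and
`compare`.

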