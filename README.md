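# ckmtopics

Mixed-membership topic modelling of clinical biomarker panels for
discovering candidate cardiovascular-kidney-metabolic (CKM) subtypes.

Cardiovascular disease, chronic kidney disease and type 2 diabetes
co-occur in patterned ways that a single diagnosis label hides.
`ckmtopics` implements a complete, testable pipeline for resolving that
heterogeneity from routine blood and urine measurements in a population
cohort:

1. **Discretization** — continuous biomarkers into five sex-stratified
   percentile bins (thresholds at the 10/30/70/90th percentiles); blood
   pressure into guideline categories (normal / elevated / hypertensive).
2. **Topic model** — a Bayesian mixed-membership model over (biomarker,
   bin) tokens, fitted by collapsed Gibbs sampling (Rcpp). Each
   participant gets a loading vector `θ` (a 0–100% score per profile);
   each profile is a probability table `φ` over biomarker bins. Missing
   biomarkers simply contribute no token, so partially measured
   participants need no imputation. The number of profiles K is chosen by
   held-out predictive likelihood on a 1:2 training–validation split.
3. **Chain alignment** — independent MCMC chains are relabelled by
   optimal-transport matching (squared-Hellinger cost, exact assignment
   solver), non-replicating topics are excluded by silhouette score, and
   pooled samples give 95% credible intervals. Convergence is diagnosed
   by an R-hat on loading entropy.
4. **Phenotype association** — multivariate OLS of rank-transformed
   loadings on demographics, anthropometrics and self-reported disease,
   Bonferroni-corrected. A topic simultaneously, significantly and
   positively associated with kidney disease, type 2 diabetes and
   cardiovascular disease is a candidate CKM subtype; all-negative makes
   it protective. Prevalence is computed under a 50% loading threshold
   with a sensitivity sweep.
5. **Genetics** — per-platform GWAS of rank-inverse-normal loadings,
   fixed-effect inverse-variance meta-analysis across genotyping
   platforms, genomic-control λ, greedy LD clumping to lead variants, and
   polygenic risk scores validated by logistic regression in a disjoint
   cohort.

A synthetic-cohort generator (`gen_config()` / `generate_cohort()` /
`generate_genotypes()`) emulates this data structure — latent topics,
block-missing biomarkers, disease risk logistic in the loadings, variants
in LD blocks with additive effects on loadings, three genotyping batches —
with full ground truth recorded, so every stage is benchmarked without
access-restricted data.

## Worked example

Simulate a small cohort with one disease-promoting and one protective
topic planted, fit four chains, align and filter, and classify subtypes:

```r
library(ckmtopics)

w <- c(1.5, -1.5, 0)   # topic 1 raises disease odds, topic 2 lowers them
specs <- list(disease_spec("kidney_disease", qlogis(0.08), w),
              disease_spec("t2dm",           qlogis(0.10), w),
              disease_spec("cvd",            qlogis(0.12), w))
cfg <- gen_config(n_participants = 2000, n_features = 12, K_true = 3,
                  disease_specs = specs, seed = 42)
coh <- generate_cohort(cfg)

chains <- fit_chains(coh$binned, K = 3, n_chains = 4, base_seed = 42,
                     n_burn = 300, n_samples = 50, thin = 2)
ens <- silhouette_filter(align_ensemble(chains))
ens
#> <ckm_ensemble> 4 chains, K = 3, 3 robust topic(s)
ens$silhouette
#> # A tibble: 3 × 3
#>   topic silhouette robust
#>   <int>      <dbl> <lgl>
#> 1     1      0.993 TRUE
#> 2     2      0.994 TRUE
#> 3     3      0.995 TRUE
entropy_diagnostic(chains)
#> <ckm_diagnostic> PASS: 100.0% of participants with R-hat < 1.10

design <- coh$pheno[, c("sex", "age", "smoking", "bmi", "whr", "weight",
                        "kidney_disease", "t2dm", "cvd")]
classify_subtypes(associate(ens$theta_mean, design))
#> # A tibble: 3 × 2
#>   topic  call
#>   <chr>  <chr>
#> 1 topic1 protective
#> 2 topic2 neither
#> 3 topic3 candidate_CKM
```

All three fitted topics replicate across chains (silhouette ≈ 0.99), the
entropy R-hat diagnostic passes, and exactly one candidate CKM subtype and
one protective profile are called — the planted structure. Fitted topic
labels are arbitrary (here fitted `topic3` is the planted disease topic);
`match_topics(truth_phi, pooled_phi(ens))` maps them onto a reference.

`tidy()` / `glance()` methods give tibble views of chains, ensembles and
GWAS tables, and `plot_profiles()`, `plot_qq()`, `plot_manhattan()` and
`plot_score_curve()` give the standard figures. `run_stage()` (or
`inst/scripts/ckm-topics.R`) drives the same pipeline as file-based stages
with run manifests.

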