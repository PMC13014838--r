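---
title: "Discovering cardiovascular-kidney-metabolic subtypes from biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cardiovascular-kidney-metabolic subtypes from biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckmtopics)
```

## The problem

Cardiovascular disease, chronic kidney disease, type 2 diabetes and obesity
co-occur far more often than chance, and the umbrella label
cardiovascular-kidney-metabolic (CKM) syndrome hides substantial
heterogeneity: different people arrive at the same diagnoses through
different metabolic routes. `ckmtopics` implements a data-driven route to
candidate CKM subtypes from routine blood and urine panels in a population
cohort: discretize the biomarkers, model them with a Bayesian
mixed-membership (topic) model, keep only topics that replicate across
independent MCMC chains, classify topics by their simultaneous association
with kidney disease, type 2 diabetes and cardiovascular disease, and then
interrogate the genetic basis of each candidate subtype with a
quantitative-trait GWAS of its loadings and a polygenic-score validation in
a second cohort.

Because the cohorts this kind of analysis runs on are access-restricted,
the package ships a synthetic-cohort generator with fully recorded ground
truth; every stage of the pipeline is exercised and benchmarked against
that truth.

## The model

Each participant $i$ contributes one token per *observed* biomarker: the
token is the pair (feature, level), where levels are sex-stratified
percentile bins (five bins with thresholds at the 10th, 30th, 70th and
90th percentiles; blood pressure instead uses the three 2017 ACC/AHA
categories normal / elevated / hypertensive). The model is the standard
multinomial mixed-membership form: topic $k$ is a probability vector
$\phi_k$ over the $(feature, level)$ vocabulary, participant $i$ carries a
loading vector $\theta_i$ on the simplex, and each token is drawn from the
$\theta_i$-mixture of the $\phi_k$. Symmetric Dirichlet priors
($\alpha = 1/K$ over topics, $\beta_h = 0.1$ over the vocabulary, both
overridable) complete the model.

Missing biomarkers simply contribute no token. This is the whole
missing-data treatment: the collapsed Gibbs sampler conditions on the
observed tokens only, so no imputation is ever performed. Missingness is
assumed MCAR per feature — an assumption, since nothing in the data can
distinguish it here; MNAR mechanisms are out of scope.

### Inference

A collapsed Gibbs sampler (Rcpp) resamples each token's topic assignment
from

$$P(z = k \mid \cdot) \propto
  (n_{dk}^{-} + \alpha)\,
  \frac{n_{kv}^{-} + \beta_h}{n_k^{-} + V\beta_h},$$

where the $-$ counts exclude the token being resampled. Defaults are 500
burn-in sweeps and 100 retained samples (thinning 5), per-chain seed =
base seed + chain index, eight chains. Retained samples store two things
per sweep: the Rao-Blackwellized conditional means
$\hat\phi_{kv} = (n_{kv}+\beta_h)/(n_k+V\beta_h)$ and
$\hat\theta_{dk} = (n_{dk}+\alpha)/(n_d+K\alpha)$, which are the point
estimates, and an exact conditional draw
$\phi \mid z \sim \mathrm{Dirichlet}(n_{k\cdot}+\beta_h)$. The draw matters
for interval estimation: quantiles of the conditional means alone
understate posterior width (they omit the Dirichlet resampling step), and
in our coverage checks that distinction moved empirical coverage of the
95% credible intervals from roughly 70% to 94%. A participant with zero
observed biomarkers keeps the prior loading $1/K$ and is counted in a
warning.

### Choosing K

Participants are split 1:2 into training and validation (the literal
reading of a 1:2 train:validation ratio; `train_frac` switches it). For
each candidate K the model is fitted on the training third and scored on
the validation two-thirds by document completion: the even-indexed half of
each validation participant's tokens estimates their loading (a
deterministic EM fixed point with the training $\phi$ frozen — fully
reproducible, no extra MCMC), and the mean per-token predictive
log-likelihood of the held-back odd-indexed half is the score. Ties break
toward smaller K (parsimony). Validation participants with fewer than two
tokens are excluded and counted.

### Convergence

The diagnostic follows the within- versus between-chain variance logic of
potential scale reduction, applied to the entropy of the loading vector,
$H_i = -\sum_k \theta_{ik}\log\theta_{ik}$, computed per participant per
retained sample per chain. Entropy is invariant to topic relabeling, so
the diagnostic needs no prior chain alignment. The ensemble passes when
$\hat R < 1.1$ for at least 99% of participants. (With a single value per
chain a within-chain variance would not exist, which is why the statistic
is computed over retained samples.)

## Aligning chains and filtering topics

Topic labels are arbitrary per chain. Chains are aligned to the first
chain by balanced optimal transport with uniform marginals — a linear
assignment, solved exactly by a Jonker-Volgenant shortest-augmenting-path
routine — with pairing cost the squared Hellinger distance between
topic-level rows (bounded, symmetric, natural for probability vectors).
Tie-breaks are the solver's deterministic scan order. After relabeling,
samples from all chains are pooled into posterior means and 95%
equal-tailed credible intervals per (topic, vocabulary entry).

A topic that replicates should place each chain's posterior-mean $\phi$
row in a tight cluster. We score this with the standard silhouette
(Euclidean distance; `cluster::silhouette`), one point per chain per
topic, and retain topics with mean silhouette at or above 0.1 (default,
configurable). Zero-width clusters are defined to score 1; K = 1 leaves
the silhouette undefined and the single topic is retained with a warning.

## Phenotype association and subtype calls

Posterior-mean loadings are rank-transformed — fractional ranks
$(r-0.5)/n$ with average ranks for ties, optionally pushed through the
standard-normal quantile function — and regressed jointly on demographics,
anthropometrics and self-reported disease indicators by ordinary least
squares, one regression per topic, with two-sided t-tests per coefficient
and complete-case rows. Bonferroni correction uses a family of topics
$\times$ predictors within the analysis block (configurable). The rank
transform makes every p-value invariant to strictly monotone re-scorings
of the loadings.

A topic is called a **candidate CKM subtype** when its kidney disease,
type 2 diabetes, and cardiovascular disease coefficients are all positive
and all significant after correction; **protective** when all three are
negative and significant; otherwise neither. Prevalence counts
participants whose loading (or summed loading over the candidate topics)
reaches a threshold, 0.5 by default with a sensitivity sweep over
(0.5, 0.4, 0.3); prevalence is monotone nonincreasing in the threshold by
construction.

## Genetic association

The GWAS response is the rank-inverse-normal transform of the
posterior-mean loading (raw fractional ranks are an option): loadings are
strongly skewed, and RINT protects the calibration of the per-variant OLS.
Each genotyping platform is analysed separately (additive dosage + model
covariates, exact one-pass OLS via Frisch-Waugh-Lovell residualization)
and the three platforms are combined by fixed-effect inverse-variance
weighting — the standard treatment for batch-split single-cohort GWAS.
Genomic inflation is summarized by
$\lambda_{GC} = \mathrm{median}(\chi^2_1(1-p)) / 0.4549$. Genome-wide
significance defaults to $p < 10^{-8}$. Lead variants come from greedy
clumping: take the smallest-p unclaimed significant variant, claim
everything within 500 kb at sample $r^2 \ge 0.1$, repeat — a deterministic
internal stand-in for web-based post-GWAS tooling. Per-subtype polygenic
risk scores are $\sum_j \beta_j g_{ij}$ over lead variants, standardized,
and validated by logistic regression (linear-probability option) of each
disease on the score plus covariates in a disjoint cohort.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
not the marginal realism of any particular biobank:

* topics: per feature, K level-distributions drawn from a sharp Dirichlet
  (`topic_sharpness`, default 0.1);
* loadings: $\theta_i \sim \mathrm{Dirichlet}(\alpha_{gen})$, default
  concentration 0.3 per topic (sparse mixed membership);
* genetics: biallelic variants in LD blocks (shared latent haplotype with
  copy probability 0.9, within-block dosage $r^2 \approx 0.65$,
  independence between blocks), three genotyping platforms split
  0.12 / 0.45 / 0.43; variant $j$ tilts the loading concentration
  multiplicatively, $\alpha_{ik} = \alpha_{gen,k}\exp(\gamma_{jk} g_{ij})$,
  a monotone dosage-to-loading path that never leaves the simplex;
* diseases: Bernoulli with logit linear in $\theta$ — the weakest
  structure that makes the sign-based subtype rule recoverable;
* missingness: MCAR per feature at configurable rates (e.g. 65.5% missing
  mirrors a marker observed for about a third of a cohort);
* demographics (age, sex, smoking, BMI, WHR, weight, blood pressure) are
  independent of topics by default so type-I-error checks run under a
  true null;
* continuous biomarker values are synthesized by placing each generated
  level in its percentile band of a Gaussian scale with a sex shift, so
  the discretization module can be exercised end to end.

Everything is reproducible bit-for-bit from the config seed, and the
ground truth (topics, loadings, masks, effects) is returned alongside the
data.

What passing tests on this generator do **not** show: robustness to MNAR
missingness, to realistic biomarker marginals and measurement error, to
relatedness or population stratification (cohorts are unrelated and
homogeneous by construction), or to model-class mismatch beyond the
one-token-per-feature structure. One such mismatch is visible and
documented: the generator emits exactly one token per observed feature,
while the model treats tokens as exchangeable; when missingness differs
across features, the estimable token distribution weights each feature by
its observation rate, and comparisons against the truth account for that
reweighting.

## Benchmark configurations

The package's evaluation functions (`eval_*`, also driven by
`scripts/acceptance.R`) freeze the following study conditions, chosen once
at design time:

* **Topic recovery**: n = 3000, 20 features × 5 bins, K_true = 5,
  sharpness 0.1; 4 chains × (500 burn-in + 100 retained sweeps); mean
  best-matched total-variation distance between pooled and true topics
  (typically ≈ 0.03, required < 0.10).
* **Model selection**: the same generator, grid K ∈ {2..8}, 20 seeded
  runs; selected K ∈ {4,5,6} required in ≥ 90% (observed: the score curve
  peaks at 5 essentially always).
* **Association calibration**: 1000 null replicates at n = 200;
  uncorrected type-I error within [0.035, 0.065]; the OLS path is also
  checked against a hand-computed 6-row closed form at 1e-10.
* **Subtype recovery**: planted weights ±1.5 log-odds on topics 1-4
  (topic 5 null) on baseline prevalences 8/10/12%, n = 5000, 100
  simulations. The weights are moderate by design: much larger planted
  weights make the *null* topic's loading significantly associated with
  disease through the simplex constraint (loadings sum to one, so strong
  effects on other topics curve back), which is a genuine property of
  compositional scores, not an artifact.
* **GWAS**: null calibration at m = 20,000 (λ within [0.95, 1.05], no
  hits below 1e-8); power with a variant explaining ≈ 1% of RINT-loading
  variance at n = 5000 (γ = 0.17, MAF 0.3), compared against the analytic
  noncentral-χ² power evaluated at the population R² (estimated once on a
  large independent draw — evaluating it at each run's realized R² would
  correlate the oracle with the outcome).
* **Clumping**: three causal variants in three LD blocks on separate
  chromosomes, γ = 0.35, n = 4000; exactly three leads required in ≥ 90%
  of runs.
* **PRS**: ten causal variants across ten blocks (γ = 0.2), discovery
  n = 5000, disjoint validation n = 10,000, disease loaded on the causal
  topic; PRS-disease p < 0.01 with positive sign required in ≥ 90% of
  runs, with permuted outcomes as the uniform negative control.
* **Constellation power**: one variant (γ = 0.22, MAF 0.3) tilting a
  moderately diffuse topic (sharpness 0.3) with 50% missingness on every
  biomarker, n = 5000. The topic-loading GWAS sees the aggregated signal
  (p ≤ 1e-15 across seeds) while the best of the 100 single
  (feature, level) indicator GWAS — each with half the effective sample
  and a fraction of the signal — stays far above genome-wide significance.
  The loading here is the generative profile score, isolating the
  aggregation mechanism; recovery of loadings by the sampler is the topic
  of the first benchmark.

These sizes keep the full benchmark suite within a few minutes on one
CPU; they are the package's own desk-scale choices.

## Numerical choices and degenerate inputs

* Percentiles use the linear-interpolation (type 7) definition; values
  exactly equal to a threshold fall in the lower bin (right-closed lower
  bins), so occupancy never exceeds nominal on tied data.
* An all-missing feature for one sex is a named error at bin fitting; an
  all-constant feature collapses all four thresholds to that constant.
* Monomorphic variants yield NA effects and are excluded downstream with
  a count; a platform with an undefined estimate contributes zero weight
  to the meta-analysis; a variant undefined on every platform stays
  undefined.
* All-equal loadings rank-transform to 0.5 everywhere with a warning;
  duplicated predictors raise a collinearity error naming the columns.
* The K-selection tie-break is toward smaller K; the alignment solver's
  tie-break is its deterministic scan order; clumping is deterministic
  given the table and genotypes.

## Known limitations

* The topic model is a stated stand-in for the general mixed-membership
  family: visible behaviours (0-100% profile scores, per-level probability
  bars with credible intervals, missing-data conditioning) pin down this
  form, but other parameterizations could match them too.
* Credible intervals are Bayesian statements under the multinomial token
  model; under the stratified generator their frequentist coverage is
  close to, but not guaranteed at, nominal.
* The Bonferroni family (topics × predictors per analysis block) is one
  defensible choice among several; it is configurable.
* Whether blood-pressure categorization should fold in antihypertensive
  medication is unresolved; the package categorizes measured pressures
  only.
* FUMA-style functional annotation, LD-score regression, histone-mark
  tissue specificity and gene-set enrichment are deliberately not
  implemented; clumping is the only post-GWAS step.
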