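---
title: "Grouped-latent structural equation models for imaging genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped-latent structural equation models for imaging genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

igsem fits a structural equation model that connects candidate genetic
variants to brain region measurements through a small set of latent
variables. Each latent variable represents one *region group* — a set of
brain regions expected to respond similarly to genetic variation (in
practice, regions with a shared transcriptional profile in the healthy
brain). The measurement part relates the q observed region measurements
$x_i$ to the m latents $z_i$,

$$x_i = B z_i + \zeta_i,$$

where the q×m loading matrix $B$ is block-sparse: every region loads on
exactly one latent, the one of its own group. The structural part drives
the latents from the p observed SNP values $g_i$ (additive 0/1/2 coding,
centred),

$$z_i = A g_i + \varepsilon_i.$$

Both error terms are zero-mean Gaussian; $\varepsilon$ has a diagonal
covariance $\Psi$ with one free variance per latent, and $\zeta$ has a
diagonal covariance $\Theta$ with **one shared variance per region group**
(the same homogeneity that principal component analysis assumes within a
block). The latents are never observed, so fitting works entirely through
the covariance the model implies for the observed vector $(g, x)$:

$$
\Sigma \;=\;
\begin{pmatrix}
\Sigma_{gg} & \Sigma_{gg} A^\top B^\top \\
B A \Sigma_{gg} & B A \Sigma_{gg} A^\top B^\top + B \Psi B^\top + \Theta
\end{pmatrix}.
$$

$\Sigma_{gg}$ is fixed at the observed SNP covariance — SNPs are exogenous,
so nothing in the model parameterizes their covariance and profiling it out
removes p(p+1)/2 parameters from the search. Estimation minimizes the
normal-theory discrepancy

$$F(\theta) = \log|\Sigma(\theta)| + \operatorname{tr}(S\Sigma(\theta)^{-1})
  - \log|S| - (p+q),$$

whose minimizer is the Gaussian maximum likelihood estimate; $F \ge 0$ with
equality exactly when the model reproduces the sample covariance $S$
(computed with divisor n, the maximum-likelihood convention).

### Identifiability

A latent variable has no intrinsic scale. We fix the loading of the *first*
region of each group (in region order) to 1, which both sets the scale and
gives the latent the direction of its anchor region: shrinkage of the
anchor shows up as a decrease of the latent score. Groups with a single
region are rejected outright — with one indicator the free loading and the
group residual variance cannot be separated. The free parameter count is
then $(q - m) + mp + m + m$.

## Estimation details

The optimizer is BFGS with an analytic gradient of $F$ in all free
parameters; variances enter on the log scale so they remain positive
without constraints (a latent variance estimated at the boundary shows up
as `psi` numerically zero, not as a negative Heywood value). Starting
values are neutral: anchors and free loadings 1, $A = 0$, and both variance
sets at half the mean observed region variance. Convergence requires a
gradient norm below 1e-6 or a discrepancy change below 1e-10 between two
successive optimizer passes; on failure up to five restarts from jittered
starting points are attempted, and a fit that still fails is returned with
`converged = FALSE` (and a warning) rather than silently.

Because $\Sigma_{gg}$ equals the observed SNP covariance block and both
$\Psi$ and $\Theta$ are positive, the implied covariance is positive
definite at every point the optimizer can visit — the search never needs a
penalty barrier.

### Robust (sandwich) standard errors

Genotypes are discrete, so the normality behind the expected-information
standard errors does not hold. `robust_adjust()` keeps the ML point
estimates and replaces their covariance with the sandwich

$$\widehat{\operatorname{acov}}(\hat\theta) =
  (\Delta^\top W \Delta)^{-1} \Delta^\top W\, \hat\Gamma\, W \Delta
  (\Delta^\top W \Delta)^{-1} / n,$$

where $\Delta$ is the Jacobian of the unique elements of $\Sigma$ with
respect to the free parameters, $W$ the normal-theory weight matrix at the
optimum, and $\hat\Gamma$ the empirical fourth-moment covariance of the
sample-covariance elements. Two-sided Wald p values follow. Two numerical
notes:

* $\hat\Gamma$ is never formed explicitly — the meat is computed as the
  covariance of per-observation projections, which keeps the cost linear
  in n.
* When n does not exceed the number of unique second moments (true even at
  the default n = 500 with 70 observed variables), $\hat\Gamma$ is
  rank-deficient. The sandwich itself remains well defined; the condition
  is recorded in `robust_moment_flag` instead of warning on every default
  fit.
* At boundary optima (a group's latent variance at zero, typical under a
  deliberately misspecified grouping) the loadings of that group are not
  identified and the expected information is singular. The adjustment then
  pseudo-inverts over the identified subspace and sets `robust_pinv`;
  SNP-weight inference, which is what downstream ranking uses, lives in
  the identified part.

We implement robust standard errors and Wald p values only; a scaled
chi-squared model-fit statistic is out of scope because nothing downstream
consumes it. Whether the latent residuals should be allowed to covary is
genuinely open — the minimal reading of the model is a diagonal $\Psi$,
which is the default and the only fitted form here.

### Bartlett scores

Per-individual latent estimates use the measurement part only:
$\hat z_i = (B^\top \Theta^{-1} B)^{-1} B^\top \Theta^{-1} x_i$ with the
estimated $B$ and $\Theta$. Since
$(B^\top\Theta^{-1}B)^{-1}B^\top\Theta^{-1}B = I$, the estimator is
conditionally unbiased, and it can score samples the model was never
fitted on — that is exactly how a validation half is scored with training
estimates in `score_validation()`. A variant conditioning on the genotypes
would shrink the scores toward $A g_i$; it is deliberately not provided,
keeping the scores a function of the brain measurements alone.

## The synthetic-data generator

`simulate_dataset()` draws the study conditions the evaluation is defined
on:

| parameter | default | meaning |
|---|---|---|
| `n_individuals` | 500 | samples per replicate |
| `n_snps` | 20 | SNPs, independent, HWE with MAF ~ Beta(1, 2) |
| `group_sizes` | 20/10/10/5/5 | five region groups, 50 regions |
| `n_nonzero_A` | 10 | SNP-to-latent weights set to ±1 |
| `loading_range` | (0.5, 1.5) | uniform nonzero loadings in B |
| `latent_noise_sd`, `region_noise_sd` | 2 | Gaussian noise, both layers |
| `n_phenotype_latents` | 2 | latents with phenotype weight ±10 |

The binary phenotype is Bernoulli with success probability
$\operatorname{logit}^{-1}(w^\top z_i)$ and **no intercept** — the weights
are the only stated part of the phenotype model, and with zero-mean latents
the base rate is ½ in expectation. Latents are driven by *centred*
genotypes, matching the model's zero-mean convention; the raw 0/1/2 matrix
is what the dataset carries, and centring is preprocessing. With weights of
±10 against latent noise of sd 2 the phenotype is nearly deterministic
given the latents; perfect separation of high-dimensional logistic
baselines is therefore a regular event, not an anomaly (see below).

What the generator does *not* emulate: linkage disequilibrium between SNPs
(the simulated SNPs are independent), continuous phenotypes, covariate
confounding (available separately through `residualize_covariates()`), and
measurement heteroscedasticity within a group. Passing tests on these data
show the estimator recovers the generating process it assumes; they cannot
show robustness to LD or to group homogeneity violations beyond the
misspecification sweep.

Robustness sweeps vary the noise sds over 1–5, the number of nonzero SNP
weights over 2–20, and the number of swapped region-group links.
`swap_region_links()` exchanges one region between two groups per swap, so
sizes are preserved and each swap misspecifies exactly two links. A region
is never returned to a group it previously belonged to — slightly stronger
than only banning its original group, which keeps the misspecification
monotone in the number of swaps.

A root seed plus a counter gives every replicate its own child seed
(`child_seed()`), so any replicate of a study is reproducible in isolation.

## The evaluation framework

Each replicate feeds two comparisons:

1. **Phenotype prediction (AIC).** Logistic regressions of the phenotype
   on five feature sets: the fitted Bartlett scores, the first m principal
   components of the centred+scaled regions, all regions, all regions plus
   SNPs, and all SNPs. All models include an intercept; AIC = 2(k+1) −
   2 logLik. A perfectly separated model is kept at its limiting AIC
   2(k+1) and flagged, because the deviance vanishes in the limit — with
   ±10 phenotype weights this occurs in a substantial fraction of
   replicates, and excluding them would discard exactly the strongest
   replicates.
2. **SNP retrieval (AUC).** Each SNP-to-phenotype path through latent l
   carries the robust p value of $A_{lj}$ and the logistic p value of
   latent l for the phenotype. *SEM max* takes the pairwise maximum then
   the minimum over latents; *SEM Fisher* combines each pair with Fisher's
   method ($\chi^2$ with 4 df — it combines exactly two p values, which
   test *different* hypotheses; that caveat is inherent to the score, not
   corrected here) then the minimum. Baselines are per-SNP (univariate)
   and joint (multivariate) logistic Wald p values. The AUC uses the
   tie-corrected rank statistic, equivalent to sweeping the score
   threshold over [0, 1].

Replicates that fail — a constant genotype column from a tiny MAF draw
(about 2–4% of default replicates), an empty true-effect set, or a
non-converged fit — are excluded from aggregates but counted; more than
20% failures aborts the study.

### Scale conventions worth knowing

With the anchor loading fixed at 1, the fitted latent is expressed in units
of its anchor region. Fitting *centred but unscaled* regions therefore
makes $\hat A$ estimate $b_1 A$ (the true weights times the true anchor
loading) and non-anchor loadings estimate $b/b_1$ — this is the convention
under which parameter recovery and confidence-interval coverage are
measured. The AIC/AUC study instead standardizes regions to unit variance,
the convention for mixed-scale volume data; p values and ranking metrics
are unaffected by that linear rescaling.

## Study sizes used by the tests

The bundled checks run the default configuration at 300 replicates for the
AIC/AUC orderings — the mean AUC gap between the two SEM score combinations
is of the order 0.002, so resolving the ordering at all requires a Monte
Carlo standard error below that — 10 replicates at
n = 5000 for parameter recovery, 20 replicates per cell for the
misspecification sweep, 60 replicates for the heavy-noise comparison, and
200 replicates for coverage of the robust intervals. The heavy-noise
check asks that no SEM method *significantly* beats the SNP-only baselines
(paired one-sided t, α = 0.05): the region data are then nearly
uninformative, and "match or beat" is the defensible reading of a
stochastic ordering between methods whose means sit within a Monte Carlo
standard error of each other. One caveat the checks surface honestly: at
region noise sd 5 the Fisher combination does fall below the SNP-only
baselines, but the max combination retains a small edge — with group sizes
up to 20 regions pooling information, n = 500 keeps the robust SNP-weight
p values informative even when each single region is mostly noise.

## Known limitations

* The fit is truly multivariate and scales with the cube of p+q; it is a
  candidate-SNP method, not a genome-wide one.
* No constraints on the weight magnitudes (ridge-type extensions) are
  provided.
* The grouping of regions is consumed as an input table and trusted; the
  misspecification sweep quantifies the cost of getting it wrong but the
  package does not construct groupings.
* Wald p values from near-separated logistic fits (Hauck–Donner) can be
  close to 1 for the strongest latent-phenotype effects; the SEM-max score
  inherits this conservatism.
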