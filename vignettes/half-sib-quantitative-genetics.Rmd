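---
title: "Quantitative genetics of a half-sib breeding design: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of a half-sib breeding design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibvar)
```

## The problem

A nested full-sib/half-sib (FSHS) breeding design mates each sire to several
dams and assays several daughters per dam. Offspring of one dam are full
sibs; offspring of one sire across dams are paternal half sibs. Because
paternal half sibs share only additive genetic effects (a quarter of them),
while full sibs additionally share maternal and common-environment effects,
the design separates additive genetic variance from the nuisance sources
that inflate naive resemblance between relatives.

`sibvar` implements the complete analysis chain for two female life-history
traits measured in such a design — longevity (days) and early-life mating
frequency (matings accepted in the first six scheduled opportunities) — and
the genetic correlation between them. A negative genetic correlation between
early reproductive effort and lifespan is the signature of a "live fast,
die young" trade-off: families with a genetic propensity to mate heavily
early in life die sooner, so neither trait can evolve independently of the
other.

## Models

### Nested sire/dam mixed model

For trait value $y_{ijk}$ of daughter $k$ of dam $j$ mated to sire $i$:

$$y_{ijk} = \mathbf{x}_{ijk}^\top \beta + s_i + d_{ij} + e_{ijk},$$

with $s_i \sim N(0, V_{sire})$, $d_{ij} \sim N(0, V_{dam})$,
$e_{ijk} \sim N(0, V_{resid})$. The components are estimated by restricted
maximum likelihood (REML), written in-package: the marginal covariance is
$V = V_{sire} Z_s Z_s^\top + V_{dam} Z_d Z_d^\top + V_{resid} I$, and each
likelihood evaluation applies the Woodbury identity so the cost is a
Cholesky factorization of a $q \times q$ matrix ($q$ = sires + dams),
independent of the number of records. The optimizer works on log variance
ratios $\log(V_{sire}/V_{resid}), \log(V_{dam}/V_{resid})$ with the
residual variance and the coefficients profiled out, multi-started from two
points, using box-constrained quasi-Newton steps (`optim(method =
"L-BFGS-B")`, bounds $[-30, 15]$ on the log scale). The lower bound lets a
component reach the boundary smoothly; estimates below $10^{-8} V_P$ are
reported as exact zeros, which is how a dam component of 0 is printed for
longevity-type traits. The log-likelihood normalization follows lme4's
convention (no $|X^\top X|$ term), and the fit agrees with `lme4::lmer` to
at least six significant digits on every dataset we have compared
(`lme4` is used only as a cross-check in the test suite).

Under additive inheritance the observational components map to causal ones
as $\mathrm{cov}(\text{half sibs}) = V_{sire} = V_A/4$ and
$\mathrm{cov}(\text{full sibs}) = V_{sire} + V_{dam} = V_A/2 + V_{Ec}$, so

$$V_A = 4 V_{sire}, \qquad V_P = V_{sire} + V_{dam} + V_{resid}, \qquad
h^2 = V_A / V_P.$$

Note that $V_{dam}$ absorbs both the remaining quarter of $V_A$ and any
common-environment/maternal variance; the design cannot separate those, and
the package does not try.

### Mean-standardized evolvabilities

Heritabilities are ratios to total variance and can be small for traits
with large residual variance even when additive variance is abundant.
Mean-standardized measures avoid this:

$$CV_A = \sqrt{V_A}/\bar{y}, \quad CV_P = \sqrt{V_P}/\bar{y}, \quad
CV_R = \sqrt{V_P - V_A}/\bar{y}, \quad I_A = V_A/\bar{y}^2.$$

$CV_R$ is defined from $V_P - V_A$ (not from the model residual
$V_{resid}$); only this definition satisfies the exact identity
$CV_A^2 + CV_R^2 = CV_P^2$, which the package verifies to machine
precision, and only it reproduces the published residual coefficients for
both traits in the study this package re-implements.

### Tests

Fixed effects are tested with Wald chi-square statistics
$\hat\beta^\top \mathrm{Cov}(\hat\beta)^{-1} \hat\beta$ (df = number of
coefficients), with $\mathrm{Cov}(\hat\beta) = (X^\top V^{-1} X)^{-1}$ at
the REML optimum. Genetic parameters are extracted from *minimal* models
retaining only covariates with Wald $p < 0.05$ (single backward pass,
intercept always kept). Selection for the mating-frequency trait may be run
on the $\log(x+1)$ scale — count residuals are right-skewed — but the
variance components are always extracted from the untransformed fit,
because mean-standardized evolvabilities are not comparable across studies
when computed on a transformed scale.

Random components are tested by likelihood-ratio tests against the model
with that component dropped, statistic $2\Delta\ell$ floored at zero and
referred to $\chi^2_1$. Because the null value lies on the boundary of the
parameter space this reference is conservative (the asymptotic null is the
50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$); the plain $\chi^2_1$
convention is the default to match common practice in this literature, and
`boundary_correction = TRUE` applies the mixture. The conservativeness is
verified by simulation in the test suite.

### Jackknife standard errors

Standard errors for every derived genetic parameter come from the
delete-one-sire-family jackknife: the full REML pipeline (with the selected
fixed effects held fixed) is refitted with each sire family removed, and

$$SE = \sqrt{\tfrac{n-1}{n} \sum_i (\theta_{-i} - \bar\theta_{-})^2},$$

with $n$ the number of sire families. No Tukey pseudovalue correction is
applied to the point estimate: the plain delete-one-group formula is
deterministic and is the standard in this literature. Selection is *not*
repeated inside the jackknife loop; the SEs are conditional on the chosen
minimal model.

### Animal models and the genetic correlation

The animal model places an additive genetic effect on every individual with
covariance $V_A \mathbf{A}$, where $\mathbf{A}$ is the numerator
relationship matrix built from the pedigree by the tabular method
($A_{ii} = 1 + \tfrac12 A_{s(i),d(i)}$,
$A_{ij} = \tfrac12 (A_{j,s(i)} + A_{j,d(i)})$). For the bivariate model the
total covariance is $\mathbf{G} \otimes \mathbf{A} + \mathbf{R} \otimes I$
with 2×2 genetic and residual covariance matrices, and the genetic
correlation is $r_g = \mathrm{cov}_A / \sqrt{V_{A1} V_{A2}}$.

Estimation again is REML written in-package. A single eigendecomposition
$\mathbf{A} = U \Lambda U^\top$ (restricted to phenotyped individuals — the
marginal covariance of the observed records is exactly
$V_A \mathbf{A}_{obs} + V_{resid} I$) rotates both traits into a basis
where the covariance is block-diagonal in 2×2 blocks
$\lambda_i \mathbf{G} + \mathbf{R}$, so each likelihood evaluation is
linear in the number of records. $\mathbf{G}$ and $\mathbf{R}$ are
parameterized by their Cholesky factors, which guarantees every reported
$\mathbf{G}$ is positive semidefinite and keeps $|r_g| \le 1$ by
construction. Optimization is Nelder-Mead from three starts (genetic
correlation started at 0 and ±0.5, variances from the univariate fits).
The SE of $r_g$ is a delta-method transform of the inverse observed
information, computed by central-difference Hessian in the (co)variance
parameterization.

Fixed effects in the bivariate models mirror the per-trait univariate
minimal models. An optional dam random effect
($\mathbf{D} \otimes Z_d Z_d^\top$, `dam_random = TRUE`) is available; it
abandons the eigenbasis shortcut for a dense likelihood and is intended for
single fits. It is off by default, matching the univariate finding that dam
components in this design are at or near zero.

## The synthetic-data generator

No raw data are distributed with the study this package re-implements, so
`simulate_dataset()` generates the breeding design itself: by default 72
sires × 3 dams × 4 assayed daughters, thrice-weekly mating opportunities
(2-2-3 day gaps from age 3 days) until death, and 12% attrition from
escapes/accidental deaths (the published pipeline went from 775 assayed to
613 analysed females). Breeding values follow the infinitesimal model
($a_i = \tfrac12 a_{sire} + \tfrac12 a_{dam} + m_i$,
$m_i \sim N(0, \mathbf{G}/2)$), so half-sib and full-sib breeding-value
covariances are $\mathbf{G}/4$ and $\mathbf{G}/2$ exactly in expectation.

Mating propensity is modelled on a latent liability scale: each opportunity
is accepted with probability $\mathrm{logit}^{-1}$ of the female's latent
propensity (mean $\mathrm{logit}(0.35)$, giving a mean early-life count
near the observed 2.1), making the early-life count an *emergent* trait
with the same measurement process as the real assay. Longevity gains
`beta_lifetime_matings` days per accepted mating (default 0.5), generated
sequentially so opportunity counts and lifespan stay mutually consistent,
plus a linear start-date (batch) effect across 10 batches. Default genetic
parameters are study-like: $V_A = 50$ days², zero dam environmental
variance and residual 46 days² for longevity ($h^2 \approx 0.52$); latent
$h^2 = 0.5$ for propensity; genetic correlation $-0.65$.

What the generator does *not* emulate: age-related decline in acceptance
probability (propensity is constant over life), male-side variation (the
study standardized males from isogenic lines precisely to remove it),
fecundity traits, and any causal direction between mating and lifespan (the
per-mating increment is a phenotypic linkage sufficient for testing
covariate adjustment, not a mechanistic model). Passing parameter-recovery
tests therefore shows the estimators are correct under the stated
generative model, not that the biological assumptions hold in real flies.

Two deliberate harness choices deserve a note. First, the liability →
Bernoulli → count measurement chain attenuates the *realized-count* genetic
correlation below the latent $-0.65$; the bivariate recovery study
therefore uses `simulate_gaussian_traits()`, which emits both traits
directly on the Gaussian scale so the configured $r_g$ is the truth being
recovered. Second, the recovery study sets dam environmental variances to
zero so that the plain animal model is correctly specified — matching the
published dam components of 0 and 0.002; with substantial unmodelled dam
variance the animal model absorbs it into $V_A$ and attenuates $r_g$
(measurably: mean $\hat r_g \approx -0.52$ at a longevity dam variance of
5 days² versus $-0.63$ at zero), which is exactly why the `dam_random`
option exists.

## Numerical choices and problem sizes

* Convergence: `factr = 1e5` for the profiled nested model (relative
  log-likelihood changes near $10^{-11}$), `reltol = 1e-12`/`1e-14` for the
  bivariate Nelder-Mead stages; boundary clipping at $10^{-8} V_P$.
* Degenerate inputs: all-zero covariance matrices are accepted by the
  generator (deterministic output) but rejected by the likelihoods
  (singular $V$); non-PSD $\mathbf{G}$ and cyclic pedigrees are rejected
  with configuration errors; unknown parent ids are treated as unrelated
  founders with a warning.
* Validation sizes: oracle equivalence (dense error-contrast likelihoods,
  balanced-design expected mean squares, brute-force kinship recursion) is
  checked on fixtures of 8-50 records where the dense computations are
  exact and fast; parameter recovery runs 200 replicates (heritability,
  nested REML) and 100 replicates (genetic correlation, bivariate animal
  model) at the design scale of 70 sires × 3 dams × 3 daughters, and 1000
  replicates for the Wald type-I error at 40 sires × 2 × 2. These sizes
  give Monte-Carlo standard errors comfortably inside the recovery
  tolerances (±0.05 on $h^2$, ±0.10 on $r_g$).

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(simulation = sim_config(seed = 42), seed = 42,
                       jackknife = FALSE)
res <- run_pipeline(cfg, quiet = TRUE)
cat(res$table1, sep = "\n")
res$correlations
```

The printed table has one row per trait with `value (SE)` cells for the
variance components, $V_A$, $V_P$, $h^2$ and the evolvabilities, and
likelihood-ratio p-values for the sire and dam components; the
correlations tibble carries $\hat r_g$ with its delta-method SE. With a
simulated input the run manifest also records truth-versus-estimate pairs
for $h^2$ and $r_g$.

## Known limitations

* The Wald tests use the full-model covariance for selection, as is
  conventional; the study being re-implemented does not state which it
  used.
* "Mated at least once" is read as *anywhere in life*;
  `filter_analysis_subset(mated_scope = "early")` gives the stricter
  reading.
* The jackknife SE is conditional on the selected minimal model.
* The bivariate animal model requires complete records on both traits
  (listwise exclusion), which the paired assay design guarantees.
* No generalized (non-Gaussian) mixed models: counts are analysed on the
  Gaussian scale, with the $\log(x+1)$ option for significance testing
  only — matching the analysis being re-implemented, not a claim of
  optimality.
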