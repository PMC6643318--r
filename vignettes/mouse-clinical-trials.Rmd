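---
title: "Statistical models for mouse clinical trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models for mouse clinical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MCTrials)
```

## The design that motivates the models

A mouse clinical trial (MCT) evaluates a drug on a panel of mouse tumor
models — patient-derived xenografts (PDX), cell-line xenografts (CDX) or
syngeneic homografts — with one or more mice per model in each of the
vehicle and treatment arms. Unlike a clinical trial, the same tumor can be
placed in both arms, so each model serves as its own control; unlike a
single-model pharmacology study, efficacy is measured across a population
of tumors. The data are therefore *clustered longitudinal*: tumor-volume
measurements nested in mice nested in models. Tumor volume is measured
with calipers roughly twice a week from treatment initiation (day 0,
volumes typically 100–300 mm³ at enrollment) until the animal is
euthanized, conventionally when the tumor reaches 3000 mm³, so late
measurements are truncated for fast-growing tumors.

MCTrials implements the full analysis chain for such trials: growth-curve
endpoints, response classification, subsampling accuracy, three-level
linear mixed models (LMMs), an additive frailty survival model, and
simulation-based power analysis — together with a synthetic-trial
generator that produces data from exactly the models the estimators
assume, so every stage can be validated against known ground truth.

## Exponential growth and derived endpoints

Subcutaneous tumor growth over trial time scales is well described by
exponential kinetics,

$$TV_d = TV_0\, e^{k d}, \qquad \ln TV_d = \ln TV_0 + k d,$$

fitted by ordinary least squares of log-volume on day
(`fitExponential()`). Zero-volume measurements (complete response) are
excluded from log-scale fits and handled by the categorical layer.

Two interpolation conventions coexist deliberately:

* `volumeAt()` interpolates **log-linearly** between measured days
  (matching exponential kinetics), falling back to the volume scale when a
  flanking volume is 0.
* `timeToMultiple()` — doubling time (used as PFS) and tripling time
  (used as OS) — interpolates **linearly in volume**, because the standard
  doubling-time formula
  $d_1 + (d_2-d_1)(2TV_0 - TV_1)/(TV_2 - TV_1)$ is linear in TV. Mice
  whose tumor never reaches the multiple are censored at their last
  measured day (the literature states no convention; censoring at last
  follow-up is the conservative choice).

Continuous group endpoints (`rtvRatio()`, `tgi()`, `growthRateRatio()`,
`aucRatio()`) compare a model's treatment and vehicle groups. Group RTV is
the arithmetic mean of per-mouse RTVs (the aggregator is configurable; the
mean is what TGI formulas conventionally use). Two identities are worth
knowing and are enforced by the test suite:

* `tgi(..., variant = "rtv")` is exactly `1 - rtvRatio(...)`.
* The AUC ratio is defined on the **log-RTV** scale precisely so that
  under exponential growth the area over $[0,T]$ is $kT^2/2$ and the
  ratio collapses to the growth-rate ratio $k_t/k_c$, independent of the
  evaluation day — whereas both TGI variants are day-dependent. When an
  efficacy metric must be compared across trials with different endpoints
  days, the rate-based metrics are the stable ones.

## Categorical response methods

All four classifiers threshold relative tumor volume (RTV), differing in
thresholds and in how much of the curve they use:

| method | categories | uses | objective response |
|---|---|---|---|
| RECIST-based | CR/PR/SD/PD | RTV at one day | CR+PR |
| 3-cat | OR/SD/PD | RTV at one day | OR |
| mRECIST | CR/PR/SD/PD | best and best-average RTV, day ≥ 10 | CR+PR |
| 5-cat | MCR/CR/PR/SD/PD | min RTV and end-of-study RTV | MCR+CR+PR |

The single-day thresholds are: RECIST-based — CR: RTV = 0, PR ≤ 0.657,
SD ≤ 1.728, PD > 1.728; 3-cat — OR ≤ 0.65, PD ≥ 1.35. The mRECIST numeric
cutoffs are not fixed by a single convention in the MCT literature; this
package adopts the Gao et al. criteria expressed on the RTV scale
(CR: best < 0.05 and best average < 0.60; PR: < 0.50 / < 0.80;
SD: < 1.35 / < 1.30; else PD), exposed as `mrecistThresholds()` so other
conventions can be swapped in. "RTV = 0" is taken literally as
disappearance of measurable tumor mass.

Because mRECIST averages from day 0, a tumor that grows substantially
before disappearing late can be PD under mRECIST yet CR at end of study
under the other methods — the classifiers intentionally disagree on such
curves, and the suite contains discriminating fixtures for every method
pair. A model's response is the majority response of its mice
(`majorityResponse()`), with ties broken toward the more progressive
category (PD > SD > PR/OR > CR > MCR) — a conservative efficacy call; the
tie-break is a documented, configurable design choice rather than a field
convention.

Decisions here that the sources left open: the evaluation day for the
single-day methods defaults to the last *common* measured day; the 5-cat
"during the study period" window is taken as measured days after day 0
(day 0 has RTV = 1 and could only matter for PR); the admissible initial
volume range (50–300 mm³) is an optional warning filter, not a hard
failure.

## Subsampling: how many mice per model?

`categoricalAccuracy()` quantifies the accuracy/mouse-number relationship:
for each model, draw n mice *without replacement* (the procedure
resamples mice from a fixed cohort; with-replacement is available as an
option), take their majority response, and compare with the full-group
majority; 1000 replications by default. Accuracy is summarized per
actual-majority category plus the unweighted average across categories.
`continuousError()` does the analogue for continuous endpoints, recording
percent error (|sub − full|/full × 100) or absolute error against the
all-mice value, over models with at least 10 mice per relevant arm (the
conventional inclusion rule; the threshold is an argument). Subsampled
majorities use the same tie-break as the full-group call, so accuracy at
n = group size is exactly 1.

## Three-level linear mixed models

Viewing the MCT as a clustered longitudinal study, `fitLMM()` fits, by
REML (via lme4),

$$\log TV_{tij} = \beta_0 + \beta_1 Day_t + \beta_2 Day_t\,Treatment_{ij}
 + u_{0j} + u_{1j} Day_t + u_{0i|j} + u_{1i|j} Day_t + \varepsilon_{tij}$$

for mouse $i$ in model $j$, optionally with model-level covariates
(cancer type, gene expression) entering as additional day-interactions —
covariates modify *growth rates*, which is how categorical and genomic
differences act under exponential kinetics. Random structure: intercept
and day-slope with an unstructured 2×2 covariance at the model level and
at the mouse-within-model level, independent across levels, iid
residuals. This is the natural default when nothing is known about the
correlation of baseline and growth; both covariances are reported.
Unbalanced series and dropout need no special handling — the likelihood
uses whatever measurements exist.

Inference is by large-sample Wald z-tests on the fixed effects. No
Satterthwaite/Kenward–Roger correction is applied; at the panel sizes
this package targets (≥ 20 models, ≥ 100 mice) the z approximation is
adequate, with a mildly optimistic size (the suite verifies the
rejection rate under the null stays within [0.03, 0.07] at 20 models ×
3:3). For very small panels a df-corrected test would be preferable;
that is a documented limitation. Zero-volume observations are dropped
from log-scale fitting with a count kept on the fit object. On
non-convergence the optimizer restarts deterministically (nloptwrap,
bobyqa, Nelder–Mead).

### Biomarker scanning

`biomarkerScan()` fits, per gene,

$$\log TV = \beta_0 + \beta_1 Day + \beta_2 Day\,Gene +
  \beta_3 Day\,Treatment + \beta_4 Day\,Gene\,Treatment + \ldots$$

with the gene standardized across models (raw scale available), and
ranks genes by the Wald p-value of $\beta_4$ — the *predictive* effect,
separated from the *prognostic* effect $\beta_2$. Benjamini–Hochberg
adjusted p-values are appended; constant genes are skipped and flagged.
The naive comparator (`naiveCorrelationScan()`) correlates expression
with a single-day TGI readout and is substantially more false-positive
prone: a gene that merely tracks growth-rate or measurement noise at the
evaluation day can out-correlate the true modifier. The contrast grows
with the number of genes scanned, since the naive scan's best null
correlation grows like $\sqrt{2\log k}$ while the LMM scan pools the
whole longitudinal signal.

Computationally the scan reuses the parsed model structure across genes,
warm-starts each gene at the previous optimum and stops the optimizer at
tolerance 1e-4 (z statistics stable to ~0.02); a 150-gene scan on a
20-model trial runs in a few seconds.

`interpretGeneEffects()` turns one fit into a prognostic-vs-predictive
report with mean growth curves at low/high expression; opposite-signed
$\beta_2 < 0, \beta_4 > 0$ is the clinically confusing case — higher
expression means slower untreated growth *and* smaller treatment benefit
— which the generator can plant for demonstration.

## Additive frailty survival model

Event times (tumor doubling for PFS, tripling for OS) derived by
`deriveSurvival()` are clustered: mice of the same model share growth
biology and drug response. `fitFrailty()` fits

$$h_{ij}(t) = h_0(t)\,\exp\!\big(u_i + (w + v_i) T_{ij} + \beta^T X_i\big),
\qquad (u_i, v_i) \sim N_2\!\left(0, \begin{pmatrix} \sigma^2 &
\rho\sigma\tau \\ \rho\sigma\tau & \tau^2 \end{pmatrix}\right)$$

with Weibull baseline $h_0(t) = (a/b)(t/b)^{a-1}$ (this shape/scale
parameterization is stated because conventions differ). $u_i$ captures a
model's characteristic hazard (it correlates with the vehicle growth
rate, `frailtyGrowthCorrelation()`); $v_i$ captures drug-response
heterogeneity. Removing both reduces the model to proportional hazards —
and that is the point: ignoring real heterogeneity, the marginal Cox
estimate (`fitCox()`, Breslow ties) is *attenuated toward HR 1*, so the
frailty model recovers a stronger, less biased treatment effect. The
suite demonstrates both the reduction (σ² = τ² = 0 data) and the
attenuation (clustered data).

Numerics, all of which matter for reliability:

* The frailty pair is integrated per cluster by **adaptive Gauss–Hermite
  quadrature**: a damped Newton iteration, vectorized across clusters,
  finds each cluster's posterior mode; nodes are centered there and
  scaled by the local curvature. Nine nodes per dimension leave the
  log-likelihood stable to < 1e-4 against 15 nodes on realistic cluster
  sizes (3–10 mice).
* The frailty covariance is parameterized by its **log-Cholesky factor**,
  so estimates are non-negative definite by construction; boundary
  estimates (a variance hitting 0) are flagged on the fit rather than
  silently returned.
* Wald tests of σ² > 0 and τ² > 0 use delta-method standard errors from
  the positivity-respecting scale and one-sided p-values; at the boundary
  the test statistic is meaningless and p is reported as 1. The exact
  construction of a boundary-corrected variance test is an open choice;
  this one is documented, not claimed canonical.
* ρ is estimated by default; `rhoFixed = 0` stabilizes small panels and
  matches generators with independent frailties. `tau2Zero = TRUE` gives
  the classical shared-frailty special case.
* Starting values come from a Weibull AFT fit ignoring clustering;
  per-cluster frailty estimates are posterior modes (empirical Bayes).

## Simulation-based power

`powerLMM()` and `powerFrailty()` estimate power for balanced n:n designs
by simulating trials from the generator, fitting the corresponding model
and counting two-sided Wald rejections of the treatment term at α = 0.05.
Failed fits count as non-rejections (conservative) and are reported, with
a flag when they exceed 5% of a cell. The headline design fact these
reproduce: at a fixed effect, power depends mostly on the *total* number
of mice, not on how they are split between many models with few mice or
fewer models with more mice — so panel composition can be chosen on
biological grounds (tumor diversity) without large power penalties.

## The synthetic-trial generator

`simulateMCT()` draws data from exactly the three-level LMM above:
model- and mouse-level random effects from their configured bivariate
normals, iid log-scale residuals, volumes exponentiated, measurements
truncated after a volume exceeds the dropout threshold (mirroring
euthanasia; the mechanism is missing-at-random given the latent
trajectory, so LMM fits on truncated data remain valid — which the
recovery tests exercise). `simulateSurvival()` draws clustered event
times from the additive frailty model by inverse transform, with
administrative censoring. `simulateExpression()` embeds the per-model
covariate that drove the slopes as one causal gene among iid
standard-normal noise genes.

The default "cisplatin-like" preset was fixed once, from published
anchors and standard xenograft practice, and is used unchanged by the
validation suite:

| parameter | default | why |
|---|---|---|
| schedule | days 0,3,6,…,21 | 21-day trial, twice-weekly measurement, 8 points |
| β₁ | 0.06 /day | vehicle growth rate of the order reported for PDX panels (doubling ≈ 11.5 d) |
| β₂ | −0.012 /day | a 20% growth-rate reduction, a moderate effect |
| initial volume | log-uniform 100–300 mm³ | dosing-start convention |
| residual SD | 0.25 (log scale) | ≈ 25% caliper measurement CV |
| model-level slope SD | 0.02 /day | growth-rate heterogeneity across models |
| mouse-level slope SD | 0.012 /day | within-model heterogeneity |
| mouse intercept SD | 0.1 | engraftment variability |
| dropout threshold | 3000 mm³ | euthanasia volume |
| gene effects | −0.015 (growth), +0.015 (treatment) | the magnitude scale of reported prognostic/predictive expression coefficients, opposite-signed |
| survival preset | Weibull shape 1.5, scale 12 d; σ² = 0.5, τ² = 0.2, ρ = 0; horizon 60 d | vehicle tripling times ≈ 10 days; strong but realistic clustering |

What the generator deliberately does *not* emulate: bimodal/polarized
responses of immunotherapy on syngeneic panels, measurement-day jitter
between mice, informative (toxicity-driven) dropout, and non-exponential
(Gompertz/logistic) growth near the volume ceiling. Passing tests
therefore validate the estimators under the stated models, not the
models themselves against real tumors.

## Problem sizes used by the validation suite

The acceptance-level tests run at desk scale, chosen as the smallest
sizes at which each property is statistically decidable: type-I error at
1000 simulated trials of 20 models × 3:3; coverage of the growth and
treatment effects at 200 trials; frailty recovery/attenuation at 100
trials of 100 clusters; the biomarker contrast at 100 trials of a
150-gene scan; power structure at 500 replicates per design cell. The
same machinery scales to publication-grade settings by raising the
counts. One caveat is inherent to scale: the naive-vs-LMM ranking
contrast decouples fully only on genome-sized panels (the best null
Spearman correlation grows like $\sqrt{2\log k}$ while the LMM scan's
null z threshold grows much more slowly), so on a 150-gene panel the
naive scan is out-ranked in a substantial fraction — but not the
majority — of replicates, and the corresponding acceptance-level
assertion documents that gap rather than papering over it.

## Known limitations

* Wald z inference throughout; no small-sample df corrections.
* The frailty model assumes a Weibull baseline; no spline baselines,
  time-varying covariates or competing risks.
* Only balanced n:n designs in the power engines; asymmetric designs are
  a straightforward extension of the generator.
* Group PFS in the subsampling module summarizes censored doubling times
  at face value (median of observed times); with heavy censoring a
  Kaplan–Meier median would be preferable.
```
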