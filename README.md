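# MCTrials

Design and analysis of **mouse clinical trials** (MCTs): preclinical
oncology studies in which a panel of mouse tumor models (PDX, CDX or
syngeneic), each with one or more mice in the vehicle and treatment arms,
is used to evaluate drug efficacy across a tumor population. The data are
clustered longitudinal tumor-volume series — measurements nested in mice
nested in models — and the package provides the statistical machinery that
structure calls for, end to end.

## What it implements

**Growth and endpoints.** Exponential kinetics
`TV_d = TV_0 e^{kd}` fitted on the log scale; doubling time (PFS) and
tripling time (OS) by the standard linear interpolation
`d1 + (d2−d1)(2·TV0 − TV1)/(TV2 − TV1)`; the four categorical response
methods used in MCTs (RECIST-based, 3-category, mRECIST with best/best-
average response, 5-category), majority response per model and objective
response rates; and the five continuous endpoints (RTV ratio, TGI in both
its `1 − RTV_t/RTV_c` and `1 − ΔT/ΔC` forms, growth-rate ratio, AUC ratio
on the log-RTV scale, which reduces exactly to the growth-rate ratio
under exponential growth).

**Subsampling accuracy.** How measurement accuracy of categorical calls
and continuous endpoints grows with the number of mice per model, by
repeated subsampling against the all-mice value.

**Clustered longitudinal modeling.** Three-level REML linear mixed
models for log tumor volume,

    log TV_tij = β0 + β1·Day + β2·Day·Treatment (+ Day × covariates)
                 + u0j + u1j·Day + u0i|j + u1i|j·Day + ε,

with per-gene biomarker scanning (the Day×Gene×Treatment coefficient
separates predictive from prognostic effects) and a naive
Spearman-vs-TGI comparator.

**Clustered survival.** An additive frailty model with Weibull baseline,

    h_ij(t) = h0(t) · exp(u_i + (w + v_i)·T_ij + βᵀX_i),
    (u_i, v_i) ~ N2(0; σ², τ², ρ),

fitted by maximum marginal likelihood with adaptive Gauss–Hermite
quadrature — alongside the naive Cox fit, whose hazard ratio is
attenuated toward 1 when model-level heterogeneity is real.

**Power.** Simulation-based power for balanced n:n designs under both
the LMM and the frailty analysis.

**Synthetic trials.** A generator drawing from exactly these models
(with dropout at 3000 mm³, log-uniform 100–300 mm³ initial volumes,
planted biomarker effects, known latent truth) so every estimator is
validated by parameter recovery.

## Worked example

```r
library(MCTrials)

sim <- simulateMCT(mctSimConfig(nModels = 20, micePerArm = 3,
                                beta2 = -0.02), seed = 1)
sim$dataset
#> MCTDataset
#>   20 models, 120 mice, 960 measurements
#>   arms: treatment=60, vehicle=60
#>   days 0-21

table(responseCalls(sim$dataset, "mrecist")$category)
#> PD PR SD
#> 33  1 26

modelEndpoints(sim$dataset, "M001")
#>   model_id eval_day n_treated n_vehicle pfs_median rtv_ratio   tgi_rtv
#> 1     M001       21         3         3   8.286945 0.5865207 0.4134793
#>   tgi_delta growth_rate_ratio auc_ratio
#> 1 0.3601254         0.7505393 0.7284899

fitLMM(sim$dataset)
#> MCTLmmFit (REML): 960 obs, 120 mice, 20 models
#>           term estimate      se    z       p
#>    (Intercept)  5.18000 0.06850 75.6 0.0e+00
#>            Day  0.06110 0.00547 11.2 5.4e-29
#>  Day:Treatment -0.02176 0.00259 -8.4 4.3e-17
#> model-level SDs (icept, Day): 0.2966, 0.02277 | mouse-level: 0.07698, 0.009322 | resid: 0.2657

ff <- fitFrailty(deriveSurvival(sim$dataset, "tripling"), rhoFixed = 0)
ff
#> MCTFrailtyFit: 20 clusters, 120 records, 69 events (GH 9 nodes/dim)
#>   w = -1.146 (SE 0.264), HR = 0.318 (95% CI 0.190-0.533)
#>   sigma2 = 1.217, tau2 = 0.000, rho = 0.000
#>   Weibull baseline: shape 3.359, scale 18.781; logLik -254.41 [boundary: tau2]
```

Reading the output: the generating treatment effect `β2 = −0.02/day` is
recovered as −0.0218 (SE 0.0026) — the drug cuts the growth rate by about
a third (`β2/β1 ≈ −0.36`). On the tripling-time (OS) scale the treatment
hazard ratio is 0.32; the `sigma2` estimate says models differ strongly in
baseline hazard (their growth rates vary), while `tau2` sits at the 0
boundary — with 20 models there is no evidence of additional
drug-response heterogeneity beyond the planted growth spread.

The command-line wrapper exposes the same workflow
(`simulate`, `classify`, `endpoints`, `accuracy`, `fit-lmm`, `scan`,
`survival`, `power`):

```sh
Rscript inst/cli/mct.R simulate --models 20 --mice 3 --seed 1 --out trial/
Rscript inst/cli/mct.R classify --volumes trial/volumes.csv --method recist --out calls/
```

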