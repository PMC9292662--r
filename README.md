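# DDIsignal

Signal detection for drug-drug interaction (DDI) adverse events in
spontaneous reporting system (SRS) data, for pharmacovigilance analysts and
methods researchers. The package implements a propensity score-adjusted
three-component mixture model (PS-3CMM) that turns observed and expected
report frequencies into a local false discovery rate per drug-drug-ADE
combination, alongside the Ω shrinkage statistic and proportional reporting
ratios (PRR) as comparators, a report-level simulator, and ROC/AUC
evaluation.

## The model

For a drug pair and an adverse event (ADE), reports cross-classify into
eight cells *a…h* with reporting rates r₀₀ = a/(a+b), r₁₀ = c/(c+d),
r₀₁ = e/(e+f), r₁₁ = g/(g+h); the observed frequency is N = g.

**Expected frequency (PS-adjusted).** Per combination a logistic outcome
model

  logit P(ADE) = β₀ + β₁D₁ + β₂D₂ + β₃D₁D₂ + β₄PS₁ + β₅PS₂

is fitted, with PSⱼ drug j's propensity score (probability of exposure
given the report's comedication profile, a logistic model on principal
components of the comedication indicator matrix). Dropping the interaction
term gives the no-DDI expectation over the g+h doubly-exposed reports:

  E = Σᵢ invlogit(β̂₀ + β̂₁ + β̂₂ + β̂₄PS₁ᵢ + β̂₅PS₂ᵢ).

**Mixture / adjusted-FDR.** Across combinations the latent relative
reporting ratio λ follows a point mass at 0, a background gamma with
shape = rate = α₂ (mean 1), and a signal gamma with shape α₃ > rate β₃
(mean > 1), mass ratio ρ = P₃/P₂; N is Poisson(λE). The parameters are
estimated by conditional (N > 0) maximum likelihood with `nlminb`, and

  adjusted-FDR(k, E) = F(k; α₂, α₂, E) / [F(k; α₂, α₂, E) + ρ·F(k; α₃, β₃, E)]

is the posterior probability the combination is background (F the negative
binomial pmf). Combinations are ranked by −log₁₀(adjusted-FDR).

**Comparators.** Ω = log₂((N+α)/(E+α)) against an additive-odds baseline
with single-drug odds clamped at the background, with Ω₀₂₅ the log₂ lower
95% gamma-posterior credibility bound; and PRR with 95% CI lower bounds and
the pair-as-new-drug interaction rule.

## Worked example

```r
library(DDIsignal)

ct <- ContingencyTable(a = 100, b = 900, c = 20, d = 80,
                       e = 30, f = 70, g = 10, h = 10,
                       drug1 = "drugA", drug2 = "drugB", ade = "delirium")
omegaScore(ct)
#> OmegaResult: N = 10, E = 7.241, omega = 0.4399, omega025 = -0.5903 (alpha = 0.5)
prrScore(ct)
#> PrrResult
#>         drug1  drug2   pair
#> PRR    2.1154 3.0556 4.0000
#> PRR025 1.4915 2.2541 2.5172
#> interaction signal: TRUE
```

Ten of the twenty doubly-exposed reports mention the ADE against an
additive-baseline expectation of 7.24, so Ω is positive but the credibility
bound Ω₀₂₅ stays below 0 — too few reports to call an Ω signal. The PRR
route, which applies no shrinkage, already flags the pair (its lower bound
2.52 exceeds both single-drug bounds).

A small end-to-end benchmark (simulate → fit → mixture → AUC):

```r
cfg <- simConfig("a", nReports = 20000, nSignals = 100, nNegatives = 100,
                 seed = 7)
bench <- runBenchmark(cfg)
round(bench$auc, 3)
#> ps3cmm  omega
#>  0.738  0.773
bench$mixture
#> MixtureFit on 150 combinations, logLik -274.841 (start 'tight', code 0)
#> MixtureParams: alpha2 = 1.562, alpha3 = 1.603e+05, beta3 = 2.624e+04, rho = 0.03778
#>   background: mean 1, SD 0.800; signal: mean 6.108, SD 0.015
```

At this deliberately tiny size both methods are noisy and the
signal-component shape is barely identified; the methods separate at the
benchmark scale below (see the vignette for why, and for what the simulator
does and does not emulate).

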