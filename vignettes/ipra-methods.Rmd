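---
title: "Methods: two-dimensional probabilistic risk assessment of nanosilica in food"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-dimensional probabilistic risk assessment of nanosilica in food}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipra)
```

## The problem

Synthetic amorphous silica (the food additive E551) is used as an anti-caking
agent in powdered foods, and a fraction of it occurs in nano-form. A
deterministic risk screen compares a single worst-case exposure with a single
animal effect level. This package instead characterizes the risk
probabilistically, separating *variability* (true differences between people
in how much they eat and how sensitive they are) from *uncertainty* (what we
do not know: sampling error, the nano fraction, dose-response model choice,
extrapolation factors). The result is a distribution of individual margins of
exposure (IMoE) with explicit uncertainty bounds, plus a decomposition of
which uncertainty sources dominate.

## The model

### Exposure side

Person-day exposure is

$$\mathrm{IDEXP} = \sum_k \frac{\mathrm{amount}_k}{\mathrm{bw}}
  \times F \times C_k,$$

where $C_k$ is the total-silica concentration of food $k$ (from measured
basic powder products, linked to consumed foods through composition
fractions), and $F$ is the nanofraction — the uncertain proportion of total
silica in nano-form. Concentrations enter in mg/g, amounts in g, body weight
in kg; the canonical internal unit of exposure is µg/kg BW/day, converted to
mg/kg BW/day only at the risk-characterization boundary.

Because the endpoint is chronic, person-day intakes must be converted to
long-term usual intakes. `fit_usual_intake()` implements a two-part
logistic-normal-normal model: a logistic random-intercept model for the
probability that a person consumes on a given day, and a lognormal
random-intercept model for the amount on consumption days,

$$\mathrm{logit}\,P(\text{positive day}) = \alpha + u_1, \qquad
  \ln(\text{amount}) = \beta + u_2 + \varepsilon,$$

with $(u_1, u_2)$ bivariate normal person effects and
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$. A person's usual intake is
$P(\text{positive} \mid u_1)\, e^{\beta + u_2 + \sigma_\varepsilon^2/2}$.
This is the package's own implementation of the two-part shrinkage approach
used in usual-intake software, not a replication of any external program:
the frequency likelihood is integrated by fixed-order Gauss–Hermite
quadrature (21 nodes), the amount part has a closed-form marginal normal
likelihood per person, and the amount transform is the plain log (no Box–Cox
family, no covariates). With two recall days per person the correlation
between $u_1$ and $u_2$ is weakly identified, so the default fixes it at 0
("LNN0"); `correlation = "estimate"` fits it by a joint quadrature
likelihood. When every person-day is positive the frequency part is fixed at
1 and the amount part reduces to a one-way random-effects decomposition.

The uncertain nanofraction is logistic-normal on (0, 1), pinned by its median
(0.5) and 95th percentile (0.8); this leaves roughly 2% probability above
0.85 and below 0.15. Sampling uncertainty in the survey is a person-level
bootstrap; in the concentrations, a within-basic-product bootstrap of the
measured products (1–5 per basic product, so this understates that
uncertainty — a known limitation).

### Hazard side

The animal endpoint is quantal: positive liver-fibrosis slides out of 10 per
rat, Binomial(10, $p(d)$). Seven candidate models for $p(d)$ are fitted by
maximum likelihood — logistic, probit, log-logistic, log-probit, weibull,
gamma, and linearized two-stage — and the benchmark dose (BMD) is the ED50:
the dose at $p = 0.5$ for logistic/probit, and midway between the background
$p_0$ and 1 (additional risk 50%) for the five models with an explicit
background parameter. The AIC-best model supplies the nominal BMD; model and
sampling uncertainty are carried by a parametric bootstrap, 100 replicate
datasets per model refitted and the 700 ED50s pooled into one set that the
outer loop resamples uniformly.

The individual benchmark dose divides out three extrapolation factors,

$$\mathrm{IBMD} = \frac{\mathrm{BMD}_{\text{animal}}}
  {EF_{\text{chronic}} \times EF_{\text{inter}} \times IEF_{\text{intra}}},$$

with:

* $EF_{\text{chronic}}$ (subchronic-to-chronic): nominal 1.475; uncertainty
  lognormal with *arithmetic* mean 1.80 and sd 1.52. These published summary
  values are mutually inconsistent (the lognormal's implied median is 1.375,
  not 1.475); the package reproduces both as given rather than resolving the
  discrepancy.
* $EF_{\text{inter}}$ (rat-to-human): nominal $(70/0.25)^{0.25} \approx 4$
  by caloric-demand allometry; uncertainty lognormal with geometric mean 4
  and GSD 1.48, derived from an assumed 99th percentile of 10.
* $IEF_{\text{intra}}$ (between-human sensitivity): lognormal with geometric
  mean 1 and GSD 1.91. The GSD itself is uncertain through
  $\sigma^2 = \sigma_0^2\,\nu/\chi^2_\nu$; $(\sigma_0, \nu)$ are solved
  jointly so that the 95% uncertainty interval of the 95th-percentile
  sensitivity ratio $e^{z_{0.95}\sigma}$ is exactly [2, 10]
  ($\nu \approx 6.25$). The chi-square is taken to act on $\sigma^2$; this
  convention reproduces the nominal GSD of 1.91.

### Risk characterization

`run_ipra()` nests two Monte Carlo loops. Each outer (uncertainty) iteration
draws one state of knowledge — bootstrapped survey and concentrations, a
nanofraction, a pooled-set BMD, and the three factor draws — then the inner
(variability) loop simulates a fresh usual-intake population sample IEXP and
an IBMD sample, combined independently as $\mathrm{IMoE} = \mathrm{IBMD} /
\mathrm{IEXP}$; an individual is at risk when IMoE < 1. Each iteration
records the IMoE percentiles (p0.1 through p99.9) and the fraction at risk;
across iterations these yield one-sided uncertainty whiskers for the IMoE
bars and statements like "with 95% confidence, at least 99% of the
population has IMoE above 1" (`prob_population_safe()`).

Dose metrics: exposure and hazard can both be expressed per unit mass or as
particle numbers, assuming monodisperse spheres at the median diameter
(default 100 nm) and amorphous-silica density 2.2 g/cm³. The source of that
particle-count formula is a spherical reconstruction chosen here — the
diameter and density stay configurable. Because both sides of the IMoE ratio
are scaled by the same constant, a chronic assessment is exactly
dose-metric-invariant; the engine exploits this by fitting the usual-intake
model once on the mass scale and applying the conversion as a single
multiplicative constant at the boundary, which also makes the invariance
hold to machine precision.

### Uncertainty contributions

`run_factorial()` runs the engine over the full $2^7$ factorial of on/off
patterns of the seven uncertainty sources, each cell with matched sub-stream
seeds so a source receives identical draws in every cell that includes it.
The variance of $\log_{10}$ of the target percentile across repetitions in
each cell is decomposed by a least-squares additive model; the intercept
estimates pure Monte Carlo noise and the main effects the variance each
source adds. Variance is taken on the log scale because IMoE spans orders of
magnitude (the summary scale is not dictated by the method's description;
this is a recorded package choice). Negative fitted effects, possible from
Monte Carlo noise, are clipped to zero for the contribution bars but
reported raw.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| nanofraction p50, p95 | 0.5, 0.8 | – | median measurement-based; p95 allows values up to 1 after digestion |
| particle diameter | 100 | nm | median of measured consumer-product distributions |
| particle density | 2.2 | g/cm³ | amorphous silica |
| body weights | 70 / 0.25 | kg | standard human / rat reference weights |
| EF_chronic nominal, mean, sd | 1.475, 1.80, 1.52 | – | published NOAEL-ratio summaries |
| EF_inter p99 | 10 | – | conventional upper plausibility bound |
| intraspecies bounds | 2–10 | – | assumed range of the p95 sensitivity ratio |
| outer iterations | 500 | – | uncertainty loop |
| inner sample | 100 000 | – | variability loop; percentiles to p0.1 |
| bootstrap reps/model | 100 | – | 7 × 100 = 700 pooled BMDs |
| GH quadrature order | 21 | nodes | frequency-part integration |

## The synthetic-data generators

The original consumption survey (a two-day 24-h-recall study of 3819
respondents) and the rat-level fibrosis counts are not public, so the
package ships seeded generators with the statistical structure the analysis
assumes:

* `generate_survey()` draws body weights, correlated person effects for
  consumption frequency (logit scale, sd 1) and amount (log scale), and
  Bernoulli-lognormal person-day-food records. The shared person effect
  (frequency–amount correlation 0.5 by default) makes the usual-intake fit
  non-trivial. It does **not** emulate survey weights, demographics, food
  classification systems, or realistic food-specific amount distributions —
  those are free parameters, not calibrated claims.
* `generate_dose_response()` reproduces the emulated study design — dose
  groups 0, 810, 819 mg/kg BW/day, 5 rats per group, 10 slides per rat —
  with a logistic simulation truth (background 2%, ED50 1160 mg/kg BW/day)
  and an optional beta-binomial overdispersion switch. The rat-level counts
  behind the published fits are unavailable, so published BMD values cannot
  be (and are not) reproduction targets.
* The measured-concentration table and the food-link table are packaged as
  checksummed CSV fixtures (25 measured products, 13 basic products).
  Nanosilica values below the 0.1 mg/g quantification bound are stored
  left-censored and are not used by the pipeline — the nanofraction model
  replaces direct nanosilica measurements.

Consequently, green tests demonstrate that the machinery is correct under
the assumed structure (recovery of known simulation truths, exact
invariances, calibrated error rates), not that any real population is safe.

## Numerical choices

* Quantal fits maximize the exact binomial likelihood on per-group totals;
  slopes are kept positive by log transforms, and the power/slope parameters
  of the log-dose models (and the gamma shape) are constrained ≥ 1, the
  convention of standard benchmark-dose software. On a 3-group design with
  two nearly identical treatment doses the unconstrained log-dose models are
  weakly identified (the slope collapses and the ED50 diverges); the
  constraint restores a well-defined ED50.
* Optimisation is Nelder-Mead with a BFGS polish; the binomial-coefficient
  constant is kept out of the objective so relative stopping tolerances
  behave consistently across datasets. Flat likelihood directions (a
  background parameter drifting to its boundary when the control group has
  no responders) are handled by restart-until-stationary, and boundary
  solutions trigger perturbed restarts before a refit is declared
  non-converged. Genuinely flat or non-increasing resampled datasets have no
  ED50 and are dropped and counted, never retried with new data.
* Quantiles use linear interpolation of order statistics (R type 7,
  position $p(n-1)+1$); exceedance curves use strict inequality.
* The amount-part intercept is optimised after centring log amounts, making
  the fit exactly shift-equivariant, hence the engine exactly
  scale-equivariant under concentration scaling.
* Every stochastic stage of every outer iteration draws from a named
  sub-stream derived from the master seed, so results are bitwise
  reproducible and toggling one uncertainty source never perturbs another —
  the property the factorial decomposition relies on.
* Degenerate inputs: a nanofraction fit with $\sigma < 10^{-8}$ is rejected;
  `solve_intraspecies(lower == upper)` returns the closed-form
  infinite-degrees-of-freedom limit with `nu` capped at 200 and flagged;
  all-zero or flat dose-response data raise an ED50-undefined error.

## Problem sizes in the shipped tests

The test-suite and acceptance computations are sized for a single CPU: the
engine properties run at 20 outer iterations × 10⁴ inner samples on
150-person synthetic surveys; statistical calibrations use 200 simulated
studies (bootstrap coverage, at 10 replicates per model), 1000 simulations
(goodness-of-fit type-I error), and 2000 persons (usual-intake recovery);
the factorial tests run 10 repetitions per cell at an inner sample of 10³.
The full published-scale configuration (500 outer iterations, 100 000 inner,
50+ repetitions per factorial cell) is the package default for real runs.

## Known limitations

* The concentration bootstrap understates uncertainty with 1–5 measurements
  per basic product; worst-case product-linking assumptions are inherited
  from the fixture and not themselves given uncertainty distributions.
* The engine pairs IEXP and IBMD draws independently: no exposure–sensitivity
  correlation is modelled.
* Acute (person-day-level) risk is out of scope; only the chronic usual-intake
  route is implemented, as is no surface-area dose metric.
* The additive variance decomposition reports main effects only; interaction
  contributions and Sobol-type indices are out of scope.
* Nothing here is an authoritative statement about real dietary risk: inputs
  are synthetic stand-ins wherever the original data are not public.
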