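---
title: "Methods: lifetime space-radiation cancer risk projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime space-radiation cancer risk projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerisk)
```

# The risk model

`spacerisk` projects the lifetime **risk of exposure-induced cancer (REIC)**
and **death (REID)** for a population exposed to charged-particle space
radiation. The model is a *relative-risk (RR) transfer*: the
radiation-attributed cancer rate of a tissue is proportional to that
population's background rate, with the proportionality given by excess
relative risk (ERR) coefficients fitted to the Life Span Study (LSS) of
atomic-bomb survivors, and with the radiation quality of the mixed
galactic-cosmic-ray (GCR) field absorbed into a gamma-equivalent dose.

## Instantaneous rates

For tissue $T$, sex $s$, exposure age $a_E$, attained age $a$ and
gamma-equivalent dose $H_T$ (Gy):

$$\lambda_{IT}(a_E, a, H_T) = \mathrm{ERR}_T(a_E, a)\,\lambda_{0IT}(a)\,H_T,
\qquad
\lambda_{MT} = \frac{\lambda_{0MT}(a)}{\lambda_{0IT}(a)}\,\lambda_{IT},$$

where $\lambda_{0IT}, \lambda_{0MT}$ are the background incidence and
mortality rates. Solid cancers use

$$\mathrm{ERR}(D, a, a_E) = \rho_s D\,(a/70)^{\eta}\,e^{\gamma(a_E-30)},$$

and leukemia (excluding CLL) replaces the age-at-exposure modifier with a
time-since-exposure factor, by default the power law
$((a-a_E)/40)^{\upsilon}$ with $\upsilon = -0.81$. The registry
(`err_registry()`) carries the LSS coefficients per tissue and sex with
their 95% intervals; unreported modifiers are zero. Two readings of the
leukemia latency factor circulate — a power law and an exponential
$e^{\upsilon(a-a_E)/40}$ — and both are implemented
(`time_form = "power"` is the default, matching the tabulated "power
−0.81" description). Minimum latencies are hard gates: 5 y for solid
cancers and 2 y for leukemia (a 1-y leukemia latency also appears in the
source literature; 2 y is the default here and both are configurable).
Thyroid is not in the LSS registry used and carries BEIR-VII-style
configurable defaults; the remainder ("other") grouping uses its LSS row.
Uterine cancer is excluded (negligible estimated radiogenic risk).

## The lifetime integral

$$\mathrm{REIC} = \sum_{j=1}^{N_m}\int_{a_{Ej}}^{100}
\lambda_{Ij}(a_{Ej}, t)\, S_0(t)\,
\exp\Big[-\sum_k \int_{a_{Ek}}^{t} \lambda_{Mk}(a_{Ek}, z)\,dz\Big]\,dt,$$

with $S_0$ the background survival function and the inner exponential the
probability of not having already died of a *radiation-induced* cancer
(competing risk across all exposure events and tissues). REID is identical
with $\lambda_M$ in the outer integrand. Integrals terminate at age 100.

**Discretisation.** Ages are integers 0..100; all rates are piecewise
constant on $[a, a+1)$ and $S_0(a) = \exp(-\sum_{k<a} h(k))$
(exponential-within-year). The outer integral is an annual left-Riemann
sum and the inner one a cumulative sum over completed years. These
conventions are exact for piecewise-constant inputs, which lets the test
suite compare the engine against a brute-force enumeration at $10^{-10}$
relative tolerance rather than against an approximation. The printed form
of the inner integral's lower bound is ambiguous between the exposure age
of event $k$ and of event $j$; we accumulate each event's mortality from
its own exposure age, which is numerically identical to accumulating from
birth because each event's integrand vanishes inside its latency window.

Per-tissue REIC/REID use the single-tissue $\lambda$ in the outer
integrand while the inner competing-mortality sum always spans all
tissues; totals are therefore exact sums over tissues.

## Radiation quality and non-targeted effects

Ion effectiveness relative to gamma rays is
$$R_{QF} = \frac{1-P(Z,E)}{\mathrm{DDREF}}
 + \frac{6.24\,(\Sigma_0/\alpha_\gamma)\,P(Z,E)}{L},
\qquad
P = \big[1 - e^{-Z^{*2}/(\kappa\beta^2)}\big]^m\big[1 - e^{-E/0.2}\big],$$
with $L$ the LET (keV/µm), $Z^*$ the Barkas effective charge and the
DDREF dividing only the gamma-like term. Equivalently, the
targeted-effects (TE) pseudo-action cross section per unit gamma-ray slope
is $\Sigma_{TE}/\alpha_\gamma = (\Sigma_0/\alpha_\gamma) P + L(1-P)/6.24$.
The non-targeted (NTE, bystander) variant adds
$\eta/F$ with
$\eta/\alpha_\gamma = (\eta_0/\alpha_\gamma)\,x\,e^{-\eta_1 x}
\,[1-e^{-F A_{bys}}]$, $x = Z^{*2}/\beta^2$ — a per-particle contribution
that saturates with fluence $F$, so NTE effects dominate at low fluence
and recover the TE model at high fluence.

A mixed field folds these over the particle spectra
($(\Sigma F) = \sum_j \int \phi_j \Sigma(Z_j, E)\,dE$, trapezoidal
quadrature on each component's grid), and the engine's dose-like scalar is
the **gamma-equivalent dose**
$H = \sum_j \int \phi_j\,(L/6.24)\,R_{QF}\,dE$, computed separately for
the solid-cancer and leukemia endpoint classes (distinct parameter sets,
leukemia RBEs being smaller).

### Parameter values

The quality-factor and NTE constants are *calibration placeholders*, not
results of this package: the defaults put $6.24\Sigma_0/\alpha_\gamma$ at
7000 µm²Gy (solid) and 1750 (leukemia) with $\kappa = 624$, $m = 3$ and
DDREF = 2, which lands peak heavy-ion quality factors in the 20–40 range
and a dose-averaged quality factor near 4 for the default GCR field — the
scale published fits occupy. The bystander amplitude
$\eta_0/\alpha_\gamma = 0.005$ was chosen once so that enabling NTEs
roughly doubles (factor ~2–3) the risk of the 940-day Mars scenario, the
magnitude reported for non-targeted effects; tests assert only the
direction NTE > TE, never a factor. All of these are plain configuration
(`qf_params()`, `nte_params()`) and the formula-level tests are
parameter-agnostic. LET comes from a simplified Bethe stopping-power
formula for water (mean excitation 75 eV) with Barkas effective charge —
a standard external physics convention, accurate to a few percent above a
few MeV/u and swappable via the `let` argument where exposed.

# Synthetic populations

No demographic or registry data ship with the package. The generator
(`synthesize_population()`) builds, deterministically:

* **Life tables** with Gompertz–Makeham hazard
  $\mu(a) = c + b e^{\theta a}$ ($c = 2\times10^{-4}$/y,
  $\theta = 0.095$/y), calibrating only $b$ by root finding so the life
  expectancy at birth matches the published 2018 value for each of eight
  presets (four U.S. race/ethnicity groups × two sexes; e.g. API female
  86 y, Black male 71.3 y) within 0.1 y. One-parameter calibration keeps
  the inverse problem well posed.
* **Cancer-rate tables** with per-tissue age curves
  $\lambda_{0IT}(a) \propto (a/70)^{k_T} e^{-\max(a - a_{pk,T},0)/8}$ — a
  multistage-carcinogenesis power of age with an old-age roll-off past a
  tissue-typical peak age (leukemia gets a childhood peak plus adult
  rise). The roll-off matters: an unbounded power law concentrates nearly
  all incidence above age 80, which both inflates old-age rates beyond
  anything observed and suppresses the attained-age advantage of young
  exposures that drives the decline of REIC with exposure age. Curves are
  scaled so the age-adjusted total (under a single-year spread of the US
  2000 standard million, `us2000_standard_weights()`) matches the
  published 2014–2018 total for each preset within 1%, with tissue shares
  from an editable, sex-specific mix patterned on coarse U.S. site
  distributions. Mortality is incidence times a per-tissue lethality
  ratio kept at or below $1/1.1$, so the mortality-consistency correction
  (`apply_mortality_correction()`, which caps
  $\lambda_{0MT} \le \lambda_{0IT}/1.1$) is never triggered on generated
  tables. The correction itself follows the reading that *incidence must
  exceed mortality by 10%* — the printed sentence inverts this, but the
  inverted reading contradicts its own motivation (delay-adjusted
  incidence falling below mortality at old ages); the margin is an
  argument.

The GCR environment is likewise a labelled synthetic stand-in for an
environment-plus-transport calculation: five ion groups (H, He, C/O, Si,
Fe) with broad spectra peaking near 300 MeV/u on a 120-point log grid
(converged to ~$10^{-3}$ under trapezoidal folding), number fractions
giving a realistically proton-dominated field, globally scaled so the
absorbed dose rate equals a target (default 0.4 mGy/day, the scale
measured in deep space behind ~20 g/cm² aluminum near solar minimum).
Mission profiles lump each segment into one acute exposure at its
midpoint age (tested to agree with a 12-way monthly split within 2% on
REIC); the Mars surface is a single multiplicative flux attenuation
(default 0.45, i.e. surface dose rate about half of free space) — a
knob, not atmosphere transport.

**What passing tests do and do not show.** The synthetic world reproduces
the *calibration targets* (life expectancies, age-adjusted totals), the
*arithmetic* of the ERR registry, and the *structural behaviour* of the
pipeline (linearity, latency gates, competing-risk direction, orderings
driven by rates × longevity). It does not reproduce population-specific
age *structure* of cancer rates — all presets share tissue mixes and
curve shapes — so cross-population results that hinge on that structure
(e.g. the relative ranking of Black versus API males, where early-onset
rate differences matter) are outside what the generator can show, and
absolute REIC/REID magnitudes depend on the placeholder quality-factor
calibration and synthetic spectrum, not on transported organ fluences.
One documented consequence: with the LSS remainder coefficient rising
with exposure age (+26%/decade) and remainder being ~30% of male
incidence, the longest-lived male preset (API) shows a flat-to-slightly-
rising REIC between exposure ages 30 and 50 instead of a strict decline;
all other presets decline monotonically.

# Uncertainty propagation

`parameter_pdfs()` assigns each ERR coefficient a distribution matched to
its central value and 95% interval: lognormal (median at the central
value) when the interval is strictly positive and right-skewed by more
than 20%, else normal with $\sigma = \text{width}/3.92$; entries without
an interval stay fixed. DDREF and $\Sigma_0/\alpha_\gamma$ are lognormal
about their configured medians (geometric SDs are configuration, since
the underlying posteriors are not refit here), NTE parameters are wide
lognormals, and an overall flux-scale factor (normal, mean 1, SD 0.1)
carries dosimetry uncertainty.

Sampling uses counter-based per-trial substreams: trial $i$ under master
seed $s$ re-seeds from a fixed affine function of $(s, i)$, so trials are
order-independent and results are bit-reproducible. Within a trial the
DDREF, quality-factor and NTE draws are shared across tissues while ERR
coefficients are drawn independently per tissue (shared-coefficient
tissues — esophagus, leukemia — stay shared); which parameters should be
correlated across tissues is not settled, and this default is switchable
by supplying a modified PDF set. Sampled values are clamped to their
domains (coefficients at 0, DDREF at 1); point estimates are never
truncated. Intervals are empirical percentiles (default 2.5/97.5) across
trials, with the point estimate always computed from the central
parameters; non-finite trials are dropped with a logged count and more
than 1% rejections is an error.

# Problem sizes and runtime choices

The age grid is fixed at 101 points, so a single lifetime-risk evaluation
is microseconds-to-milliseconds. The test suite uses 100 randomized
engine-versus-enumeration instances, 25 random fluxes for fold
inequalities, and Monte-Carlo runs of 100–4000 trials (mission-level runs
use 100–150 trials, enough to exercise reproducibility, bracketing and
width orderings; percentile-accuracy checks use 4000 trials on a scalar
model where each trial is a single draw). The 120-point energy grid was
chosen by checking trapezoidal convergence against a 10× refinement.

# Known limitations

* All quality-factor, NTE and DDREF numerics are placeholders at the
  published scale; absolute REIC/REID values are therefore indicative
  only, a few-fold above the corresponding published mission estimates.
* The RR transfer is linear in dose with no high-dose saturation, so
  multi-Gy inputs can produce nominal "percent" risks above 100; the
  intended regime is the sub-Gy gamma-equivalent scale of GCR missions.
* One body-average spectrum stands in for tissue-specific transported
  fluences; shielding dependence is a label, not a calculation.
* Smoking interaction (beyond the zero-smoking lung limit), circulatory
  endpoints, and additive-transfer mixtures are out of scope.
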