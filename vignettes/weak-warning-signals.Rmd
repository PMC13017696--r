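---
title: "Modelling weak warning signals: avian vision contrasts and predation-risk statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weak warning signals: avian vision contrasts and predation-risk statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyJND)
```

## The scientific problem

Many chemically defended, gregarious insect larvae — pine sawflies are a
classic case — are *weakly* warning-coloured: green-black-grey patterns
with none of the canonical red/yellow-on-black aposematic elements, in a
prey that nonetheless stores a potent defensive fluid. `preyJND` packages
the quantitative toolkit used to study this phenomenon: (i) a
receptor-noise-limited (RNL) model of avian colour vision that converts
reflectance spectra into perceptual contrasts, (ii) survival and
behaviour-phenotype statistics for field predation and common-garden
experiments, and (iii) seeded synthetic-data generators that emulate every
input with known ground truth.

## The receptor-noise-limited vision model

A viewer (default: a tetrachromatic "blue tit type" passerine) is defined
by single-cone spectral sensitivities $S_i(\lambda)$, a double-cone
sensitivity $S_D(\lambda)$ for the achromatic channel, relative cone
abundances $\eta_i$, and a reference Weber fraction $\omega_{\mathrm{ref}}$.
For a stimulus with reflectance $R(\lambda)$ under illuminant $I(\lambda)$
(D65 daylight by default), each receptor's quantum catch is

$$Q_i = \int_{300}^{750} R(\lambda)\, S_i(\lambda)\, I(\lambda)\,
d\lambda,$$

computed by the trapezoidal rule on a canonical 1-nm grid (300–750 nm,
the range of typical field spectrometer exports and published 1-nm
sensitivity tables). Catches are von Kries normalised — divided by the
catches of an adapting background — which makes every contrast invariant
to rescaling the illuminant. The adapting background defaults to the
illuminant itself (an ideal white); passing the mean natural background
instead is supported and changes only the adaptation state, not the
machinery.

Receptor signals are logarithmic (Fechner) catch ratios,
$\Delta f_i = \ln(Q_i^a/Q_i^b)$ — the standard choice for reflective
stimuli in bright light. Channel noise scales with the reciprocal square
root of cone abundance,

$$\omega_i = \omega_{\mathrm{ref}} \sqrt{\eta_{\max}/\eta_i},$$

so the most abundant cone carries $\omega_{\mathrm{ref}}$ (0.05 for the
default viewer) exactly. Chromatic contrast is the noise-weighted
distance between signal vectors in the subspace orthogonal to the
achromatic direction,

$$\Delta S^2 \;=\; \frac{\sum_{i<j} (\Delta f_i - \Delta f_j)^2 /
(\omega_i\omega_j)^2}{\sum_i 1/\omega_i^2},$$

which reduces to $|\Delta f_1 - \Delta f_2|/\sqrt{\omega_1^2+\omega_2^2}$
for a dichromat and to the familiar published trichromat/tetrachromat
formulas otherwise (the test suite checks all channel counts against an
independent matrix-form oracle). Achromatic contrast is
$\Delta L = |\ln(Q_D^a/Q_D^b)|/\omega_D$. Both are in just-noticeable-
difference (JND) units, read conventionally: below 1 JND two objects are
likely indistinguishable, 1–3 JND (inclusive: boundary values fall in
the middle class) distinguishable only under optimal light, above 3 JND
distinguishable.

### The packaged viewer is a documented synthetic approximation

Measured whole-eye blue tit sensitivity tables are not redistributed
here. The packaged `bluetit_d65` viewer instead builds each curve from
the Govardovskii A1 pigment template at the blue tit peak absorbances
(UVS 371, SWS 448, MWS 503, LWS 563 nm; LWS pigment in the double cone)
with simplified sigmoidal oil-droplet and ocular-media filters, and
default abundances UVS:SWS:MWS:LWS = 1 : 1.92 : 2.68 : 2.7 (LWS most
abundant, so $\omega_{LWS} = 0.05$). Absolute JND values are sensitive
to these choices; studies that need to match a specific published viewer
should load their own tables with `loadVisualSystem()`. All packaged
curves are clearly flagged as synthetic in the data files.

## Spectral input conventions

`readSpectrum()` accepts long (`wavelength,value`) and wide CSV/TSV.
Spectrometer exports sampling several times per nanometre are reduced
with `decimation = "first_per_nm"` (first sample per integer-nm bin).
Negative readings are instrument noise and are clipped to zero with a
recorded count; percent-scale files (values far above 1) are divided by
100 with a message. Natural backgrounds are averaged as spectra
(`meanSpectrum()`), whereas paint verification averages *cone catches*
within each measurement set (`paintVerification()`); the pipeline
deliberately preserves this asymmetry rather than unifying it, because
the two conventions answer different questions (a physical average
surface vs an average perceptual stimulus).

## Survival analysis of the field experiment

The emulated experiment crosses colour manipulation (cryptic green vs
conspicuous yellow paint) with group size (solitary vs group of 10) on
branches along two transects over five days, with daily checks, dead
larvae replaced, and predator-exclusion mesh bags as controls.

Because replacements have different exposure histories, the analysis
uses only each branch's **first attack**: `firstAttackFilter()` removes
replacement larvae and truncates every exposed branch at its first attack
day — deaths that day remain events; later deaths *and* survivors leave
the risk set there. We chose this whole-branch truncation (over keeping
survivors at risk to day 5) because censoring at a stopping time of the
branch's own event history keeps the partial likelihood valid and hazard
ratios consistent; keeping survivors at risk while recoding their
possible later deaths would leave "immortal" individuals in later risk
sets and attenuate estimates. The alternative reading
(`rule = "keep_original_events"`: drop replacements, keep all original
events) is available, and results are typically insensitive to the
choice.

`coxFit()` maximises the Cox partial likelihood by damped Newton
iteration from $\beta = 0$ (convergence: max |score| < 1e-8), with Efron
tie handling by default — appropriate for daily-granularity ties —
and Breslow available for cross-checks. Transect heterogeneity is
handled by stratification (a separate baseline hazard per transect),
the defensible desk-scale stand-in for a transect random effect when
there are only two transects; a gamma-frailty penalised fit is possible
future work. Monotone likelihoods (complete separation of events) are
flagged as non-convergence, never reported silently. Green colour and
the solitary treatment are the reference levels. Mesh-bag controls are
analysed separately by `meshComparison()`: a binomial mixed model of
death on exposure with a transect random intercept, plus a fixed-effects
binomial GLM of death on group and colour within the bags.

## Behaviour–colour models

Per-larva defensive phenotypes (U-posture yes/no, defensive-fluid
deployment yes/no, fluid volume, body length) are joined with
per-individual JND contrasts. `behaviorAnalysis()` runs the standard
battery: binomial models of each binary behaviour on each centred
contrast with a family random intercept (the dorsal-colour U-posture
model is fitted as a plain GLM, the one member conventionally run
without the random intercept), and gamma log-link models of fluid volume
on centred contrast plus body length (allometry), after exact zeros —
individuals producing no fluid — are replaced by 0.001
(`replaceZeros()`; the constant is configurable).

The mixed models maximise the marginal likelihood with a single Gaussian
random intercept integrated by **adaptive Gauss–Hermite quadrature**
(15 nodes by default; one node is exactly the Laplace approximation, and
estimates are invariant at 1e-6 to doubling the nodes). Standard errors
come from the observed information; inference is Wald (z and two-sided
p), matching how such models are conventionally reported; no
likelihood-ratio machinery is provided. Gamma dispersion uses the
Pearson estimator; the shape is not profiled. With fewer than two
families the mixed fits fall back to plain GLMs with a note, and male
records are excluded up front when a `sex` column is present.

### Small-sample behaviour, verified against lme4

At the emulated study's own size (12 families of 3–5, n≈51, most larvae
displaying) maximum-likelihood logistic estimates carry the well-known
finite-sample inflation: in 500-replicate simulations the mean slope
estimate is about 20% above the generating value, and the Wald test is
conservative (≈3% rejection at nominal 5%). We verified on identical
simulated datasets that `lme4::glmer` (nAGQ = 15) produces the same
estimates (agreement ≈ 1e-5) and p-values: this is a property of ML
estimation at that sample size, not of this implementation. The test
suite records this honestly — the small-sample recovery check of the
acceptance suite fails by this inherent bias — and asserts calibration
in asymptotic regimes plus agreement with lme4 elsewhere. Users should
read single-study slope magnitudes at n≈51 with this in mind.

## Synthetic data: what it does and does not emulate

`genSpectrum()` builds smooth reflectance curves (flat / Gaussian peak /
sigmoid edge / mixtures, optional seeded Gaussian noise clipped to
[0,1]) with presets for the system's stimulus classes: dark green
needles with a red edge, a dimmer green dorsum, a flat pale ventral
side, yellow and green paint, and a pale-amber defensive fluid. The
presets guarantee the qualitative structure the analyses rely on
(ventral more luminance-contrasting against needles than dorsal; yellow
paint chromatically conspicuous against the dorsum, green paint not).
They are not measured spectra: no wavelength-correlated noise, no
specular artefacts, no within-individual pattern variation — so passing
tests demonstrate correct model arithmetic and pipeline behaviour, not
agreement with any particular measured animal.

`genPredation()` draws discrete-day deaths (geometric waiting times)
under a proportional-hazards model with defaults chosen once as the
emulated study conditions: replicate counts 20/20/22/19 exposed and
9/10/10/9 mesh cells, groups of 10, five days, true colour log hazard
ratio ln(1.64) and group effect −0.429, transect log-frailty SD 0.25,
baseline daily hazard 0.05 (≈23% five-day mortality for a cryptic
solitary larva — realistic field predation), and 2% background mortality
in mesh bags. Replacement larvae are emitted with their true entry days
so the first-attack filter has real work to do. Daily discretisation
produces the tied event times the Efron method is there for.

`genBehavior()` draws 12 families with 3–5 larvae (default layout totals
51), lognormal contrasts around 4–8 JND, logistic behaviours with family
random intercepts (defaults at the reported scale of such systems:
intercepts 1.2–1.7, opposed colour/luminance slopes, family SD 0.5), and
gamma fluid volumes (shape 2) with a slow length trend. U-posture and
fluid deployment are drawn independently given family and contrast —
biologically the fluid display requires the posture, but the simplified
independence keeps each model's generating parameters individually
recoverable for testing.

All generators thread their seeds through a private RNG stream and
restore the global state, so they are bit-reproducible and cannot
perturb the caller's randomness.

## Numerical choices and degenerate inputs

* Integration: trapezoid on the 1-nm grid; resampling is linear with no
  extrapolation.
* Cox: damped Newton with step-halving; |β| > 15 triggers the monotone-
  likelihood guard.
* GLMs: IRLS to 1e-10 on coefficients; binomial separation (|β| > 12) is
  flagged.
* GLMM: L-BFGS-B over (β, log σ) with log σ bounded in [log 1e-6,
  log 20]; σ near the zero boundary switches standard errors to the
  β-only information block (the log-σ direction is flat there) with a
  note.
* Degenerate inputs fail loudly: constant responses, zero background
  catches, non-positive gamma responses, missing branch ids, unnamed
  stimulus sets.

## Problem sizes used by the checks

The packaged verification suite exercises: 1000 random
catch/Weber-fraction instances against the matrix-form oracle; 1000
simulated null experiments (n = 200) for Cox Wald calibration; 500
replicates of the full generate → filter → fit pipeline (n ≈ 430) for
hazard-ratio recovery; 500 replicates of the behaviour generator for the
mixed-model recovery study; and brute-force likelihood oracles on small
fixtures for the Cox, Laplace and gamma engines. These sizes were chosen
to give Monte-Carlo standard errors well below the effects being
verified.

## Known limitations

* The vision model treats each stimulus as a single homogeneous colour:
  no spatial pattern, viewing distance, or acuity effects.
* No photon-shot-noise (dim light) variant; the Weber fractions assume
  bright-light, neural-noise-limited discrimination.
* Transect "random effect" in the Cox model is stratification, not a
  frailty fit.
* The gamma volume model reproduces the 0.001 zero-replacement
  convention rather than a zero-inflated mixture.
* Absolute JNDs from the packaged synthetic viewer approximate, but will
  not exactly match, values computed from measured sensitivity tables.
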