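# preyJND

Quantitative tools for studying **weak warning signals**: how chemically
defended but inconspicuously coloured prey (green-black-grey gregarious
sawfly larvae are the motivating system) appear to avian predators, and
what increased conspicuousness costs them in the field.

The package bundles three layers that are usually scattered across ad-hoc
scripts:

1. **A receptor-noise-limited (RNL) model of tetrachromatic bird vision.**
   Reflectance spectra R(λ) are combined with receptor sensitivities
   S\_i(λ) and an illuminant I(λ) into quantum catches
   Q\_i = ∫ R S\_i I dλ (trapezoid, 1-nm grid, 300–750 nm), von Kries
   normalised by an adapting background. With log receptor signals
   Δf\_i = ln(Q\_i^a/Q\_i^b) and abundance-scaled Weber fractions
   ω\_i = ω\_ref √(η\_max/η\_i) (ω\_ref = 0.05 on the most abundant cone),
   chromatic contrast is

       ΔS² = Σ_{i<j} (Δf_i − Δf_j)²/(ω_i ω_j)²  ÷  Σ_i 1/ω_i²

   and achromatic (double-cone) contrast is ΔL = |ln(Q_D^a/Q_D^b)|/ω_D,
   both in just-noticeable-difference (JND) units: < 1 indistinguishable,
   1–3 distinguishable only in optimal light, > 3 distinguishable.

2. **Field-experiment statistics.** A first-attack filter for daily
   predation records with replacement larvae; an in-package Cox
   proportional-hazards engine (damped Newton on the partial likelihood,
   Efron/Breslow ties, transect stratification); mesh-bag control
   comparisons; logistic mixed models with a family random intercept
   fitted by adaptive Gauss–Hermite quadrature; gamma log-link models for
   defensive-fluid volume with the 0.001 zero-replacement convention.

3. **Seeded synthetic-data generators** for spectra (needles, larval
   dorsum/venter, paints, defensive fluid), whole predation experiments
   (eight treatment cells, five days, replacements, mesh bags) and
   family-structured behaviour records — so the entire pipeline is
   testable end to end with known ground truth.

The packaged `bluetit_d65` viewer is built from pigment-template
(nomogram) curves with simplified droplet/ocular filtering and is clearly
documented as a synthetic approximation; load measured tables with
`loadVisualSystem()` to match a specific published viewer.

## Worked example

```r
library(preyJND)

vs  <- bluetitVisualSystem()   # tetrachromatic viewer, LWS Weber 0.05
d65 <- illuminantD65()         # daylight illuminant

# how conspicuous is the pale ventral side against pine needles?
needles <- genSpectrumSet("needle_green", n = 6, noise_sd = 0.01, seed = 2)
larva   <- genSpectrum("larva_ventral_pale")
jndContrast(larva, meanSpectrum(needles), vs, d65)
#> Contrast 'larva_ventral_pale' vs 'mean of 6 spectra':
#>   chromatic  dS = 16.838 JND (distinguishable)
#>   achromatic dL = 25.476 JND (distinguishable)
```

Both contrasts are far above the 3-JND threshold: the ventral surface a
larva exposes during its defensive display is clearly discriminable to
the modelled bird even though the resting dorsum is near-cryptic
(`genSpectrum("larva_dorsal_green")` gives ΔS ≈ 1 against the same
background).

```r
# a simulated five-day predation experiment, analysed like the field data
rec  <- genPredation(seed = 1)           # true colour log-HR = ln(1.64)
filt <- firstAttackFilter(rec)           # drop replacements, first attacks
coxFit(filt)
#> Cox proportional-hazards fit (efron ties, strata: 2 strata)
#> n = 432, events = 47, converged: TRUE (5 iterations)
#>                  coef hazard ratio     se       z      p
#> color(yellow)  0.0789       1.0821 0.2935  0.2687 0.7881
#> group(10)     -0.4042       0.6675 0.3643 -1.1094 0.2672
```

A single simulated experiment is noisy (here the yellow hazard ratio
happens to land near 1); across replicated experiments the estimator
recovers the generating hazard ratio — the acceptance checks verify a
500-replicate mean within Monte-Carlo error of ln(1.64).

```r
# behaviour-colour battery on simulated phenotype records
beh <- genBehavior(seed = 1)             # 51 larvae, 12 families
behaviorAnalysis(beh, models = "uposture")$uposture_ventral_luminance
#> binomial model (logit link), 12 groups:
#>   u_posture ~ ventral_luminance_jnd + (1 | family)
#> n = 51, converged: TRUE
#>                       estimate     se      z      p
#> (Intercept)             1.6164 0.4902 3.2978 0.0010
#> ventral_luminance_jnd   0.1756 0.1974 0.8899 0.3735
#> random-intercept SD = 0.2916
```

The estimate is the log-odds change in displaying the U-posture per JND
of (centred) ventral luminance contrast, with the family random
intercept absorbing shared ancestry.

A thin CLI over the same functions lives at `inst/scripts/preyjnd`
(`contrast-table`, `cox`, `behavior`, `simulate` subcommands).

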