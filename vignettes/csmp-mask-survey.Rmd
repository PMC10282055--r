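---
title: "Methods: radiometric analysis of CsMP mask surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiometric analysis of CsMP mask surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmpsurvey)
```

This vignette documents the models implemented in `csmpsurvey`, the
parameter choices that matter, what the synthetic survey generator does and
does not emulate, and the numerical conventions the package commits to.

## The measurement chain

A mask survey of radiocesium-bearing microparticles (CsMPs) produces four
linked tables: masks (with ¹³⁴Cs/¹³⁷Cs activities from gamma spectrometry),
isolated particles, stacked inner/outer mask pairs, and residences with
distances from the release point. Every quantitative claim downstream —
particle sizes, collection efficiencies, activity fractions, the distance
law — is algebra on decay-corrected activities, so the package builds up
from a small set of primitives.

### Decay correction

Activities are referenced to calendar dates and moved between them by the
exponential law with half-lives 2.0652 y (¹³⁴Cs) and 30.08 y (¹³⁷Cs). These
are standard nuclear-data values; the package validates them end to end, by
checking that forward-correcting the bundled worn-date particle table
reproduces the published 2011-03-11 table to its printed precision. Date
arithmetic uses whole-day differences divided by 365.25: the survey records
dates only, and at the precision of three printed digits 365- and
365.25-day years are indistinguishable, so the choice is a convention, not
a fit. The decay factor is treated as exact — half-life uncertainties are
orders of magnitude below counting uncertainties here. Censored
(below-detection-limit) activities decay-correct their limit by the same
factor and keep their flag.

### Counting statistics

Quantification is comparative: a sample's net count rate against a standard
of known activity in the same geometry, with first-order quadrature of both
relative counting errors. A net estimate driven below zero by a background
fluctuation reports 0 Bq with its honest sigma. Detection limits follow
Currie, $L_D = 2.71 + 4.65\sqrt{B}$ counts; the surveys state their limits
(0.070 Bq per nuclide on masks at 50 000 s) but not the formula behind
them, so Currie is adopted and used *inversely*: `background_for_limit()`
calibrates the synthetic instrument background to whatever limit is stated.
A value exactly at the limit censors (conservative tie rule). Efficiency is
a single effective scalar per geometry; no energy-dependent curve, peak
fitting, or coincidence-summing correction is modelled.

### Particle sizing

Spherical Type-A particles obey
$A_{137} = 2\times10^{16}\,V^{1.40}$ (Bq at 2011-03-11, V in cm³), inverted
as $V = (A/2\times10^{16})^{1/1.40}$. For the diameter the package's
default is the formula exactly as published,
$d = 2\,(3V\pi/4)^{1/3}\times10^4$ µm. That expression is *not* the
geometric sphere inversion — π sits in the numerator where the sphere
formula divides by it — but it is what reproduces every published diameter,
so the package treats it as the reference convention (`as_printed`) and
also provides the true sphere (`spherical`), which is smaller by exactly
$\pi^{2/3} \approx 2.145$ for every volume. The discrepancy is surfaced in
the documentation rather than silently "fixed", because the published
diameter range (1.33–4.30 µm) and any comparison against it only make sense
in the printed convention. Optional first-order size uncertainties use
$\sigma_V/V = \sigma_A/(1.40\,A)$ and $\sigma_d = d\,\sigma_V/(3V)$; they
are off by default since the source tables report none.

### Pair efficiency, fractions, accounting

Collection efficiency of a stacked pair is
$(1 - A_{137}^{inner}/A_{137}^{outer})\times100$ %. Because the outer mask
pre-filters the air reaching the inner one, this overestimates the true
single-mask efficiency; the package reports the formula verbatim and
documents the bias rather than attempting a correction that the data cannot
constrain. "Significant" means efficiency above zero — the survey's own
tally ("51 of 76 cases") is reproduced under that reading, and summary
statistics (min, max, mean) are taken over significant cases only. CsMP
activity fractions are plain ratios at the worn date, flagged as upper
bounds when the numerator is censored. Particle accounting derives the host
mask from the particle ID's letter suffix when no explicit mask column
exists.

### Distance regression

Mask activity against residence distance is fitted by ordinary least
squares on log₁₀–log₁₀ axes; an inverse-square dilution law is slope −2,
and noiseless power-law data recover their exponent to 1e-10. A
`fixed_slope` option fits the intercept only and reports the constrained
model's $R^2 = 1 - RSS/TSS$. One analysis choice deserves emphasis: in the
end-to-end pipeline, censored masks enter the regression *at their
detection-limit value* instead of being dropped. Censoring probability
rises with distance, so dropping censored masks preferentially removes far,
low-activity observations and attenuates the slope toward zero — in
synthetic replicates that selection bias is ~+0.25 on a slope of −2 and
drops confidence-interval coverage to ~80 %; detection-limit substitution
restores ~93 % coverage at the light (~5–10 %) censoring rates these
surveys operate at. The regression operates on whatever (distance,
activity) rows the caller supplies: the package imposes no per-residence
aggregation, since multiple masks are legitimately worn per visit.

### Imaging-plate workflow

The IP forward model deposits, per source, a total expected
photo-stimulated-luminescence count (activity × a single calibration scalar
× exposure) through a Gaussian kernel — isotropic with σ = 1.5 px for
insoluble particles, anisotropic (default 3:1 axes, major scale 6 px) for
soluble smears — over a uniform background, then draws per-pixel Poisson
counts. Defaults (background 1 count px⁻¹ min⁻¹, 30 min exposure, 20 counts
Bq⁻¹ min⁻¹) put a ~1 Bq particle comfortably above threshold on a 64×64
grid while keeping background-only false positives below 5 % of images.
These constants are configuration, not physics: the real workflow used a
commercial plate reader and an external image tool whose internals are not
reproducible, so the simulator's role is to give the detection and
discrimination logic a controllable stand-in.

Hotspot detection thresholds at background mean + 5σ, with background
statistics estimated robustly (median and MAD) so the sources themselves do
not inflate the threshold, and groups pixels by 8-neighbour connectivity.
Spot circularity is the ratio of minor to major principal second moments of
the background-subtracted component — 1 for a circular distribution (the
signature of a spherical glassy particle), small for elongated smears; a
single-pixel component scores 1 by convention, and the metric is invariant
under 90° rotation. The isolation simulation removes a `solubility`
fraction of the source activity per sonication round: an insoluble particle
gives a flat count trace within noise, fully soluble material falls to
background after one round, and intermediate solubility declines
geometrically. The observable cannot distinguish truly soluble material
from a brittle particle destroyed by handling or accumulated
self-irradiation; `solubility` is a phenomenological removal fraction and
the package makes no mechanistic claim.

## The synthetic survey generator

`survey_config()` defaults encode the campaign's study conditions: 59
residences at 1.6–16.1 km, six persons, ~284 masks, roughly half worn in
stacked pairs, N95 respirators a ~5 % minority, worn dates spanning
2016–2019, counting at 50 000 s (masks) and 600 000 s (particles) with
backgrounds Currie-calibrated to the stated detection limits, and a
¹³⁴Cs/¹³⁷Cs ratio of 1.08 at 2011-03-11 (the Unit-2 value, which the
surveyed particles matched).

Where the study conditions leave parameters open, the defaults are chosen
once as field-plausible values and documented here:

* **Distance law**: soluble mask loading $C/d^2$ with $C = 300$ Bq km² and
  1.0 dex of per-mask lognormal scatter. This reproduces the observed
  dynamic range of mask activities (~0.5–1400 Bq) and, deliberately, a
  *weak* log-log association (mean $R^2 \approx 0.21$ across replicates) —
  the observed relationship was moderate, not tight. Scatter is drawn per
  mask, not per residence: within-visit variation (rooms, tasks, persons)
  dominates, and it keeps OLS confidence intervals honest.
* **Particle occurrence**: expected CsMP count per mask is
  $0.35\,\max(0,\ \log_{10}(S/10\,\mathrm{Bq}))$ in the soluble loading $S$
  — zero below 10 Bq and rising with activity, the minimal monotone form
  consistent with how occurrence was reported; the coefficient yields
  ~30–50 particles per campaign.
* **Particle activities**: lognormal at 2011-03-11 (meanlog log 0.35,
  sdlog 1.0), truncated at 25 Bq — the campaign's new finds never exceeded
  that. Activities are drawn at 2011 *first* and volumes derived through
  the power law, so sizing recovery has an exact internal truth.
* **Pair efficiency**: drawn uniformly on 0–85 %, applied to the soluble
  component of the inner mask; the recorded per-pair truth is the realized
  total-activity efficiency (particles land on each mask independently), so
  recovery isolates counting noise.

Every mask's true total is its soluble background plus the sum of its
particles, so the particle inventory can never exceed the mask total.
Ground truth (per-mask, per-particle, per-pair, and the law parameters) is
retained immutably alongside the observable tables, and one seed governs
all draws: a fixed config regenerates byte-identical surveys.

What the generator does **not** emulate: person-level behaviour (cleaning
vigour, wearing time — unrecorded), building-material effects, plume
chronology, within-residence correlation of mask loadings, and the real
joint distribution of soluble versus particle-bound cesium, which is
unknown (the surveys themselves flag it as open). Passing recovery tests
therefore demonstrates that the *pipeline* is unbiased under its stated
assumptions, not that those assumptions exhaust real indoor contamination.

## Numerical conventions

* **Printed-value agreement.** Recomputed values are compared to table
  cells by rounding to the tables' 3-significant-figure convention and
  allowing one unit in the last printed digit. The source tables were
  computed from unrounded intermediates (e.g. the first particle's
  diameter prints 3.61 µm but recomputes to 3.617 from the rounded 1.15 Bq
  input), so exact ties are not attainable from printed inputs.
* **Known cell anomalies.** One published volume (9.51×10⁻¹² cm³ for the
  particle recomputing to 9.52×10⁻¹³) is an evident exponent typo — its
  printed diameter matches the 10⁻¹³ value. Two particle tables disagree on
  a handful of IDs; `match_particle_ids()` joins by ID, pairs leftovers by
  nearest worn-date ¹³⁷Cs activity, and warns about every non-identity
  assignment instead of guessing silently.
* **Degenerate inputs.** Same-date decay factors are exactly 1; censored
  numerators propagate as flagged upper bounds; zero-significant
  efficiency summaries return NA statistics rather than errors; empty
  particle tables count as zeros; background-only IP images return an
  empty hotspot table.
* **Problem sizes.** The test suite runs the generator at its default
  scale (~300 masks) for single-survey checks, 100 replicates for
  slope-coverage, 20 replicates for bias metrics, and 200 seeded images
  for hotspot recall — sizes at which the binomial/Monte-Carlo margins of
  the asserted thresholds are comfortable.

## Limitations

The package reimplements the survey's *algebra* faithfully but cannot
reproduce measurements it has no access to: raw spectra, the supplementary
per-mask tables, per-residence size-fraction activities, and the original
IP scans are not deposited, so the corresponding stages are validated on
bundled transcriptions and on synthetic data instead. The efficiency
formula's overestimation bias is documented, not corrected. The ¹³⁴Cs decay
of nine-plus years means single-particle isotope ratios carry large errors;
the ratio machinery propagates them honestly, and unit attribution should
be read from the ensemble, not from individual particles.
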