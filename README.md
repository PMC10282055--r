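# csmpsurvey

Radiometric analysis of radiocesium-bearing microparticles (CsMPs) collected
on face masks worn during indoor cleaning of residences near the Fukushima
Dai-ichi Nuclear Power Plant (FDNPP).

After the 2011 accident, insoluble glassy microparticles carrying highly
concentrated radiocesium ("Type A" CsMPs, ~1–5 µm) remained preserved inside
evacuated houses. Surveys that put non-woven masks and N95 respirators on
people cleaning those houses, then gamma-counted the masks and isolated
individual particles by imaging-plate (IP) autoradiography, produce a
characteristic bundle of tabular data: per-mask ¹³⁴Cs/¹³⁷Cs activities with
counting uncertainties and detection-limit censoring, per-particle
activities, stacked inner/outer mask pairs, and residence distances from the
release point. `csmpsurvey` implements that entire analysis chain as a
tested, reusable, tidyverse-style R package — every function takes a data
frame and returns a tibble — together with a synthetic survey generator so
the whole pipeline runs and is validated with no external data.

## What it computes

* **Decay correction with uncertainty.** Activities move between reference
  dates by `A(t₂) = A(t₁) · exp(−ln2 · Δt/T½)` with T½(¹³⁴Cs) = 2.0652 y,
  T½(¹³⁷Cs) = 30.08 y; σ and detection limits scale by the same factor.
  Isotope ratios `R = A₁₃₄/A₁₃₇` at a common date carry first-order
  quadrature errors, `(σ_R/R)² = (σ₁₃₄/A₁₃₄)² + (σ₁₃₇/A₁₃₇)²`, and attribute
  material to a reactor unit (≈ 0.94 / 1.08 / 1.05 for Units 1–3 at
  2011-03-11).
* **Particle sizing.** The Type-A power law
  `A₁₃₇ [Bq] = 2×10¹⁶ · V[cm³]^1.40` (activity at 2011-03-11) is inverted
  for volume; diameter follows the published formula
  `d [µm] = 2·(3Vπ/4)^⅓·10⁴` (with a true-sphere variant, differing by
  exactly π^⅔, also provided).
* **Counting statistics.** Comparative quantification against an activity
  standard, Currie detection limits `L_D = 2.71 + 4.65√B`, and conservative
  censoring at the limit.
* **Survey analytics.** Stacked-pair collection efficiency
  `(1 − A_inner/A_outer)·100 %`, CsMP-to-mask activity fractions, particle
  accounting, occurrence frequency by mask activity class, and log-log
  regression of mask activity on distance (slope −2 = inverse-square
  dilution).
* **IP autoradiography simulation.** A forward model for plate exposures,
  5σ hotspot detection with 8-connected components, a spot-circularity
  score that separates spherical particles from soluble smears, and the
  cut–sonicate–re-image isolation workflow.
* **Synthetic surveys.** `generate_survey()` draws a full campaign
  (residences, masks, pairs, particles, Poisson counting noise, censoring)
  with retained ground truth; `recover_and_score()` runs the pipeline and
  reports bias against that truth.

## Worked example

The first catalogued particle, Mask-001-A, was measured at 1.01 ± 0.01 Bq
¹³⁷Cs referenced to its worn date (2016-09-29). Sizing it:

```r
library(csmpsurvey)

p <- tibble::tibble(particle_id = "Mask-001-A", a137_bq = 1.01,
                    a137_sigma = 0.01, ref_date = as.Date("2016-09-29"))
size_particles(p)
#> # A tibble: 1 × 8
#>   particle_id a137_bq a137_sigma ref_date   a137_2011_bq a137_2011_sigma
#> 1 Mask-001-A     1.01       0.01 2016-09-29         1.15          0.0114
#> # ℹ 2 more variables: volume_cm3 <dbl>, diameter_um <dbl>
```

The activity decays back to 1.15 Bq at 2011-03-11, giving a volume of
2.51×10⁻¹² cm³ and a diameter of 3.6 µm — the published estimate for this
particle. The bundled reference tables reproduce the survey's headline
statistics:

```r
efficiency_summary(reference_pair_efficiencies()$efficiency_pct)
#>       n n_significant min_pct max_pct mean_pct
#> 1    51            51    1.37    81.7     34.7

count_particles(reference_particles_worn())
#>   n_total n_new n_masks_with_new
#> 1      48    44               27
```

i.e. a mean collection efficiency of 34.7 % (maximum 81.7 %) over the 51
informative mask pairs, and 48 catalogued particles of which 44 were new
finds. A synthetic campaign exercises the full chain against ground truth:

```r
sv <- generate_survey(survey_config(seed = 1))
sv
#> <csmp_survey> 305 masks, 37 particles, 57 pairs, 59 residences (seed 1)
recover_and_score(sv)
#>    metric                                    value
#>  1 particle_activity_rel_bias             0.000441
#>  2 particle_diameter_mean_abs_rel_error   0.00314
#>  3 efficiency_mean_abs_error_pp           1.62
#>  4 slope                                 -2.19
#>  7 slope_covers_true                      1
#>  8 r_squared                              0.212
#>  ...
```

Particle activities come back with ~0.04 % bias, diameters to 0.3 %, pair
efficiencies to 1.6 percentage points, and the fitted distance-law slope's
confidence interval covers the true exponent −2.

See the methods vignette (`vignettes/csmp-mask-survey.Rmd`) for the models,
parameter choices and limitations.

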