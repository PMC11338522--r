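# axoncontact

Quantification of axonal ER–ribosome association and local-translation
readouts from fluorescence microscopy, with a built-in forward-model
simulator for validation by parameter recovery.

Developing axons translate mRNA locally, and a substantial share of axonal
ribosomes sits within nanometres of the tubular endoplasmic reticulum (ER).
Establishing that association from images — and measuring what happens to
axonal translation when the ER is perturbed — rests on a handful of bespoke
image quantifications that are usually re-implemented ad hoc per study.
This package provides them as tested, reusable estimators for anyone
analyzing two-channel axon imaging (STED, expansion, SMLM or confocal):

* **Contact fraction** — threshold the ER channel (Otsu or fixed), measure
  the proportion of ribosome-channel intensity inside the mask, inside the
  mask enlarged by a physical distance (5 nm convention), and under a
  flipped-channel chance-overlap null:
  `f = Σ_mask I / Σ_all I`, with association read from `f − f_flipped`.
* **Segmented-line intensity** — background-corrected mean intensity along
  a polyline with perpendicular averaging; group effect sizes as
  `100·(mean_ctrl − mean_test)/mean_ctrl`.
* **Polarity index** — `PI = (I_d − I_a)/(I_d + I_a)` with `I_d` the mean
  of three dendrites; 0 unpolarized, < 0 axonal, > 0 dendritic.
* **Split-APEX normalization** — per-batch normalization of streptavidin
  proximity signal to the control mean, optional V5×HA expression
  correction; branch-point versus shaft fold enrichment.
* **FRAP** — background subtraction, reference-ratio correction for
  acquisition bleaching, exact 100%/0% anchoring on the three pre-bleach
  frames and the first post-bleach frame, curve averaging, recovery at a
  stated time.
* **Morphology** — Sholl intersection counts on thresholded neuron fills
  (10 µm steps, connected-component counting on discretized circles) and
  kymographs by path reslicing with maximum projection.

The companion simulator (`make_scene()`, `render_channel()`,
`emit_localizations()`, `simulate_frap()`, `simulate_morphology()`)
generates ground-truth scenes — a tubular ER with programmable coverage, a
programmable ER-bound punctum fraction and binding distance, Gaussian PSF,
Poisson noise — so every estimator is checked by recovering programmed
effects. Shipped presets encode the headline effect sizes studied in this
problem domain (29/30/37% intensity reductions, a 40–50% contact band,
1.75-fold branch enrichment).

## Worked example

Simulate 20 STED-like axon segments with 45% of ribosome puncta bound
within 30 nm of the ER tubule, then measure the association blind:

```r
library(axoncontact)
library(dplyr)

segs <- simulate_contact_segments("fig2-sted-contact", n_segments = 20, seed = 5)
res  <- analyze_segments(segs)

summarise(res, across(c(fraction_in_mask, fraction_in_enlarged,
                        fraction_flipped, mask_area_fraction), mean))
#> # A tibble: 1 × 4
#>   fraction_in_mask fraction_in_enlarged fraction_flipped mask_area_fraction
#>              <dbl>                <dbl>            <dbl>              <dbl>
#> 1            0.439                0.552            0.373              0.416

wilcox.test(res$fraction_in_mask, res$fraction_flipped,
            paired = TRUE, alternative = "greater", exact = FALSE)$p.value
#> [1] 4.78e-05
```

44% of ribosome-channel intensity falls in the ER mask — inside the
reported 40–50% band for this geometry — while mirroring the ribosome
channel drops the overlap to 37%, so the association is far beyond chance
(`plot_contact_summary(res)` draws the paired comparison). An end-to-end
knockdown experiment compresses to one call:

```r
glance(run_experiment(list(preset = "fig1-kd-puro", n = 30, seed = 42)))
#> # A tibble: 1 × 8
#>   preset           n  seed effect_quantity effect_value  p_value method        …
#> 1 fig1-kd-puro    30    42 percent_change          28.1 3.02e-11 Mann-Whitney U
```

The preset programs a 29% reduction in the test group's photon budget; the
pipeline recovers 28.1% from the rendered images and a Mann–Whitney test
on per-segment corrected means confirms the group difference.

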