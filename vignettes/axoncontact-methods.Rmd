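---
title: "Methods: estimators, forward model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, forward model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoncontact)
```

axoncontact quantifies the spatial association between the axonal
endoplasmic reticulum (ER) and ribosomes in two-channel fluorescence
images, together with the surrounding readouts used in studies of axonal
local translation: segmented-line intensity quantification, the polarity
index, split-APEX proximity normalization, FRAP recovery curves, Sholl
profiles and kymographs. Because raw imaging data in this field are rarely
reusable for estimator validation, the package pairs every estimator with
a forward-model simulator, and validity is demonstrated by parameter
recovery: simulate with a known effect, measure blind, compare.

## The contact estimator

An axon segment is imaged in an ER channel (e.g. GFP-Sec61β) and a
ribosome channel (e.g. RpS12 immunostaining), straightened, and analyzed
as follows:

1. the ER channel is thresholded into a binary mask (Otsu by default);
2. the mask is enlarged by a stated physical distance (conventionally
   5 nm) via disk dilation;
3. the proportion of total ribosome-channel intensity falling inside the
   plain mask, the enlarged mask, and the plain mask with the ribosome
   channel mirrored left–right (the *flipped null*) is reported.

The statistic is a plain intensity proportion,
$f = \sum_{\text{mask}} I \,/\, \sum_{\text{all}} I$. Two properties
matter for interpretation. First, $f$ is monotonically non-decreasing in
dilation distance, so mask and enlarged-mask values are nested measures.
Second, $f$ includes the in-mask share of any diffuse background: if a
fraction $\beta$ of total intensity is unstructured background and the
mask covers an area fraction $m$, then $f$ contains a baseline term
$\approx \beta m$ on top of the genuinely ER-associated signal. This is
not a defect of the implementation but a property of the measurement as
practiced — it is exactly why the flipped-channel null is carried along:
mirroring one channel preserves the baseline and the intensity envelope
while destroying the spatial correlation, so a genuine association shows
up as `fraction_in_mask > fraction_flipped` in a paired comparison.

Numerical conventions, chosen once and asserted against brute-force
oracles in the test suite: thresholding uses a strict `>`; pixel indices
are 0-based externally with centers at $(i + 0.5)\,\mathrm{px}$;
localization histograms bin with half-open edges; the dilation disk
contains offsets with $dx^2 + dy^2 \le r^2$; a sub-pixel enlargement
distance rounds up to one pixel (a 0-pixel dilation would make the two
reported measures identical, which contradicts their role as nested
measures); dilation with distance 0 is the identity. The "enlarged" mask
is the filled dilated mask (original ∪ ring), not the ring alone; both
are computable from the returned quantities since the plain-mask value is
always reported alongside.

## The forward model

`make_scene()` models a straightened axon as a 2D strip (the projection
actually quantified) of programmable width containing a single centered
ER tubule of radius $r$, present either continuously or as discrete
stretches covering a stated fraction of the length (`er_coverage`,
exponentially distributed run lengths). Real axonal ER is "a few long,
narrow tubules", not a perfectly uniform rod; the coverage parameter is
what gives the flipped null its power — a strictly
translation-invariant tubule would make the flip a no-op by symmetry.

Ribosome-like puncta split into a bound class — placed within
`bind_distance_nm` of the tubule *surface* ($||y| - r| \le d$), at
positions drawn over the tubule stretches — and an unbound class, uniform
over the strip but excluded from a clearance zone of the same width
around the tubule band. Two conventions deserve emphasis:

* the clearance is measured to the *full-length band* $|y| \le r$, not to
  individual stretches. If unbound puncta were only excluded near
  existing stretches, gap-dwelling puncta at central $y$ would mirror
  onto the mask and the flipped "null" would sit *above* the unflipped
  value — an anti-correlated null. With the band convention the null is
  centered (verified by a dedicated calibration test on uniform scenes).
* with `bind_distance_nm = 0` the clearance is empty and puncta are
  exactly uniform; this limit is what the null-calibration tests use.

The exclusion zone is a simulator convention that makes the ground-truth
bound fraction identifiable, not a biological claim.

`render_channel()` projects the scene onto a pixel grid, convolves with
an isotropic Gaussian PSF (FWHM in nm; kernel truncated at $4\sigma$,
normalized, hence mass-conserving to well under 1%), scales to photons,
and applies Poisson shot noise followed by Gaussian read noise with a
clip at zero. Puncta deposit their amplitude into the containing pixel;
the tubule deposits a per-column mass of $2r/\mathrm{px}$ distributed
transversally either as the projection of a uniformly labeled cylinder
*surface* (default, `er_profile = "surface"`: the arcsine-shaped,
edge-bright profile a membrane marker actually produces in projection)
or as a flat ridge (`er_profile = "solid"`, a volume marker). The
surface profile matters quantitatively: its blurred tails push the Otsu
mask edge beyond the geometric radius, so puncta bound within a thin
shell of the membrane are captured with high efficiency, whereas a flat
ridge puts the mask edge at the radius itself and caps capture of a
surface-symmetric bound shell at about one half.

`emit_localizations()` provides the same ground truth as a
single-molecule localization table (Poisson blink counts per punctum,
Gaussian jitter at the stated precision, tubule-surface sampling for the
ER channel), and `render_localizations()` reconstructs images from such
tables; localization *fitting* from raw frames is out of scope.

## Presets and the recovery suite

Named presets (`inst/extdata/presets.yaml`, versioned) freeze complete
parameter sets:

* `fig1-kd-puro` / `fig1-removal-puro` — condition pairs with the test
  group's photon budget scaled by 0.71 / 0.70 (29% / 30% programmed
  reductions in puromycin-labeling intensity);
* `fig1-kd-rps12` — punctum density scaled by 0.63 (37% fewer ribosomal
  puncta);
* `fig2-sted-contact` — STED-like contact geometry: 20 nm pixels, 60 nm
  PSF FWHM, 30 nm binding shell, bound fraction 0.45 (mid-range of the
  reported 40–50% band);
* `fig3-branch` — branched segments with punctum density in 2 µm windows
  at branch points at 1.75× the shaft density.

Where the underlying study states a value (scale factors, binding shell,
bound fraction, PSF/pixel scale, profile lengths of 30–50 µm, 10 µm Sholl
steps, 30 s FRAP intervals), the preset uses it. Where it does not —
puncta density, tubule radius, axon width, ER coverage, photon budget —
the presets are simulator conventions, chosen once so that the
`fig2-sted-contact` operating point sits inside the reported 40–50% band
and then frozen. Under that preset the measured per-segment
`fraction_in_mask` averages ≈ 0.44–0.47 across master seeds (20
segments each), the mask covers ≈ 0.45 of the segment area, and the
flipped null sits ≈ 6 points lower (paired one-sided Wilcoxon
p ≈ 5×10⁻⁵). Condition-pair recoveries land within ~1 point of the
programmed 29/30/37% at n = 30 segments per group, and the branch preset
recovers 1.76 ± 0.06-fold across seeds at n = 16 segments. In the
branch preset the *measured* window is the central 1.5 µm of the 2 µm
enrichment zone: the PSF-blurred density transition at the window edges
otherwise dilutes the branch mean by a few percent.

A reproducibility note: every generator takes a seed, and independent
substreams are derived by hashing (master seed, group, replicate) with
`seed_stream()`, so any single image can be regenerated without
replaying the whole simulation.

## Intensity readouts

`profile_mean()` resamples an image along a polyline at one-pixel arc
steps with bilinear interpolation, averages across a stated perpendicular
width, and subtracts the mean of an explicit background ROI. The
background is explicit because the source protocols say only
"background corrected"; an explicit ROI is reproducible and testable.
Negative corrected means are retained and flagged rather than truncated
at zero — truncation would bias group percent changes.

`percent_change()` is `100 (mean_c - mean_t)/mean_c` (positive =
reduction). `polarity_index()` implements
$PI = (I_d - I_a)/(I_d + I_a)$ with $I_d$ the mean of exactly three
dendrite intensities; $PI = 0$ is unpolarized, negative axonal, positive
dendritic. `normalize_apex()` divides streptavidin intensities by the
per-batch control mean (control mean ≡ 1 by construction); optional
expression correction divides each cell's value by the product
V5 × HA of its split-fragment expression markers *before* batch
normalization. The product form and the order are conventions — the
source protocol states that a correction was applied but not its
functional form — and are documented as such; cells with a zero marker
are flagged and excluded rather than propagating infinities.

## FRAP

`normalize_frap()` subtracts background, corrects acquisition bleaching
by dividing by the unbleached same-cell reference trace rescaled to its
own pre-bleach mean (the ratio method; the correction is exact for any
multiplicative per-frame decay, which the test suite asserts), then
affine-maps so the mean of the three frames preceding the bleach is
exactly 100% and the first post-bleach frame exactly 0%. The bleach
anchor is the first post-bleach frame, not the trace minimum. No
resampling or interpolation happens anywhere: curves must share a time
grid to be averaged, and `recovery_at()` reads the nearest sampled
timepoint — with the standard 30 s interval a resampler would only hide
acquisition errors. The simulator emits the reference trace alongside
the bleached one because the correction requires it; when no reference
exists the correction can be disabled explicitly.

## Morphology

`sholl()` counts, for each radius in fixed steps (default 10 µm) around
a chosen soma center, the 8-connected components of foreground pixels in
an annulus of 1.5 px around the circle. The annulus is wider than
$\sqrt{2}/2$ px so an 8-connected neurite path cannot step across it
undetected; component counting (rather than counting foreground pixels)
makes the count independent of neurite thickness. The default maximum
radius is the image diagonal. `simulate_morphology()` co-emits the
analytic circle–segment crossing counts computed from its segment list;
the raster counts match the oracle on 100% of radii across a 20-seed
suite once radii grazing a segment endpoint within 1.5 px are excluded
(at such tangencies the discrete and continuous answers legitimately
differ).

`kymograph()` reslices a movie along a traced path (bilinear, one-pixel
arc steps, symmetric sampling grid so reversing the path exactly reverses
the rows) and projects across the band thickness with a maximum by
default (mean available). Row 0 is the path start; anterograde movement
appears as streaks advancing down the rows across frames.

## What the simulator does not emulate

The forward model is deliberately 2D: no z-stacks, no depth-dependent
PSF, no STED depletion or expansion-microscopy distortion physics, no
fluorophore photophysics beyond Poisson blink counts, no organelle
motion, no spectral crosstalk, and no localization fitting. Passing the
recovery suite therefore shows that the estimators are unbiased and
correctly implemented *under the stated forward model* — it does not
certify performance on real images with structured background,
out-of-focus light or chromatic misalignment. The contact statistic in
particular inherits a baseline from mask area and diffuse background;
conclusions about association should always be drawn from the contrast
with the flipped null, never from the absolute proportion alone.

## Problem sizes

The shipped test suite and the acceptance script use the study-scale
sizes: 30 segments per group for condition pairs, 20 segments for the
contact preset, 16 for the branch preset, 50 uniform segments for null
calibration, a 20-seed Sholl oracle suite, and 8–10 replicate FRAP
traces per sweep point. The complete suite runs in well under a minute
on one core; unit tests use smaller n where the full size adds nothing.
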