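---
title: "Methods: from field images to osteoblast differentiation hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from field images to osteoblast differentiation hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoscreen)
```

## The assay and its statistical model

Early osteoblast differentiation is read out through cellular alkaline
phosphatase (ALP) activity. The fluorogenic substrate ELF 97 precipitates
where ALP is active and appears as punctate spots; DRAQ5 stains nuclei; an
optional Ki67 channel marks proliferating cells. A 384-well screening plate
is imaged at 15 fields per well (about 80 % of the well area), and the
whole screen is run in triplicate plates.

The quantitative chain is:

* **Per field** — the number of segmented nuclei, and the summed
  background-corrected ELF intensity over the detected spot area.
* **Per well** — cell number is the *sum* of nuclei over fields; per-cell
  ALP activity is the *unweighted mean over fields* of (ELF intensity in
  spot area / nuclei count). Fields with zero nuclei carry no per-cell
  information and are excluded from that mean rather than entered as
  zeros, which would bias the well downward; a well in which *no* field
  has nuclei gets a missing value, never a fake zero. The Ki67 fraction is
  computed from pooled counts (positives over all fields divided by nuclei
  over all fields), which stays unbiased when fields differ in density.
* **Per plate** — each well's cell number and ALP activity are expressed
  as percent of the mean over the plate's Non-Targeting (NT) control
  wells, so the NT mean is exactly 100 %. ALP activity is additionally
  binary-logarithmized and z-scored within the plate using the sample
  standard deviation.
* **Per gene** — the three replicate wells are averaged, and their log2
  ALP values are tested against all NT log2 values of the replicate group
  with an unpaired, homoscedastic (pooled-variance), two-tailed Student's
  t-test. The homoscedastic variant is used because it is the only variant
  the protocol names.

Hits are called by three criteria applied in order:

1. **Viability** — genes whose mean percent cell number falls below 60 %
   of NT are excluded (`excluded_viability`). The published criterion
   ("reduced cell number less than 60 %") is grammatically ambiguous; we
   read it as a cut at 60 % of control with the boundary itself passing,
   consistent with the transfection control (siKif11, ~25 % of control)
   being the archetype of what the filter removes.
2. **Effect size and significance** — suppressors need ALP ≥ 160 % and
   activators ALP ≤ 40 % of control (both bounds inclusive), with an
   unadjusted p < 0.05. Unadjusted p-values reproduce the published
   procedure; a Benjamini–Hochberg option exists (`p_adjust = "BH"`) but
   is off by default, and the multiplicity caveat stands.
3. **z-score margin** — the gene's mean z must lie at least 1.0 above
   (suppressor) or below (activator) the *NT wells' mean z*, not zero.
   Centring on the NT mean is deliberate: published cut values on a real
   plate differ by exactly 2.0 while being asymmetric about zero, which is
   what one gets when the band is placed around a nonzero NT mean z.

Two further conventions where the source is silent: wells with an ALP
activity of exactly zero (possible in strong knockdowns) receive half the
smallest positive value on the plate as a pseudocount before the log2 and
are flagged (`log2_pseudocount`); and the z-score pool includes library,
NT and positive-control wells but excludes Kif11, mock and untreated wells,
whose ALP is not part of the screened distribution. Both are configurable.

## Segmentation operators

Two operator sets are implemented and kept deliberately independent, so
either can serve as a check on the other.

**Threshold pipeline.** Nuclei are masked by adaptive Otsu thresholding:
Otsu's threshold is computed in 50 px windows, and windows whose intensity
range falls below 25 % of the image's global range fall back to the global
Otsu threshold (a windowed Otsu on a featureless tile would split noise).
Masks are hole-filled, touching nuclei are split by a distance-transform
watershed (tolerance 1, on by default; whether the original analysis split
or merged touching nuclei is not stated, so the split is a configurable
choice), and components outside the 4–21.22 µm equivalent-diameter band
are discarded. The ELF channel is background-corrected by subtracting a
median-smoothed background estimate (filter radius 20 px, larger than the
10 px object scale), clipped at zero. Spots are then taken above a single
global threshold: twice the mode of the 256-bin intensity histogram — with
one numerical safeguard. The mode of a background-subtracted, zero-clipped
image is 0, and a threshold of zero would label pure read noise as spots;
the threshold is therefore floored at 6 robust noise SDs, where the noise
SD is estimated from the 0.9 quantile of the zero-clipped image (the 0.9
quantile of clipped zero-mean Gaussian noise is 1.2816 σ, and sparse
bright spots barely move that quantile). Both the multiplier and the floor
are exposed in `detection_params()`.

**Round-object pipeline.** All channels are background-corrected with a
white top-hat (disc structuring element; feature size 50 px for the
nuclear channel, 100 px for ELF and Ki67, plus a second 10 px top-hat at
the spot stage). Images are reflected at their borders before the
morphology so border pixels are treated like interior ones. Round-object
detection then keeps connected components that (a) reach the intensity
threshold — 200 a.u. for nuclei, 1000 a.u. for spots, interpreted as the
component's *peak* intensity since the original software's semantics
(peak vs mean) are not documented; (b) have an equivalent diameter
(diameter of the circle of equal area) inside the size gate; and (c) have
circularity `4·π·area / perimeter²` of at least 0.6. The perimeter is a
four-direction Crofton estimate from boundary crossings; digital disks
score about 0.9 and elongated bars below 0.5 under this estimate, so the
0.6 default separates them cleanly. The cut itself is our choice — the
operator's name implies a roundness criterion but no value is given — and
it is configurable. Intensity thresholds are instrument-scale quantities;
when analysing images on a different scale (including synthetic fixtures)
they should be adapted, which is why every threshold lives in
`detection_params()` rather than in code.

Ki67 positivity is per nucleus: mean Ki67 intensity over the nucleus's
pixels strictly greater than 300 a.u.

Degenerate inputs are defined, not errors: a constant image has no Otsu
threshold and yields zero objects; an all-background ELF image yields zero
spots; an empty label map yields zero Ki67 positives. Zero-variance log2
values make a z-score undefined and *are* an error naming the plate.

## The synthetic-screen generator

No raw images of the screen are deposited, so the generator is the
package's substitute experiment, and its defaults are the study
conditions: 384-well plates in triplicate, 15 fields per well covering
80 % of the well, pixel size 1.29 µm at binning 2 (the sensor geometry is
not published, so the 696×520 px default field is explicit configuration,
not a hard-coded fact), nucleus diameters drawn from 9–15 µm (inside the
detectable 4–21.22 µm band), spot diameters from 2–6 µm (inside
1.3–8 µm), and a baseline population of 3000 cells per well — a plausible
growth endpoint for 1800 seeded cells, consistent with the 0–6000 display
scale used for plate heatmaps.

The stochastic model: per-gene effects act multiplicatively on expected
cell number (`viability_fraction`) and on per-cell ALP
(`alp_fold`); each well draws two independent lognormal noise factors
(mean 1, CV `noise_cv`, default 0.10 — an assumption, as the assay
publishes no quantitative noise model, chosen to match the scale of
mean ± SEM triplicate variability typical of such screens); field-level
nuclei counts are Poisson; spots per cell are Poisson (mean 4); per-spot
total intensities are lognormal (CV 0.5), the standard shape for
fluorescence intensities, whose bounded left tail also keeps faint spots
from falling below any detection floor. Setting `noise_cv = 0` makes cell
counts deterministic, so a null screen reproduces its baseline exactly. In
`kif11_control` wells the planted viability effect applies only to the
transfected cell fraction (`transfection_efficiency`, default 0.75): with
complete killing of transfected cells the surviving fraction is
1 − 0.75 = 0.25, which is what makes Kif11 wells report transfection
efficiency as ~75 % cell loss.

Geometry and rendering: nuclei are placed by rejection sampling with no
overlap (centres at least the sum of radii plus 2 px apart; a bounded
number of retries, then an error suggesting a lower density); spots are
perinuclear, optionally also non-overlapping (`spots_nonoverlapping`,
used for fixtures whose detected counts must equal ground truth, with the
search ring widening as retries accumulate so dense cells can still place
all spots). Nuclei render as raised-cosine-edged disks (edge width 1 px)
rather than binary disks, so thresholding is exercised realistically;
spots render as normalized kernels whose pixel sum equals the planted
intensity exactly (sub-pixel spot radii are widened to 1 px for rendering
— a 1.3 µm spot is a single pixel at this sampling and would otherwise
fall between pixel centres and lose its planted intensity). Each channel
gets a constant background (default 100 a.u.) and additive Gaussian read
noise (default SD 10 a.u.), clipped at zero. Ki67 is simulated at the
nucleus level from two well-separated normal distributions (positive
800 a.u., negative 50 a.u., both SD 10 % of mean) around the 300 a.u.
threshold.

Two consistent surfaces exist: `simulate_screen()` generates geometry and
rendered images with full ground truth, while `simulate_measurements()`
draws field-level statistics directly from the same distributions (the
summed spot intensity is the identical compound-Poisson-lognormal sum,
just never rasterised). The fast path makes whole-screen power studies
tractable; the rendered path validates the full segmentation chain against
planted truth. Everything is deterministic given the config seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: optical point-spread functions, uneven
illumination beyond what the background filters are asked to remove,
overlapping or multi-layered cultures (the assay itself excluded a cell
line whose nuclei overlapped), debris and staining artefacts, plate-edge
effects, and spatial autocorrelation of effects across a plate. Exact
ground-truth count recovery is demonstrated on well-separated, in-range,
high-SNR objects; crowded or dim real images will segment worse than the
fixtures do.

## Problem sizes used by the tests and the acceptance script

The rendered fixtures use 200×260 to 240×320 px fields at 40–60 cells per
field, 2–4 fields per well and up to 20 wells per plate — small enough to
run the whole suite in well under a minute of rendering while keeping the
cell density (cells per unit area) at the default field's level, so
placement and segmentation behave as they would at full field size. The
per-well statistics are ratios and means, invariant to that scaling.
Fixture detection uses a spot-peak threshold matched to the fixture
intensity scale, as the a.u. thresholds are instrument properties. The
recovery study runs the full screen geometry (320 library genes plus
controls, triplicate, measurement-level path). The Kif11 acceptance run
renders 20 wells × 4 fields; repeated simulation of that statistic at
this plate size spreads with an SD of about 2.4 percentage points around
the 75 % transfection efficiency, which is the basis of the tolerance
used in its test.

## Known limitations

* The two operator sets share the µm→px conversion and labeling helpers
  but not thresholds; numerical agreement between them is only guaranteed
  on clean fixtures.
* Percent-of-control normalization presumes healthy NT wells; a plate
  whose NT wells fail has no defined scale and the pipeline stops rather
  than guessing.
* p-values are unadjusted by default (faithful to the published
  procedure); treat `not_hit`/hit boundaries near p = 0.05 accordingly.
* The B-score/median-polish family of plate-effect corrections is
  intentionally out of scope; the model assumes no systematic row/column
  effects, and the generator plants none.
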