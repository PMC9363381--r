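---
title: "Quantifying stress granules and polyQ aggregates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress granules and polyQ aggregates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulescope)
```

## The measurement problem

Cells expressing polyglutamine-expanded ataxin-7 (ATXN7) form bright nuclear
and cytoplasmic inclusions that sequester RNA-binding proteins such as TDP-43
and TIA1, while the stress-granule nucleator G3BP1 condenses into small
puncta ("speckles") and, under oxidative stress (arsenite), into full stress
granules. granulescope turns multi-channel immunofluorescence micrographs of
such cells into the quantities used to characterise this biology:

* co-localisation of partner stains with ATXN7 aggregates, scored on
  intensity profiles along a line through each aggregate;
* counts of speckles, granules and G3BP1/TIA1 double-positive stress
  granules, normalised per cell;
* object morphometry (eccentricity, form factor, area, perimeter) and signal
  texture (intensity variance);
* stress-granule disassembly kinetics after stress release;
* replicate-level fold changes with mean ± SEM and Welch tests.

Because the original micrographs of such experiments are rarely deposited,
the package ships a synthetic-micrograph generator that plants all of these
structures with known ground truth. Every analysis stage is validated by
parameter recovery against planted values, not against real images.

## Segmentation model

**Three-class Otsu with the middle class as background.** Speckle and
aggregate foregrounds come from a global Otsu threshold with three classes on
a 256-bin histogram of the channel; the two lower classes (true background
and diffuse cellular staining) are both treated as background, so foreground
means *strictly above the upper threshold* `t_high`. The search over
threshold pairs is exhaustive on the binned histogram (vectorised with
cumulative sums), hence exact; ties break towards the lowest pair. The
per-replicate *minimum threshold* mirrors calibration against a bright
reference condition (arsenite-treated non-induced cells): the floor is the
median `t_high` over the replicate's reference images, and is applied as
`max(t_high, floor)` — it can only shrink foreground, never grow it.

**Speckle rules.** A candidate component (8-connected by default) is a
speckle iff its area lies within `[min_area, max_area]`, its moments-ellipse
eccentricity is at most `max_eccentricity` (the "rounded or oval" rule), and
its intensity is at least eightfold over the immediate background. The
immediate background is the median of a 2-px-wide ring starting 2 px outside
the object, excluding pixels of any other object; the median resists
contamination by neighbouring speckles. The intensity statistic is the
object's *peak* intensity by default: for a diffraction-limited Gaussian
punctum of true peak fold 10, the mean over the segmented mask (which is the
bright top of the Gaussian) measures only about 7–8-fold, so a mean-based
eightfold rule would systematically reject puncta that a human scorer —
judging peak brightness — accepts. `fold_statistic = "mean"` is available
for the stricter reading.

**Aggregates.** The diffuse ATXN7 level differs between nucleus and
cytoplasm, so one global threshold either swallows cytoplasmic aggregates or
floods the nucleus. The detector therefore computes the three-class
threshold separately over the nuclear region and the extra-nuclear region
and unions the two top classes. Touching aggregates are declumped with a
distance-map watershed. Two sanity rules reject non-aggregate foreground: an
area floor (default 20 px², separating aggregates from diffraction-limited
speckles, whose above-threshold cores are below ~15 px²) and a peak-over-ring
fold of at least 2.5 (in images with *no* true aggregates the top Otsu class
necessarily lands inside the noise of the diffuse stain; such blobs sit
within ~1.5-fold of their surroundings and are discarded). Compartment is
assigned by centroid containment in the nucleus mask.

**Nuclei.** Two-class Otsu on the DNA channel, hole filling, a small
opening, then a distance-map watershed to split touching nuclei, with an
area floor of 60 px². Nucleus counts normalise all per-cell measures.

## Co-localisation scoring

Through each sampled aggregate a line is drawn along the object's principal
axis with total length `max(length, 3 × major axis)`; all channels are
sampled at 1-px steps by bilinear interpolation. The reference (ATXN7) peak
is the maximum of the 3-point moving-average-smoothed series; the partner
peak is the smoothed local maximum nearest the reference peak. The immediate
background is the median of the partner's raw values over the outer quartiles
of the line. An aggregate is positive iff the partner peak is within 3 px of
the reference peak and at least twofold over that background (inclusive
`>=`; a `strict` switch gives `>`).

Two numerical choices matter here:

* *Peak smoothing* (3-point moving average) suppresses single-pixel noise
  maxima; the threshold comparison still uses the raw-median background, so
  scoring is exactly invariant under multiplying all channels by a constant.
* *In-cell background.* When the line exits the cell, its outer quartiles
  sample the dark exterior, which understates the immediate background and
  inflates the fold — diffuse cytoplasmic staining would then score as a
  "peak". When a cell-region mask is available (union of nuclei dilated by
  the cytoplasm width), out-of-cell samples are excluded from the background
  median (falling back to all samples if fewer than four remain). This is
  what a human scorer does implicitly: "immediate background staining" means
  staining, not coverslip.

Sampling follows the five-cytoplasmic + five-nuclear aggregates from five
images per replicate scheme. Selection is deterministic given a seed and
*keyed to image identity* (a per-image hash ranks and seeds the draws), so
reordering the image list changes nothing.

## Morphometry

Eccentricity is that of the ellipse with the object's second central
moments (0 = circle, the CellProfiler convention); pixels are modelled as
unit squares, adding 1/12 to the diagonal moments. On exhaustively
rasterised ellipses with semi-axes 5–40 px the estimator is within 0.02 of
the analytic value for all but a handful of small near-circular shapes
(worst ≈ 0.04 at semi-axes 7×6), where the binary raster genuinely does not
determine the eccentricity more precisely — masks of neighbouring parameter
values coincide. This is a property of any pixel-moment estimator, not of
the implementation, which agrees with a naive per-pixel oracle to machine
precision.

Perimeter is the Moore-traced contour length with corner-corrected
chain-code weights (0.980 per axial step, 1.406 per diagonal, −0.091 per
corner): raw pixel-edge counting overestimates smooth contours by ~5 %,
which would deflate the form factor `4π·area/perimeter²` of a disk to ~0.9.
With the correction, disks of radius 10–40 px are within 0.05 of form factor
1; below ~10 px radius the discretisation bias of any contour estimator
exceeds that band, which is why shape metrics are only computed for objects
of at least 5 px and reported with that caveat. Objects touching the image
border are counted but excluded from morphometry (their shape is undefined).

Texture is the plain population variance of pixel intensities over the
analysis region — the simplest reading of a "variance" texture output. The
default region is the cell area (nuclei dilated by the cytoplasm width), so
empty background does not dilute the contrast; whole-image mode is
available. Total stain intensity is reported per nucleus.

## Statistics

The biological replicate is the statistical unit: per-image measurements are
averaged per replicate, and conditions are compared on replicate means with
a two-sided Welch t-test (Mann–Whitney optional). This matches the n = 3–9
designs these experiments use; with so few replicates, Welch is the safest
default and no multiple-testing correction is applied (mirroring how such
panels are conventionally reported; noted in output metadata). Flags follow
p < 0.05 (*) and p < 0.01 (**). Fold change is the ratio of condition mean
to control mean; SEM is over replicate means. Recovery curves divide each
timepoint's mean per-cell granule count by the t = 0 mean, so the t = 0
value is exactly 1 and SEM is propagated on the normalised scale.

## The synthetic generator: what it emulates and what it does not

Each scene plants elliptical nuclei (bright DNA stain), a cytoplasmic
annulus, per-compartment diffuse staining, and Gaussian-profile objects:
aggregates (σ 3–5 px, peak 12× local background), speckles/granules
(σ 1.3–2 px, peak 10×, axis ratio 0.7–1), partner-stain peaks on aggregates
(fold 3–5, concentrated at 0.6× the aggregate σ) and on granules
(double-positive stress granules). Noise is Poisson shot noise followed by
Gaussian read noise (sd 3.5), quantised to 16-bit. Intensities are in
arbitrary units chosen so that diffuse levels sit well above the noise floor
but far below saturation.

Preset conditions encode the study regimes: the control plants 0.75 G3BP1
speckles per cell; the polyQ condition plants exactly six times as many and
the same amplitude, which — given the measured variance floor of the noise
model — yields a planted texture-variance contrast of about fourfold over
the cell region. The arsenite preset plants six granules per cell, 80 %
TIA1-double-positive and half ATXN7-positive; the recovery preset reuses it
as the t = 0 frame of independent-frame series whose expected counts are
thinned by `2^(−t/half-life)`. TIA1 co-localisation probabilities on
aggregates are 0.8 (cytoplasmic) and 0.6 (nuclear); G3BP1 never co-localises
with aggregates. Scene sizes default to 256×256 px with 6 cells; tests and
the acceptance script use 20 frames per arm for contrasts, 100 sampled
aggregates per co-localisation regime, 8 frames per timepoint for kinetics,
and 200 simulated two-arm experiments (128×128, 3 cells) for the null
rejection rate — sizes chosen so each planted quantity is estimated with a
standard error several times smaller than the effect it checks.

What the generator does *not* emulate: optical blur correlations (noise is
pixel-independent), uneven illumination, autofluorescence gradients,
out-of-focus light, 3D structure, photobleaching, or cell-to-cell
morphological variability beyond ellipse radii. Passing parameter-recovery
tests therefore demonstrates that the measurement chain is correct and
unbiased under a realistic point-spread/noise model — not that segmentation
would be equally accurate on real micrographs with debris, clumped cells or
staining artefacts.

## Degenerate inputs and edge policies

* Images with fewer than three distinct values cannot be three-class
  thresholded and raise a degenerate-input error; blank DNA channels yield
  an empty nucleus mask with a warning, and such images are excluded from
  per-cell measures (logged).
* Profile lines are truncated symmetrically at image borders; fewer than 7
  samples is an error and the aggregate is skipped (logged as a sampling
  shortfall).
* A zero partner background along a profile is degenerate (no fold can be
  formed).
* Ties in the threshold search break towards the lowest threshold pair;
  label masks are always relabelled consecutively from 1.
* Masks with more than 65535 objects cannot be written as 16-bit label
  TIFFs and raise an error.

## Known limitations

* Eccentricity of very small near-circular objects is discretisation-limited
  (above); form factor of sub-8-px-radius disks is biased high.
* The aggregate/speckle boundary is a configurable area floor, adequate for
  the planted size separation; real data with a size continuum would need a
  joint shape/intensity classifier.
* The line-profile rule scores one partner peak per aggregate; multi-lobed
  partner staining within one aggregate is collapsed to the nearest local
  maximum.
* Recovery series are independent fields per timepoint (fixed-cell design),
  so the curve estimates a population mean, not single-cell kinetics.
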