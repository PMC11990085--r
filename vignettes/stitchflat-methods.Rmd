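---
title: "Correcting vignetting on stitched mosaics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting vignetting on stitched mosaics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchflat)
```

## The problem

Large-field microscopy (SRS nanoscopy, whole-slide fluorescence and
brightfield) assembles its images from a grid of small tiles. Each tile is
acquired through the same optics, so each carries the same radially
decreasing illumination pattern — vignetting — and the stitched mosaic shows
a periodic grid of dark seams. The artifact degrades segmentation, spectral
unmixing and super-resolution deconvolution, and most existing correctors
(BaSiC, CIDRE, MIST) need the individual tiles, which are often no longer
available for archived or database images.

`stitchflat` corrects the shading *directly on the fully stitched image*.
The key observations are that (i) the tile grid leaves a strong periodic
imprint on the per-row and per-column mean intensity profiles, so its period
can be recovered from their frequency spectra without any metadata, and
(ii) once the period is known, the profile's envelope at the tile scale
separates the shading from genuine tissue structure.

## Pipeline

For an input mosaic `I` the pipeline runs:

1. **Sanitization.** NaN pixels (non-rectangular scan ROIs) are ignored
   throughout; Inf pixels are set to the maximum finite value. The
   brightest pixels — the top 1% of finite intensities, or all fully
   saturated pixels if those are more numerous — are *withheld*: replaced
   by the mean tissue intensity and recorded. Extremely bright, sparse
   features would otherwise dominate the mean profiles; they are restored
   bit-exactly at the end. Ties at the cutoff break by scan order
   (column-major, R's native order), making the rule deterministic.
   "Fully saturated" is defined against a known detector ceiling (recorded
   automatically for 8/16-bit TIFFs); for float data with no ceiling only
   formerly-Inf pixels count, so a constant image withholds `ceil(0.01 N)`
   pixels, not all of them.

2. **Tissue isolation.** A disk-structuring-element texture filter
   (morphological closing then opening, disk radius 15 px by default)
   removes features smaller than the disk; Otsu thresholding of the
   texture map, boundary smoothing, hole filling and small-component
   removal yield the tissue mask. Two guards make this stage safe on
   images it was not designed for: the mask is honoured only if it covers
   at least `min_mask_coverage` of the frame *and* the excluded
   "background" is genuinely empty — its mean intensity at most
   `background_ratio_max` (default 0.2) of the tissue mean. A "background"
   only 2–3x dimmer than the tissue is usually the shaded part of the
   content itself, and masking it out would hide exactly the regions the
   correction must see; in that case every finite pixel is treated as
   tissue. On large mosaics tissue detection runs on a downsampled copy
   (texture is coarse; the stage otherwise dominates runtime) and the mask
   is upsampled back.

3. **Tile-grid detection.** Per-row and per-column mean intensity profiles
   are computed over tissue pixels only; positions with no tissue are
   excluded and linearly interpolated. Each profile is mean-detrended and
   Fourier transformed; searching upward from the lowest frequency, the
   first local maximum of the magnitude spectrum whose topographic
   prominence reaches 10% of the largest non-DC magnitude is taken as the
   tile frequency. Periods below `min_tile_period` (64 px) are excluded —
   those frequencies belong to tissue features, not tiling. The grid
   offset is the shift of the boundary comb that minimizes the mean
   profile value at boundary positions (boundaries sit at troughs). Rows
   and columns are detected independently, so rectangular tiles are
   supported.

4. **Envelope correction.** At the detected tile scale, profile extrema
   are found with an enforced minimum separation of 3/4 of a period,
   rejecting tissue-frequency wiggles. Half a period would be the obvious
   choice, but true same-kind extrema are a full period apart, and a
   half-period rule still admits ripple maxima sitting in the troughs
   (anywhere between P/2 and P from a real peak); 3/4 rejects those while
   keeping one peak per tile. Profile ends are handled by half-period
   reflection. Monotone shape-preserving cubics through the
   maxima and minima, smoothed with a moving average
   (`max(31, period/10)` px), form the upper and lower envelopes; their
   mean — the midline — is the model of the vignette-free profile. The
   correction multiplier is midline ÷ smoothed profile, so troughs are
   lifted onto the midline; its per-boundary peaks are constrained so
   that none exceeds the mean peak height (the vignetting effect is
   assumed consistent between tiles, so an outsized per-tile peak is not
   trusted; sub-mean peaks are left alone, since scaling a barely-above-1
   noise bump up to the mean would inflate it by an arbitrary factor) and
   the result is clipped to `[1/cap, cap]` (cap 5).
   The vertical (row-axis) multiplier is applied first; the horizontal
   multiplier is then derived from the *corrected* image and applied —
   the passes are sequential, not joint. Smoothing the denominator (with
   the same window as the envelope lines) keeps sampling noise in
   sparsely populated rows out of the multiplier while still tracking the
   tile-scale trough shape; a much wider window would round the trough
   and under-correct the seams. Positions with no tissue keep
   multiplier 1.

5. **Optional top-hat refinement.** If enabled, bright spots above the
   99th percentile are replaced by their 5×5 neighbourhood medians, the
   image is white-top-hat filtered with a disk (radius ≈ period/2) and a
   horizontal line (length ≈ period), and the ratio of the two top-hats
   forms a coarse flat baseline image. The ratio of baseline to current
   image is reduced to per-axis mean profiles over tissue, smoothed with a
   51-px moving average, normalized to mean 1 (only the shape matters; the
   global scale is meaningless and the final renormalization absorbs it),
   constrained like the envelope multipliers, and applied row-wise then
   column-wise. The stage is off by default: it is a finishing touch for
   dense tissue images and is ill-suited to sparse particle fields.
   Whether the residual multiplier should be a dense 2D field or two 1D
   profiles is genuinely open; the separable 1D form was chosen because
   the constraint machinery is 1D and the residual shading after the
   envelope passes is predominantly axis-aligned.

6. **Restoration.** The corrected image is mapped by a single global
   affine transform back into the original intensity range and the
   withheld pixels are restored bit-exactly. The affine anchors the
   minimum exactly and only *expands* the upper end toward the original
   range when the correction left the image narrower than the input:
   pixels the correction legitimately brightened are never compressed
   back. This anchor rule matters: a naive min/max affine is driven by
   single strongly-multiplied outlier pixels and can darken the whole
   image, while matching bulk quantiles of the original distribution
   statistically undoes the correction. With the chosen rule the identity
   correction round-trips bit-exactly, and the output's finite min/max
   always equal the input's because the withheld set contains the
   brightest original pixels and never the minimum.

## The synthetic mosaic generator

Since real stitched SRS mosaics cannot ship with the package, a simulator
provides ground-truthed test data emulating a stitched nanoparticle
calibration field:

* a `grid_n × grid_n` mosaic (default 5×5) of `tile_px²` tiles (default
  1024²);
* per tile, 30–50 particles of diameter 4–10 px placed uniformly at
  random, with intensity `u·diameter`, `u ~ U(0.5, 1)`, so larger
  particles are brighter (the law of `u` is the package's choice);
  overlapping particles combine by maximum;
* convolution with a truncated Gaussian PSF (square support of radius
  21 px, σ = 2 px, normalized to unit mass);
* additive zero-mean Gaussian noise at 1% of the image maximum, floored
  at 0;
* per-tile exponential vignette `gain = exp(−k·d/D)`, where `d` is the
  distance from the tile's vignette centre (tile centre plus an offset of
  `round(tile_px·(0.05, 0.03))` px — vignetting is rarely perfectly
  centred) and `D` is the tile half-diagonal; the same pattern is tiled
  across the mosaic, consistent with the between-tile consistency
  assumption above.

The stages run blur → noise → vignette, so the optical gain modulates the
noise floor as well as the signal. The decay default is `k = 2` (corner
gain `e⁻² ≈ 13.5%` of centre). This value was chosen as the weakest decay
under which a global-threshold particle detector visibly loses the shaded
margins — the regime the method is about. A much weaker vignette (`k ≲ 1`)
barely affects detection at all, because a global threshold adapts and
local SNR is unchanged.

Every stochastic stage derives its stream deterministically from the seed
(particles at `seed`, noise at `seed + 1`), so simulations are exactly
reproducible and individual stages are independently reproducible.

A second generator, `tissue_phantom()`, places non-overlapping textured
disks on an empty background with the support mask returned, for scoring
the tissue-masking stage exactly (optionally with a NaN border emulating
circular scan ROIs).

**What the simulator does not emulate:** real tissue morphology and its
spatial frequency content, focus variation between tiles, stitching seams
with blending, tile-to-tile illumination drift, and detector nonlinearity.
Passing tests on simulated mosaics therefore demonstrates correctness of
the mechanics (grid recovery, envelope extraction, renormalization
bookkeeping) and relative improvements under a known gain field — not
performance guarantees on arbitrary real slides.

## Evaluation metrics

`profile_flatness()` reports the coefficient of variation of the per-axis
tissue profiles and the mean absolute profile jump across tile boundaries
(±5 px). `detect_particles()` is a deliberately simple stand-in detector
(Otsu threshold → 8-connected components → minimum area 4 px → centroid,
equivalent diameter, total intensity); nanoscopy pipelines normally
deconvolve before detecting, which this package does not do, so only
*relative orderings* between vignetted, corrected and ground-truth images
are meaningful, not absolute counts. `tile_density_map()` folds particle positions modulo the tile
period into a `bins × bins` histogram normalized to sum 1 (32² default;
tests use 8² so each bin keeps a usable count at small scale), and
`compare_density_maps()` scores RMSE and Pearson correlation against the
ground-truth map. `histogram_components()` fits a k-component Gaussian
mixture (EM, via mclust) to the tissue intensity histogram and reports
equal-posterior thresholds between components, separating background,
shaded tile-edge pixels and bright tile-centre pixels.

## Numerical choices and degenerate inputs

* Morphology uses flat structuring elements (Euclidean disk: centre
  distance ≤ radius; lines rounded up to odd length) with
  shrink-at-border semantics, implemented as run-decomposed sliding
  min/max in C++ — results equal a brute-force min/max over in-bounds
  neighbours exactly, which the tests assert.
* The closing-then-opening order of the texture filter follows the
  detailed description of the procedure; the opposite order is exposed as
  an option because prose summaries of it conflict.
* Division guards: the multiplier denominator is floored at 5% of the
  midline; top-hat and divisor denominators at 5% of the median of their
  positive values. A constant image makes both top-hats vanish; the
  baseline is defined as 1 everywhere in that case.
* A constant profile has no spectrum and raises a no-periodicity error;
  a user-supplied period is the fallback. A constant corrected image
  renormalizes to the range minimum with a warning.
* Profiles are mean-detrended but not windowed before the FFT; at the
  profile lengths involved, leakage from the non-integer number of
  periods is far below the 10% prominence criterion.
* Withholding ties are broken by scan order; saturated counting needs a
  known ceiling (see above). Both rules exist so that the pipeline is a
  pure function of its inputs — identical input and configuration give
  bit-identical output, with no RNG anywhere in the correction path.

## Problem sizes used in the tests

The test suite exercises the full 5×5 grid of 1024² tiles once (grid
recovery on the reference simulation, about a minute) and otherwise uses
3×3 grids of 256² tiles, 20 random 64×64 images for the morphology
oracle, and 10⁴-point profiles for the envelope closed forms. The scaled
detection-ordering experiment supplies the simulation's known tile size
to the pipeline: a 3×3 grid offers only three periods per axis, too few
for reliable spectral detection, which is exercised separately at full
scale. These sizes keep the suite fast while leaving every code path
covered.

## Known limitations

* The correction is separable (sequential 1D row and column passes), so a
  radial per-tile gain is reduced but not eliminated in the tile corners;
  the optional top-hat refinement addresses part of the residual.
* Images whose only contrast *is* the vignette (featureless phantoms) are
  pathological for the final renormalization: the restored top-1% pixels
  all sit at tile centres and re-imprint a periodic pattern. Real images,
  whose bright pixels are feature-driven, do not show this.
* Absolute pixel intensities change by design; quantitative analyses that
  depend on them should be interpreted accordingly.
* Tile detection needs the whole image (the spectrum of a cropped section
  has a different fundamental), so the pipeline does not process images
  in sections.
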