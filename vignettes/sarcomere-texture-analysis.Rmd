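---
title: "Quantifying sarcomere organization with masked Haralick texture surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcomere organization with masked Haralick texture surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcotex)
```

## The problem

Fibroblasts can be directly reprogrammed toward cardiomyocyte-like cells, but
marker expression alone says little about whether a reprogrammed cell has
built the contractile machinery of a real cardiomyocyte. The visible evidence
of that machinery is the sarcomere: alpha-actinin-stained Z-lines appear as
periodic bright bands, roughly 1.8-2.2 um apart in cardiomyocytes, running
perpendicular to the myofibril axis. `sarcotex` turns multi-channel
immunofluorescence fields into a per-cell table of subtype calls, morphology,
and sarcomere-structure metrics, with no manual region selection.

## The texture model

The core statistic is built from the gray-level co-occurrence matrix (GLCM).
For a displacement vector $\mathbf{d}$, intensities inside the cell mask are
binned into $g$ equal-width bins ($g = 8$ by default, 2 for binary images)
over the in-mask min-max range, and $p(i,j)$ counts how often a pixel of bin
$i$ has a partner of bin $j$ at displacement $\mathbf{d}$ — with *both*
pixels required to lie in the mask, which is what frees the method from
bounding boxes and lets it handle arbitrary cell shapes. Accumulation is
symmetric (each pair counted in both directions).

From $p$ the package evaluates four Haralick features:

$$\mathrm{correlation} = \sum_{i,j}\frac{(i-\mu_i)(j-\mu_j)\,p(i,j)}{\sigma_i\sigma_j},
\qquad \mathrm{contrast} = \sum_{i,j}|i-j|^2\,p(i,j),$$
$$\mathrm{uniformity} = \sum_{i,j}p(i,j)^2,
\qquad \mathrm{homogeneity} = \sum_{i,j}\frac{p(i,j)}{1+|i-j|},$$

with $\mu$ and $\sigma$ the marginal means and standard deviations. A
*variance value* — the sum of contrast over the angle grid at unit offset —
serves as a cheap patternedness screen (zero for homogeneous regions).

The feature is computed over a grid of orientation angles
$\theta \in \{0°, 4°, \dots, 176°\}$ (the surface is 180°-periodic) and
offset distances $d \in \{1, \dots, 40\}$ px: the displacement
$d(-\sin\theta, \cos\theta)$ is rounded to the nearest integer pixel offset,
duplicates within an angle are computed once, and each value sits on the
offset axis at the Euclidean length of its rounded displacement. Each
per-angle trace is then linearly interpolated to 1/8-px resolution.
Striated texture produces a decaying oscillation along the trace of the
periodicity direction: pixels one period apart fall into the same bins again.

From the correlation surface the package extracts:

* **sarcomere organization** — the maximum topographic prominence over all
  interpolated traces. Prominence (height of a local maximum above its
  highest enclosing saddle) is baseline-free on a decaying trace, unlike raw
  peak height;
* **primary sarcomere direction** — the angle of that maximum. The reported
  angle is the axis along which intensity is periodic, i.e. the myofibril
  axis, perpendicular to the Z-line bands;
* **sarcomere length** — the offset of the peak times the pixel size;
* **cell-sarcomere misalignment** — the angle between the cell's major axis
  and the sarcomere direction, folded into [0°, 90°] because both are axial.

Length and direction are only reported when organization exceeds 0.1; below
that, peak positions reflect arbitrary intensity features, and lengths fall
far outside the plausible sarcomere range.

### Numerical choices

Three numerical decisions deserve explanation because they are where a naive
implementation goes wrong:

* **Linear, not spline, interpolation.** Cubic splines overshoot badly on the
  unevenly spaced deduplicated offsets, manufacturing prominences larger than
  the trace's actual swing. Piecewise-linear interpolation can never exceed
  the computed values.
* **Minimum pair count (`min_pairs = 300`).** The correlation estimate has
  standard error roughly $1/\sqrt{n_\text{pairs}}$. A compact mask at a large
  oblique offset can leave only a few dozen valid pairs, whose correlation is
  essentially random in $[-1, 1]$ and would dominate the prominence scan.
  Entries with fewer than 300 pairs are treated as missing (keeping the SE
  under about 0.06); missing entries never poison their neighbours.
* **Tie-breaking toward the shortest offset (`tie_tol = 0.02`).** On highly
  coherent periodic texture, an off-axis angle whose rounded offsets happen
  to land on the stripe lattice swings almost as hard as the true direction —
  but always with a stretched apparent period ($d = \text{period}/\cos\Delta\theta$),
  and harmonics of the true period tie at multiples of it. Among all peaks
  within 2% of the maximum prominence, the one at the smallest offset
  therefore identifies both the true direction and the fundamental period.
  On real, decaying traces the maximum is isolated and the rule is inert.
  When the winning peak is not the first peak of its trace (a harmonic won),
  the `length_is_first_peak` flag records it.

A caveat the phantom tests make explicit: for *infinitely coherent* stripes
(no noise, no lateral band offsets), texture is constant transverse to the
periodicity axis, so the GLCM value depends only on the displacement's
projection onto that axis and the orientation is fundamentally
near-unidentifiable at 4° resolution. Real sarcomeres have finite lateral
coherence; the orientation-recovery tests therefore use phantoms with modest
per-band jitter, which is also what the jittered panel of the phantom set
emulates.

## Segmentation

The segmentation stage mirrors a standard high-content design:

1. **Bleed-through correction.** Marker signal can bleed into the DAPI
   channel. A DAPI pixel is zeroed when the reference marker intensity
   (pixelwise max of Nppa and Hcn4) exceeds 1.5 times the DAPI intensity —
   i.e. when the apparent DAPI signal is marker-dominated. True nuclei
   (bright DAPI over dark markers) are never touched. Note the direction of
   the ratio: zeroing pixels with *high* DAPI-to-marker ratio instead would
   delete the nuclei of every marker-negative cell and could not remove
   marker bleed, which by construction has high marker relative to true
   DAPI.
2. **Nucleus detection.** Morphological closing (disc radius 3), Gaussian
   smoothing ("radius 4" is interpreted as kernel radius 4 px with
   $\sigma = 2$ px), Otsu threshold, removal of objects under 60 px.
3. **Marker classification.** Marker channels are smoothed and
   Otsu-binarized the same way; a nucleus *fully* inside a foreground is
   positive for that marker (strict by default; `coverage_frac` relaxes it).
   Otsu's threshold is scale-covariant, so classification is invariant to
   global intensity rescaling.
4. **Binucleate joining.** Same-class nuclei whose boundary-to-boundary
   distance is at most 25 px (3.91 um) are joined, transitively, into one
   cell group. Nppa status does not participate in the join.
5. **Perinuclear Nppa.** Each nucleus is scored in an annulus extending 8 px
   (1.25 um) from the nucleus edge (nucleus pixels excluded, clipped at the
   border); positive when the 90th-percentile ring intensity exceeds 0.1.
   The percentile uses linear interpolation between order statistics.
6. **Sequential-masking watershed.** Actinin-only cells are segmented on the
   actinin image with the Hcn4 foreground masked out, hcn4-only cells on the
   converse, and dual-positive cells on the combined image with the
   already-segmented regions masked out — so adjacent cells of different
   subtypes cannot merge. Within each pass, a seeded priority-flood
   watershed of the Sobel gradient magnitude (computed on a strongly
   smoothed image, $\sigma = 4$ px, so striation-scale edges do not raise
   interior barriers as tall as the cell border) assigns territory among the
   nucleus groups, and cell extent comes from the solidified Otsu foreground
   (closed with a 13-px disc and hole-filled, so sub-threshold stripe bands
   stay inside their cell). A foreground component seeded by exactly one
   group is that group's cell; components holding several groups are split
   along the watershed boundary. A background marker was deliberately not
   used: sub-threshold stripe bands open onto the background at the cell
   edge, and a background basin floods into them through those mouths,
   carving striated cells down to their bright bands.

Cells touching the image border are flagged (`on_border`) but kept:
morphology is unreliable there, and the caller should decide.

## Morphology

Area is the pixel count times the squared pixel size (0.15625 um/px by
default, from the 25 px = 3.91 um calibration). Axis lengths come from the
eigenvalues of the pixel-coordinate covariance, with the 1/12 unit-square
correction, matching the usual same-second-moments-ellipse convention;
eccentricity is focal distance over major axis, elongation the axis ratio.
Circularity is $4\pi A / P^2$. The perimeter estimator is the largest source
of small numeric disagreement between implementations: the package traces
the 8-connected contour and applies Kulpa's step weights (0.948 axial, 1.340
diagonal), which brings a rasterized disc within about 1% of circularity 1;
the estimator name is recorded in the output.

## Comparator metrics

Two previously proposed scores are implemented for head-to-head evaluation:

* **Gabor score** — a filter bank over 10 log-spaced wavelengths (4-32 px)
  and 16 orientations; per orientation, the in-mask mean response magnitude
  versus wavelength is fit to a quadratic plus Gaussian (quadratic because it
  tracks the long-wavelength background better than an exponential), and the
  score is the maximum Gaussian amplitude. Kernels are zero-DC and
  unit-energy so the aperiodic response does not scale with wavelength.
* **Fourier score** — the 2-D FFT of the cell's *bounding box* (this is the
  method's structural weakness: the box carries cell-shape artifacts), with
  the magnitude spectrum radially integrated over one-degree sectors into a
  frequency profile, normalized by annulus sample count, fit to two
  exponentials plus a Gaussian; the score is the Gaussian area. Annuli with
  fewer than 8 FFT samples are dropped as unaverageable.

Both fits use multi-start Levenberg-Marquardt (quantile centers plus the
profile argmax). Box constraints are avoided — they make the initial
Jacobian singular on these profiles — and replaced by reporting rules: a
negative fitted amplitude, a bump wider than half the support, or a center
outside the support count as "no periodic component". The fitted magnitude
spectrum is used rather than power; this is configurable.

## The synthetic-data generators

`make_stripes()` produces idealized striation: rectangular bands (hard edges
smoothed by a 1-px Gaussian; a sinusoidal profile is available) of known
period, direction, duty cycle (0.5 by default), additive Gaussian noise
(clipped to [0,1]), partial coverage contiguous along the periodic axis, and
random per-band lateral offsets. Default band intensities are 0.85/0.15 —
the source figures show hard-edged bands but state no contrast, so these are
parameters, not claims. `make_stripe_panels()` fixes the six canonical
variants (plain, rotated, longer period, noisy, one-third coverage,
jittered).

`make_cell_field()` renders a full multi-channel field: wobbled-ellipse cells
(semi-axes ~30-42 x 16-26 px — with the default pixel size, areas of roughly
35-80 um^2, a scaled-down but shape-realistic cell), one or two DAPI nucleus
blobs (binucleate centers 22 px apart, under the 25-px join radius but far
enough that closing does not merge the blobs), striped actinin texture of
known period and orientation, flat Hcn4 fill, a perinuclear Nppa annulus,
and optional marker-into-DAPI bleed. The truth table carries every
generating parameter including the exact cell masks, so segmentation is
scored against ground truth rather than against another segmentation.

`make_discrimination_set()` builds the benchmark fixture: 20 organized
phantoms (periods 10-16 px, random orientation, mild noise and jitter) and
20 disorganized ones (smoothed white noise with matched intensity
statistics), both groups under a random per-image gain and offset that
emulates staining variability — deliberately penalizing metrics that are not
normalized to image contrast, as raw contrast is not.

What these generators do *not* emulate: point-spread blur, shot noise,
chromatic aberration beyond the single bleed-through scalar, out-of-focus
structure, myofibril curvature, or touching cells with ambiguous borders.
Passing the packaged tests therefore demonstrates correctness of the
algorithms under controlled conditions, not field performance on real
micrographs.

## Problem sizes and defaults

The packaged tests and the acceptance script run phantoms at 128 x 128 px,
cell fields at 512 x 512 px with 10 cells, and the benchmark at 20 + 20
phantoms — sizes chosen so the whole suite completes in minutes on one core
while every grid (45 angles x 40 offsets) stays at its full default
resolution. All thresholds (bleed ratio 1.5, Nppa threshold 0.1 at ring 8
px, join radius 25 px, organization threshold 0.1, 8 gray levels) default to
the published calibration and are configurable through `pipeline_config()`.

## Known limitations

* Orientation on noiseless, perfectly coherent stripes is reported only up to
  the lattice-aliasing ambiguity discussed above.
* The organization threshold of 0.1 was calibrated on full-scale cells;
  compact masks (a few thousand pixels) of pure noise can score up to ~0.15
  because fewer pairs enter each estimate, so borderline scores near the
  threshold deserve skepticism — consistent with the observation that
  low-organization cells yield lengths outside the plausible range.
* Sarcomere length reports the offset of the most prominent peak; on
  strongly coherent texture a harmonic can win (flagged via
  `length_is_first_peak`).
* The pipeline is 2-D; z-stacks must be projected upstream.
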