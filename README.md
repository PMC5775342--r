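# sarcotex

Automated high-content analysis of multi-channel immunofluorescence images
of cardiomyocytes and reprogrammed cardiac-like myocytes. Reprogramming
protocols are usually scored by marker induction, but marker-positive cells
often lack the contractile architecture of real cardiomyocytes; `sarcotex`
quantifies that architecture directly from images, per cell, with no manual
region selection.

The package provides:

* **Segmentation & subtype classification** — DAPI bleed-through correction,
  nucleus detection (closing + Gaussian smoothing + Otsu), strict
  fully-within marker classification against the alpha-actinin and Hcn4-GFP
  foregrounds, perinuclear-ring Nppa scoring, binucleate joining (same-class
  nuclei within 25 px), and sequential-masking marker-controlled watershed
  cell segmentation (actinin-only, hcn4-only, then dual-positive cells).
* **Morphology** — area (um^2), elongation, circularity
  `4 * pi * A / P^2`, eccentricity of the same-second-moments ellipse, and
  major-axis orientation.
* **SarcOmere Texture Analysis (SOTA)** — the core method. A gray-level
  co-occurrence matrix is computed inside the cell mask for every
  orientation (0-176 degrees in 4-degree steps) and pixel offset (1-40 px), a
  Haralick feature is evaluated on each —

  correlation = sum_ij (i - mu_i)(j - mu_j) p(i,j) / (sigma_i sigma_j)

  — and each per-angle trace is interpolated to sub-pixel resolution.
  Striations produce a decaying oscillation along the myofibril axis; the
  maximum peak prominence over all traces is the **sarcomere organization**,
  its angle the **primary sarcomere direction**, its offset times the pixel
  size the **sarcomere length**, and the angle between sarcomere direction
  and the cell's major axis the **cell-sarcomere misalignment**. Length and
  direction are reported only when organization exceeds 0.1.
* **Comparator metrics** — Gabor-filter periodic-component score and 2-D FFT
  radial-profile score, plus a benchmark (`compare_organization_metrics()`)
  that reproduces the metric comparison on labeled phantom sets.
* **Synthetic generators** — stripe phantoms with known period, orientation,
  duty, noise, coverage, and band jitter; multi-channel cell fields with
  exhaustive ground truth (flags, masks, nucleus centers, stripe geometry).
  Every algorithm in the package is testable without a single real
  micrograph.

## A worked example

Score an idealized striation image of known geometry — period 12.8 px at the
default scale of 0.15625 um/px, i.e. a 2.0 um sarcomere, oriented at
30 degrees:

```r
library(sarcotex)

ph <- make_stripes(c(128, 128), period_px = 12.8, orientation_deg = 30,
                   jitter_sd = 1, seed = 42)
sota_metrics(ph$image, pixel_size_um = 0.15625)
#>   organization length_um direction_deg length_px length_is_first_peak n_peaks
#> 1        1.938     1.953            28      12.5                 TRUE     200
```

The recovered length (1.95 um) matches the generated 2.0-um period to within
the half-pixel discretization of the offset grid, and the direction (28
degrees) is within one 4-degree grid step of the generated 30. An
organization of 1.94 is near the theoretical ceiling of 2 (a correlation
trace swinging the full [-1, 1] range); real cells score far lower.

The full pipeline on a synthetic 10-cell field:

```r
field <- make_cell_field(seed = 1)
run <- run_pipeline(field$stack, pipeline_config())
subtype_tally(run)
#>   subtype               n
#> 1 actinin               3
#> 2 actinin+hcn4          2
#> 3 actinin+hcn4+nppa     2
#> 4 actinin+nppa          1
#> 5 hcn4                  2
```

The tally equals the generator's flag table exactly, and the striped
(actinin-positive) cells report sarcomere lengths of 1.99-2.05 um against
the generated 2.0-um texture. `run$cells` is a tibble with one row per cell
(subtype, nucleus count, morphology, sarcomere metrics, misalignment);
`autoplot(surface)` and `plot_surface_traces(surface)` visualize a
`haralick_surface`, and `tidy()`/`glance()` methods give long-format and
one-row summaries.

A command-line front end with `run`, `segment`, `sota`, `baselines`,
`fixtures`, and `compare` subcommands is installed under
`inst/cli/sarcotex.R`.

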