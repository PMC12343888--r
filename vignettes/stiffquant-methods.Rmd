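---
title: "stiffquant: models, pipeline and parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stiffquant: models, pipeline and parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the quantitative models implemented by
`stiffquant`, the image-processing pipeline step by step, every tunable
parameter with its units and default, what the synthetic-scene generators
do and do not emulate, and the numerical conventions used throughout.

## 1. Biological models

### 1.1 Receptor internalization

A membrane-resident receptor is imaged at cell–cell junctions. After
ligand stimulation at `t = 0`, a mobile fraction `f_int` of the membrane
pool internalizes with first-order rate `k_int` (min⁻¹), so the membrane
fluorescence fold change relative to `t = 0` is

```
F(t) = (1 - f_int) + f_int * exp(-k_int * t)
```

Conservation holds: the signal lost from the membrane reappears as
endosomal puncta, scaled by a transfer efficiency. The scalar summary of a
time course is the trapezoidal area under the fold-change curve
(`auc_trapezoid()`); for a sampling window of 0–30 min, a non-internalizing
field (`k_int = 0`) has AUC exactly 30, and any internalization lowers it.
`internalization_series()` produces both the per-frame table (membrane
intensity, fold change, puncta count and intensity, background) and the
AUC.

### 1.2 Kinase translocation reporters

A KTR leaves the nucleus when its kinase is active. Single-cell activity
is the log2 cytoplasm-to-nucleus ratio of the reporter's median
intensities ("log2 CNR", `compute_cnr()`). A step of kinase activity with
amplitude `A` (log2 units) and time constant `tau` (min) after stimulus at
`t_stim` gives the designed trace

```
delta_log2_cnr(t) = A * (1 - exp(-(t - t_stim) / tau)),   t >= t_stim
```

Traces are normalized by subtracting each cell's value at the last
pre-stimulus frame (`normalize_traces()`), so the baseline delta is
exactly zero by construction, and summarized per frame across the
population as mean, sd and standard error (`summarize_population()`). A
plateau estimate should average per-frame means only over frames with
elapsed post-stimulus time of several time constants (≥ 5·tau leaves an
exponential shortfall below 0.7% of `A`).

### 1.3 Endpoint assays

- **Wound closure.** Cell-covered regions have high local intensity
  texture; the wound is the pixel set whose local standard deviation falls
  below a threshold (`wound_area()`). Closure percent is
  `100 * (1 - area_t / area_0)` (`wound_closure()`).
- **Laurdan generalized polarization.** Per pixel,
  `GP = (I_ordered - I_disordered) / (I_ordered + I_disordered)`, averaged
  over a cell mask (`laurdan_gp()`). GP is bounded in [-1, 1] and
  insensitive to total intensity, which is why it survives multiplicative
  noise well.
- **Flow cytometry.** Percent positive is the fraction of stained events
  strictly above the 99th percentile (type-7 quantile) of the isotype
  control (`flow_percent_positive()`). Gating the isotype against itself
  therefore yields ≈ 1% by construction — a built-in calibration check.

## 2. Image-processing pipeline

`internalization_series()` applies, per frame:

1. **Maximum-intensity projection** over z (`max_project()`).
2. **Median denoising** (`median_denoise()`, window `denoise_median_px`).
   Implemented in-package as an exact sorting network over shifted,
   border-replicated copies of the image — vectorized, no quantization,
   works on any intensity range.
3. **Background estimation** (`estimate_background()`): an Otsu split of
   the intensity histogram separates background from foreground; the
   background level is the median of the lower class. The split threshold
   is returned as an attribute.
4. **Divisive normalization** (`normalize_to_background()`): intensities
   divided by the background level, so the background maps to 1 regardless
   of lamp intensity or exposure.
5. **Adaptive thresholding** (`adaptive_threshold()`): a pixel is
   foreground when it exceeds its local box mean (window
   `threshold_block_px`) by more than `threshold_offset`. Local
   thresholding tolerates smooth illumination gradients that defeat a
   global threshold.
6. **Object classification** (`classify_objects()`): connected components
   are labelled and classified by area and circularity
   (`4π·area / perimeter²`, perimeter by marching squares):
   - *puncta*: small (area in `[punctum_area_min, punctum_area_max]`),
     round (circularity ≥ `punctum_min_circularity`);
   - *membrane*: large (area ≥ `membrane_min_area`), elongated
     (circularity ≤ `membrane_max_circularity`);
   - everything else is discarded.

   A **detection-significance filter** then removes noise-born
   candidates. For each component of area `A`, the summed residual above
   the local mean is compared against what threshold-selected noise alone
   would produce: the component is kept iff

   ```
   sum(residual - threshold_offset) > detection_min_z * sigma * sqrt(A)
   ```

   where `residual = img - box_mean(img)` and `sigma` is the robust (MAD)
   noise scale of off-object residuals. Subtracting `threshold_offset`
   inside the sum is essential: every pixel in a candidate already exceeds
   the local mean by the offset *because it was selected by the
   threshold*, so testing the raw sum would be biased in favor of noise
   clumps. On noiseless images `sigma = 0` and the filter passes
   everything.
7. **Quantification** (`quantify_segmentation()`,
   `percent_membrane_fluorescence()`): background-subtracted integrated
   intensity per class; percent membrane is
   `100 * membrane / (membrane + puncta)`.

The KTR pipeline (`ktr_cnr_table()`) segments nuclei from the H2B channel
by Otsu threshold plus distance-transform watershed to split touching
nuclei (`segment_nuclei()`), samples cytoplasm in an annulus around each
nucleus that starts `ring_gap_px` outside the nucleus, is `ring_width_px`
wide, and excludes pixels closer to any other nucleus
(`cytoplasm_ring()`), links cells across frames by nearest-centroid
matching within `track_max_displacement_px` (`track_cells()`), and
computes per-cell, per-channel log2 CNR.

## 3. Parameters

All parameters live in `default_config()` and can be overridden from YAML
with `load_config()`, which rejects unknown keys and validates ranges.

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `denoise_median_px` | 3 | px | Smallest odd median window; removes single-pixel noise excursions while moving object edges by at most one pixel. 0 disables. |
| `threshold_block_px` | 51 | px | Local-mean window; larger than any object of interest (membrane ridges are ~3 px wide, puncta ≤ ~16 px across) so objects do not inflate their own local mean, yet small enough to track illumination gradients. |
| `threshold_offset` | 1.0 | normalized intensity | One background-unit above the local mean; after divisive normalization the background sits at 1, so foreground must be ≈ 2× local background. |
| `detection_min_z` | 5 | z-score | Conventional discovery threshold; with the selection-floor correction above, genuine objects exceed it by orders of magnitude while threshold-selected noise clumps fall below it. 0 disables. |
| `punctum_area_min` / `punctum_area_max` | 4 / 200 | px | Diffraction-limited endosomes at ~0.65 µm/px span a few to tens of pixels; the upper bound excludes merged blobs. |
| `punctum_min_circularity` | 0.6 | — | Rasterized disks score 0.74–0.84 under the marching-squares perimeter; 0.6 keeps them with margin while rejecting elongated fragments. |
| `membrane_min_area` | 500 | px | Junction ridges are long; this excludes any object that could also be a punctum (validated: must exceed `punctum_area_max`). |
| `membrane_max_circularity` | 0.3 | — | Thin bars score ≈ 0.08–0.15; 0.3 rejects compact shapes. |
| `nucleus_min_area_px` | 50 | px | Debris filter below any plausible nucleus at 0.65 µm/px. |
| `watershed_tolerance` | 1.0 | distance units | Minimum basin-depth separation when splitting touching nuclei. |
| `ring_gap_px` / `ring_width_px` | 1 / 4 | px | Gap avoids nuclear-edge bleed-through; a 4-px ring samples perinuclear cytoplasm without reaching neighbors. |
| `track_max_displacement_px` | 10 | px/frame | Adherent cells move little between 2-min frames; larger jumps start a new track rather than mislink. |
| `baseline_frame` | 6 | frame index | Last pre-stimulus frame used for trace normalization. |
| `texture_window_px` | 9 | px | Local-sd window for wound detection; spans several cell-texture periods. |
| `texture_sd_threshold` | 20 | intensity | Cell texture sd is well above, wound-floor noise well below. |
| `flow_gate_quantile` | 0.99 | — | Isotype gate; self-gating then reads ≈ 1% by construction. |
| `pixel_size_um` | 0.65 | µm/px | Typical 10× camera sampling; used for unit conversions only. |
| `bit_depth` | 16 | bits | Camera ADC depth assumed when writing integer TIFFs. |

## 4. Synthetic scenes and ground truth

The generators exist so every pipeline stage can be tested by *parameter
recovery* against known ground truth, not by visual inspection.

- `make_cell_field()` builds a colony of Voronoi-like cells with 3-px
  junction ridges, returning the label image, junction mask and designed
  geometry.
- `simulate_internalization()` renders a time series from a cell field
  under the exponential model of §1.1, with signal conservation into
  puncta, plus additive Gaussian noise (and optional Poisson scaling).
  SNR here means ridge amplitude over Gaussian sd (e.g. amplitude 300,
  sd 60 → SNR 5).
- `simulate_ktr()` renders an H2B channel and two reporter channels whose
  pixel intensities obey reporter-number conservation between nuclear and
  cytoplasmic compartments, with per-frame multiplicative noise and slow
  shared drift.
- `simulate_wound()`, `simulate_laurdan()`, `simulate_flow()` produce the
  endpoint inputs with exact designed answers (closure fraction, GP,
  fraction positive).

All generators take a `seed` and restore the caller's RNG state. Ground
truth is written/read as JSON (`write_ground_truth()` /
`read_ground_truth()`) with integer matrices round-tripping exactly.

What the generators do **not** emulate: optics (no point-spread-function
blur), camera gain/offset maps, photobleaching, cell division or death,
out-of-focus light, or spatially correlated noise. They are accuracy
fixtures for the measurement code, not a microscope simulator. Problem
sizes used in the tests and analysis scripts (field sizes, cell counts,
frame counts) are the package's own choices, picked to finish quickly on
one CPU while leaving each estimator enough statistics.

## 5. Numerical conventions

- **TIFF storage.** `write_stack()` stores non-negative integer data
  within 16-bit range as `uint16`, anything else as 32-bit IEEE floats, so
  round trips are exact for both label masks and continuous intensities.
  Multi-dimensional stacks carry their axis order in the ImageDescription
  tag; ambiguous multi-page files without metadata are refused rather than
  guessed.
- **Local statistics.** `box_mean()`/`box_sd()` use summed-area tables;
  `box_sd()` is the *population* standard deviation (divide by n), the
  natural choice for a sliding texture statistic.
- **Perimeter.** Circularity uses a marching-squares contour length, which
  is far less biased than pixel-edge counting (a rasterized disk scores
  ≈ 0.8 rather than ≈ 0.6).
- **Otsu split.** The histogram is accumulated in doubles; integer
  accumulation overflows 2³¹ on megapixel images.
- **Statistics.** `t_test_two_sample()` (pooled and Welch) and
  `anova_oneway_tukey()` match `stats::t.test()`/`stats::aov()` to
  floating-point accuracy and are property-tested against hand arithmetic.
- **Determinism.** Every stochastic function takes an explicit seed and
  restores the RNG state on exit; identical configuration plus seed yields
  byte-identical outputs.

## 6. Limitations

- Shape classification assumes junctional membrane signal forms elongated
  ridges; isolated cells with unapposed membrane would be under-counted.
- Nearest-centroid tracking has no motion model and will fragment tracks
  of fast-moving cells rather than guess.
- The wound-texture detector assumes the wound floor is darker *and*
  smoother than the monolayer; debris inside the wound inflates closure
  estimates.
- Noise-significance filtering assumes approximately stationary Gaussian
  noise; strongly structured background would require a different null.
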