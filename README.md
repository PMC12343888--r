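# stiffquant

Quantification of substrate-stiffness effects on receptor membrane
localization and kinase-reporter dynamics in fluorescence microscopy.

## Scientific background

Adherent cancer cells sense the mechanical stiffness of their substrate,
and that mechanical cue feeds back on receptor trafficking and downstream
kinase signaling. Two observable consequences motivate this package:

- **Receptor internalization.** A chemokine receptor resident on the plasma
  membrane appears in junctional "ridges" where neighboring cells meet. On a
  stiff substrate, ligand stimulation drives a mobile fraction of the
  receptor off the membrane into endosomal puncta, so membrane fluorescence
  decays over minutes while punctate cytoplasmic fluorescence rises. On a
  soft substrate the receptor stays put. The membrane signal follows a
  single-exponential internalization model: a fraction `f_int` of the
  membrane pool internalizes with rate `k_int` (per minute), so the
  membrane fold change at time *t* is
  `(1 - f_int) + f_int * exp(-k_int * t)`. The fold-change time course and
  its trapezoidal area under the curve (AUC) summarize each imaged field;
  stiff and soft conditions are then compared with a two-sample *t* test.
- **Kinase translocation reporters (KTRs).** Fluorescent reporters for Akt
  and ERK shuttle between nucleus and cytoplasm as the kinase turns on, so
  single-cell activity is read out as the log2 cytoplasm-to-nucleus
  intensity ratio (log2 CNR). The pipeline segments nuclei from an H2B
  channel, samples cytoplasm in a ring around each nucleus, tracks cells
  through a time lapse, normalizes each trace to its pre-stimulus baseline,
  and summarizes the population response per reporter.

The package also computes three scalar endpoint assays that accompany such
experiments: scratch-wound closure percentage from texture-based wound
masks, laurdan generalized polarization (GP) for membrane order, and
flow-cytometry percent positive above an isotype 99th-percentile gate.

Every stage is verifiable: a synthetic-scene generator produces TIFF
stacks with full ground truth (label images, membrane masks, designed
kinetic parameters), so segmentation and quantification can be tested by
parameter recovery rather than by eye.

## Worked example

Simulate one stiff-substrate field of 12 cells imaged at 0, 15 and 30
minutes (designed kinetics `f_int = 0.6`, `k_int = 0.1`/min, Gaussian
noise sd 5 on an interior intensity of ~100), then quantify it with the
standard pipeline (max projection, 3×3 median denoise, background
estimation and division, adaptive thresholding, shape-based object
classification):

```r
library(stiffquant)

cfg <- default_config()
cf  <- make_cell_field(n_cells = 12, field_size = 256, seed = 7)
sim <- simulate_internalization(cf, timestamps_min = c(0, 15, 30),
                                f_int = 0.6, k_int = 0.1,
                                noise = list(gaussian_sd = 5, poisson_scale = 0),
                                seed = 507)
res <- internalization_series(sim$stack, cfg)
res$frames
#>   t_min membrane_intensity fold_change puncta_count puncta_intensity background
#> 1     0          11480.948   1.0000000            0            0.000   51.17214
#> 2    15           6075.345   0.5291675           25         4621.677   51.15213
#> 3    30           4850.365   0.4224708           25         5530.896   51.24253
res$auc
#> [1] 18.60617
```

The measured fold changes track the designed model closely: at 15 min the
model predicts `0.4 + 0.6 * exp(-1.5) = 0.534` (measured 0.529), and at
30 min `0.4 + 0.6 * exp(-3) = 0.430` (measured 0.422). All 25 designed
endosomal puncta are detected at both post-stimulus timepoints.

Running the full workflow (`analysis/` scripts, below) over ten stiff and
ten soft fields gives mean fold-change AUCs of **18.63 (stiff)** versus
**30.01 (soft)** — the soft condition sits at the no-internalization value
of 30 for a 30-minute window — with a two-sample *t* test *p* ≈ 1e-45.
The KTR time lapse of 25 cells ends at a mean delta log2 CNR of 0.478
(Akt) and 0.495 (ERK) at 70 min; the endpoint assays recover wound
closure 75%, mean laurdan GP 0.301 over 10,428 cell pixels, and 42.6%
flow-positive events.

## Repository layout

- `R/` — the package: TIFF/stack I/O, YAML configuration, preprocessing,
  segmentation and classification, internalization quantification, KTR
  dynamics, endpoint assays, statistics, and the synthetic-scene
  generators.
- `analysis/` — numbered driver scripts that run the full workflow on
  simulated scenes, in order:
  1. `01_simulate_scenes.R` — writes receptor fields, a KTR time lapse and
     endpoint-assay inputs under `results/scenes/`.
  2. `02_receptor_internalization.R` — per-frame membrane/puncta tables
     and per-scene AUC.
  3. `03_ktr_dynamics.R` — single-cell traces and population summaries.
  4. `04_endpoint_assays.R` — wound closure, laurdan GP, flow percent
     positive.
  5. `05_statistics.R` — stiff-vs-soft *t* test; ANOVA with Tukey pairwise
     comparisons across timepoints.
- `tests/testthat/` — the test suite.
- `vignettes/` — a methods vignette describing the models, the pipeline
  and every tunable parameter.

Run the workflow from the repository root after installing the package:

```sh
Rscript analysis/01_simulate_scenes.R
Rscript analysis/02_receptor_internalization.R
Rscript analysis/03_ktr_dynamics.R
Rscript analysis/04_endpoint_assays.R
Rscript analysis/05_statistics.R
```

Outputs land under `results/` (gitignored).

## Configuration

All tunable parameters live in a single validated configuration object
(`default_config()`), overridable from YAML via `load_config("config.yaml")`.
See the methods vignette for each parameter's meaning, units and default.

## License

MIT (see `LICENSE`).
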