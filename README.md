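# hemoflow

Automated blood-flow velocimetry and blood-cell counting for high-frame-rate
brightfield video of fish-embryo vasculature.

Transparent zebrafish and medaka embryos let you film the blood streaming
through the dorsal aorta with nothing more than a brightfield microscope and a
high-speed camera (typically 200 fps, ~10 s, with a known µm-per-pixel
calibration). hemoflow turns such a recording into physiology, fully
automatically:

1. **Stabilization** — inter-frame rigid Euclidean transforms (FFT phase
   correlation + Gauss–Newton refinement, golden-section rotation search),
   cumulative trajectory smoothed by a sliding window, frames warped by the
   residual.
2. **Vessel ROI** — a motion-energy mask from the time-averaged dense flow
   (coherent vector averaging), largest-contour bounding rectangle; or a
   manual rectangle.
3. **Dense optical flow** — per-pixel quadratic (polynomial) expansion
   `I(x) ≈ xᵀAx + bᵀx + c`; under translation `d` the linear coefficients obey
   `b₂ = b₁ − 2Ad`, solved per pixel with Gaussian-window-averaged normal
   equations, coarse-to-fine on an image pyramid. Written from first
   principles; an exhaustive block-matching estimator ships as an independent
   cross-check.
4. **Velocity trace** — median flow magnitude over moving ROI pixels per
   frame pair, converted to µm/s on the *acquisition* time base, Hampel
   despiked, Savitzky–Golay smoothed, QC-flagged against a species velocity
   band (zebrafish dorsal aorta: 0.3–1.5 mm/s; flagged, never clamped).
5. **Cell counting** — adaptive dark-mode thresholding, Suzuki–Abe-style
   border-following contours with area bounds and an unbiased counting-frame
   edge rule; per-second flux from the line-crossing model
   `rows × speed / pitch × fps` with the geometry estimated from the masks.
6. **Batch output** — per-video `*_velocity.csv`, `*_cells.csv`, two-panel
   oscillation PNGs, a combined `summary.csv`, and the resolved run config;
   re-runs are byte-identical.

A synthetic vessel-video generator with exact ground truth (speed, per-frame
counts, line-crossing flux, vessel rectangle, injected camera jitter) is a
first-class part of the package and the basis of its verification suite.

## Worked example

```r
library(hemoflow)

# a synthetic dorsal-aorta scene: 400 µm/s, 48 cells in frame, 200 cells/s
sim <- synthetic_vessel_clip(vessel_scene_params(n_frames = 30, seed = 42))
res <- analyze_clip(sim$clip, options = pipeline_options(stabilize = FALSE))
res
#> <flow_analysis>
#> <velocity_trace> 29 samples | mean 455.6 um/s | sd 236.1 | 1 QC-flagged
#> <cell_count_result> avg 47 cells/frame | 201 cells/s | 3 rows, cell width 8.96 px
#> <roi_rect> x0=0 y0=24 width=192 height=47

glance(res)[, 1:5]
#> # A tibble: 1 × 5
#>   video mean_velocity_um_s sd_velocity_um_s avg_cells_per_frame cells_per_second
#> 1 clip                400.            0.553                  47             201.
```

The raw trace mean (455.6 µm/s) is inflated by one aliased frame pair — the
sample the QC flag points at; the despiked, smoothed summary recovers the true
400 µm/s to 0.1 %, counts 47 of the 48 cells actually in frame, and estimates
the flux at 201 against a true line-crossing rate of 200 cells/s. `tidy(res)`
returns the per-frame table, `autoplot(res)` the two-panel velocity/count
oscillation figure.

Batch processing a folder of frame-directory videos:

```r
run_batch("videos/", "results/", acquisition_fps = 200, um_per_px = 0.5)
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/hemoflow.R run --input videos/ --output results/ \
    --fps 200 --um-per-px 0.5 --species zebrafish
Rscript inst/cli/hemoflow.R simulate --speed-um-s 400 --n-frames 60 --seed 7 --out sim1/
```

See `vignette("velocimetry-methods")` for the models, parameter rationale and
limitations.

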