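---
title: "Measuring embryonic blood flow from brightfield video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring embryonic blood flow from brightfield video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow)
```

## The measurement problem

Fish embryos (zebrafish, medaka) are transparent, so the blood streaming
through the dorsal aorta can be filmed directly with an ordinary brightfield
microscope and a high-speed camera — typically 200 frames per second for about
ten seconds of trunk recording at a known micrometers-per-pixel scale. Two
physiological quantities are wanted from such a clip:

* the **blood flow velocity**, in µm/s, averaged over the recording, and
* the **blood cell count**, both the number visible per frame and the flux in
  cells per second crossing the vessel.

hemoflow computes both fully automatically: stabilize → locate the vessel →
dense optical flow → physical-unit velocity trace → cell segmentation and
counting → summary tables and oscillation figures. This vignette explains each
model, its assumptions, the tunable parameters, and the design decisions that
were genuinely open.

## Video carrier and time bases

A `video_clip` holds grayscale frames in `[0, 1]` plus **two** frame rates.
The *acquisition* rate is the physical time base (what the camera saw); the
*playback* rate is presentational. High-speed recordings are commonly
re-exported at 30 fps for visual inspection — a 200 fps, 10 s recording then
plays for 2000/30 ≈ 66.7 s, a 200/30 ≈ 6.67-fold slow-motion effect.
`relabel_playback()` implements exactly this relabelling without touching the
frames, and every velocity computation in the package uses `acquisition_fps`
only: using playback time would bias all velocities by the slowdown factor.
RGB sources are converted once with fixed Rec. 601 luma weights, recorded in
the clip's JSON sidecar, so ingest is deterministic. The lossless on-disk
dialect is a directory of numbered 16-bit TIFFs; codec containers must be
exploded to frames first, because codec decoders are not bit-reproducible
across builds.

## Stabilization

Embryos twitch and rigs vibrate. The stabilizer models inter-frame camera
motion as a **rigid Euclidean transform** (translation + rotation, no scale):
anything richer, such as an affine fit, would absorb part of the biological
motion we are trying to measure. Translation is estimated by FFT phase
correlation on Hann-windowed frames with parabolic sub-pixel refinement,
followed by a two-step Gauss–Newton photometric refinement (the parabolic peak
fit alone carries a sub-pixel bias of up to ~0.2 px on smooth textures);
rotation by a golden-section search over the de-rotation angle that maximizes
the correlation peak. The cumulative trajectory is smoothed with a centered
moving average (truncated at the ends; window 1 = identity) and each frame is
warped by the smoothed-minus-raw residual with replicate-border bilinear
sampling — cropping is deliberately avoided so ROI coordinates stay valid
across the pipeline.

Camera motion must be read off the **static anatomy**. On a trunk recording
whose center is dominated by the flowing blood column, a whole-frame
estimator happily tracks the blood itself (its cumulative "camera" trajectory
then ramps at exactly the cell speed). Two defenses are built in: the
Gauss–Newton refinement only uses photometric inliers (residuals within three
robust SDs, which drops independently moving cells), and the full pipeline
first locates the vessel on the raw clip and passes its rows to `stabilize()`
as `exclude_rows` — translations survive row deletion exactly, so estimation
simply runs on the remaining rows (rotation search is disabled in that mode;
specimen jitter is predominantly translational).

The default window of 15 frames is ≈ 75 ms at 200 fps: longer than
frame-to-frame jitter, shorter than cardiac-cycle-scale signal. For
independent zero-mean jitter the residual inter-frame displacement of an
*n*-frame moving average falls like 1/*n*, so a 15-frame window removes
≈ 93 % of injected jitter; the package's tests verify ≥ 90 % on 256×256
textured scenes with up to 5 px jitter.

## Dense optical flow by polynomial expansion

The flow engine is written from first principles. Each frame is approximated
per pixel by a local quadratic
$I(\mathbf{x} + \mathbf{e}) \approx \mathbf{e}^\top A \mathbf{e} +
\mathbf{b}^\top \mathbf{e} + c$
over a `poly_n` × `poly_n` neighborhood with separable Gaussian applicability
weights of width `poly_sigma` (local coordinates, x = columns rightward,
y = rows downward). Because the weights are fixed, the normal-equation matrix
is identical at every pixel, and the whole expansion reduces to six separable
correlations plus a constant linear solve — this is what makes dense flow
affordable in pure R.

If the scene translates by $\mathbf{d}$, the two expansions satisfy
$\mathbf{b}_2 = \mathbf{b}_1 - 2A\mathbf{d}$, so
$\mathbf{d} = -\tfrac{1}{2} A^{-1} (\mathbf{b}_2 - \mathbf{b}_1)$
with $A = (A_1 + A_2)/2$. The sign convention matters: the subtraction order
in the displacement solve must be consistent with the expansion relation, and
the package pins it with an analytic test — two samples of the same global
quadratic offset by (0.6, −0.4) px must yield that displacement to within
0.05 px, which only the stated sign satisfies. Per pixel, the normal
equations $G = A^\top A$, $h = A^\top \Delta b$ are averaged over a Gaussian
window (side `window`, σ = (window−1)/4) before solving; this regularizes
flat regions, which inherit the motion of their textured surroundings.
Pixels whose averaged $G$ has condition number above 10⁶ are marked invalid
and excluded from ROI statistics.

Large displacements are handled coarse-to-fine on a Gaussian pyramid with
iterative refinement, warping the second expansion by the running estimate.
Defaults: `pyramid_scale` 0.5, `pyramid_levels` 4, `window` 15,
`iterations` 3, `poly_n` 5, `poly_sigma` 1.1. Four levels (rather than the
three common in general-purpose implementations) keep the fastest
physiologically plausible motion — ~15 px/frame at the 0.5 µm/px, 200 fps
study scale, the top of the zebrafish QC band — within ≈ 2 px at the coarsest
level, inside the solver's convergence basin; the analysis crop is grown
automatically so the coarsest level never falls below 12 px.

Two failure modes of gradient-based flow on *dense, quasi-periodic* cell
columns deserve naming. First, a displacement close to the cell pitch is
genuinely ambiguous (shifting one pitch re-aligns the pattern); only per-cell
appearance variation breaks the tie, and the pyramid must be deep enough to
see it. Second, even then an occasional frame pair can lock onto the
neighboring period. The package therefore summarizes each pair by the
spatial **median** magnitude over moving pixels (robust to minority alias
populations) and passes the per-pair series through a Hampel despiking filter
(rolling median ± 5 robust SDs, half-window 3, with a 5 % relative floor on
the scale) before Savitzky–Golay smoothing. The Hampel step is data-driven
spike removal, not a physiological clamp: smooth pulsatile oscillation at
cardiac-cycle scale passes through unchanged, as the tests assert.

An exhaustive block-matching estimator (`block_match_shift`, integer search
plus parabolic refinement — correlation-PIV style) ships with the package as
an independent cross-check; the test suite requires the flow engine to agree
with it to a median endpoint error below 0.25 px over twenty random
sub-pixel translations.

## Finding the vessel

On a stabilized clip the only coherent motion is the blood column.
`motion_mask()` averages the flow across all consecutive pairs and
thresholds the magnitude of the time-averaged displacement **vector**:
incoherent sensor-noise flow rectifies under magnitude averaging (which
would flood the mask) but cancels under vector averaging. Detection uses
single-level flow — the mask needs to know *where* motion is, not how fast
it is, and deeper pyramids smear the coarse estimate far beyond the vessel.
The support cut is `max(0.2 px/frame, half of the 95th-percentile averaged
motion)`, i.e. the flow's full-width-at-half-maximum support; the mask is
then closed (3×3), opened (3×3) to detach speckle chains, and eroded by the
averaging window's ~1 σ support dilation. `auto_roi()` takes the
largest-area contour of the mask, trims its bounding box to rows/columns
with at least 20 % of peak coverage (a stray blob that happens to touch the
vessel cannot inflate the box), and adds a 2 px margin. If nothing moves,
the error message directs the user to a manual ROI — the same fallback an
operator uses on low-contrast recordings. On the default synthetic scenes
the automatic rectangle overlaps the true vessel band with IoU ≈ 0.8.

## From flow to physiology

`frame_flow_speed()` summarizes one flow field inside the ROI: the spatial
median of $\sqrt{u^2+v^2}$ over valid pixels whose magnitude clears a
moving-pixel cut. The cut defaults to `max(0.2, 0.25 · q90)` px/frame —
static vessel-wall and plasma pixels would otherwise drag the statistic
toward zero, and tying the cut to the flow's own 90th percentile keeps slow
and fast vessels on the same footing. If no pixel qualifies (between
heartbeats), all valid pixels are used rather than an empty set. The
Frobenius-norm-per-√N variant is retained as an option for comparability
with normalization-based implementations.

Physical conversion is `px/frame × µm/px × acquisition_fps`. Species presets
supply a QC band — 0.3–1.5 mm/s for the embryonic zebrafish dorsal aorta;
none ships for medaka, where the user should supply a custom range —
and out-of-band samples are **flagged, never clamped**: clamping would
silently shrink exactly the treatment effects (hemolysis, β-agonists) such a
tool exists to detect. Traces are smoothed with an order-2 Savitzky–Golay
filter (default window 11), whose asymmetric edge fits reproduce quadratic
series exactly; summary statistics are defined over the despiked, smoothed
trace.

## Cell counting and flux

Cells are dark on the bright vessel. Each ROI frame is thresholded in dark
mode; the default adaptive threshold is `qmin + 0.42 (q90 − qmin)` of the
ROI intensities, where `qmin` is a robust minimum (0.1th percentile, cell
cores) and `q90` stands in for open vessel — the median is useless here
because a dense blood column makes cells the majority class. Otsu and fixed
thresholds are available.

Contours are traced by border following in the Suzuki–Abe style, written in
the package: outer borders of 8-connected components, hole borders of
enclosed background components, a containment hierarchy, deterministic
raster order. Enclosed pixel counts are derived from the shoelace polygon
area via Pick's theorem. Counting applies area bounds (default 8–400 px² at
the synthetic scale; always magnification-dependent) and an **unbiased
counting frame**: contours touching the ROI's downstream (right) edge are
excluded, so a cell sliced by the ROI boundary — which appears once entering
and once leaving — is counted exactly once in expectation.

Per-second flux uses the line-crossing model: with `rows` parallel cell rows
advancing `speed` px/frame, each row delivers `speed / pitch` cells per
frame past a fixed transverse line, so
`flux = rows × speed / pitch × acquisition_fps`.
`estimate_cell_geometry()` measures everything from the masks: cell width as
the median equivalent diameter of qualifying contours; the row count from
the mean per-column stacked cell height divided by `(π/4) ×` width — the
π/4 corrects for a disc's mean chord being π/4 of its diameter, and makes
the stacked-disc case exact; and the **pitch** as the median center-to-center
distance between along-flow neighbors. The pitch, not the thresholded core
diameter, is what converts speed into flux — the two coincide only when
cells run nose-to-tail in contact. A legacy per-frame accumulation form
(`rows × width / speed` summed over one second) is available behind
`formula = "printed"` for comparison with older tools; it is not
dimensionally a flux and is never the default.

## The synthetic vessel generator

Every stage above is verified against `synthetic_vessel_clip()`, which
renders scenes with exact ground truth: a bright horizontal vessel band on a
statically textured background, rows of soft-edged dark discs advected at
constant sub-pixel speed with wrap-around (so the in-frame count is
constant), per-frame Gaussian sensor noise, and optional rigid camera jitter
with the injected transforms returned. One integer seed drives texture, row
phase, per-cell variation and noise, in that order, so clips are
bit-reproducible.

The default scene is the package's reference study condition at 0.5 µm/px
and 200 fps: 96×192 px frames, a 39 px vessel band, three vertically aligned
rows of radius-5 px cells at 12 px spacing — a dense column, cells nearly
nose-to-tail, as erythrocytes actually stream through the embryonic dorsal
aorta — moving at 4 px/frame (400 µm/s), 60 frames, background texture
sd 0.02, noise sd 0.01. Cells carry ±5 % radius and ±0.08 intensity
variation: real erythrocytes tumble and vary in apparent contrast, and this
per-cell identity is precisely what disambiguates displacements beyond half
the cell pitch. The spacing constraint requires clearance for the ~1.5 px
soft-edge apron beyond the largest diameter, otherwise adjacent rendered
cells fuse at any threshold. Verification runs use 30–40 frames per clip and
this frame size; they complete on one CPU in a few minutes while leaving the
per-frame statistics well away from small-sample noise.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real recordings: pulsatile (cardiac-cycle) speed
profiles, cell deformation and overlap, out-of-plane motion, illumination
drift, and optically realistic plasma texture. The end-to-end guarantees
(velocity within 10 %, counts within 5 %, flux within 15 %, auto-ROI
IoU ≥ 0.7, ≥ 90 % jitter removal) are statements about these synthetic
conditions; on real data the same code paths run, but accuracy must be
judged against the QC flags and, ideally, a manual spot check.

## Numerical choices and degenerate inputs

* Border policy: reflected padding inside the expansion correlations,
  replicate-border bilinear sampling for all warps and crops.
* Ill-conditioned displacement solves (cond > 10⁶) are marked invalid and
  inherit the prior rather than exploding.
* Constant frames: `normalize_intensity()` warns and returns its input;
  the rigid estimator returns identity with a `low_confidence` flag.
* Degenerate ROIs below 4×4 px are rejected at construction.
* Batch runs are a pure function of inputs and the resolved options: CSVs
  are written at 6 significant digits and re-runs are byte-identical, which
  the acceptance checks assert.
* All tabular results are tibbles (`tidy()`/`glance()` on every result
  object) and figures are ggplot2, so results drop into dplyr/ggplot
  workflows; image carriers stay plain numeric matrices, which is what the
  arithmetic needs.

## Known limitations

Velocity is a 2-D projection: out-of-plane flow components are invisible.
The flux model assumes cells advect without overtaking; strongly overlapping
cells undercount (a limitation shared by any threshold-contour counter).
The automatic ROI assumes a single dominant vessel roughly axis-aligned;
oblique vessels get a correct but loose bounding rectangle. Codec ingest is
deliberately out of scope — frame directories only.
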