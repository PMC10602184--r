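---
title: "Virtual robotic OCT scanning and en-face parameter mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual robotic OCT scanning and en-face parameter mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(roctscan)
```

`roctscan` simulates a robot-held OCT probe sweeping a large tissue sample
and reconstructs quantitative en-face maps from the tracked B-scans. This
vignette records the models, the parameters that matter, and the design
choices made where the problem was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Coordinate frames and the pixel-to-world transform

Two frames are used. The base frame `{F_base}` has x along the scanline
travel direction, y along the lateral stepping direction between
scanlines, and z up. The probe frame `{F_OCT}` has x elevational (travel),
y lateral (B-scan width), z axial (into the tissue), with its origin at
the top centre of the B-scan. A pixel with 0-based lateral index j and
axial index k maps to

    p_OCT  = (0, (j - W_px/2) * alpha_lat, k * alpha_ax)
    p_base = T_OCT^base (p_OCT)          # homogeneous 4x4 transform

The entry-pose rotation `diag(1, -1, -1)` points the probe's axial axis
along -z of the base frame (nadir viewing), which is the only orientation
consistent with the scanline geometry. `alpha_res` is in mm/pixel
throughout (a transcription of the resolution as pixel-per-mm would not
type-check against the transform). Voxelization bins transformed pixels
into a regular grid whose bounds come from the data; colliding pixels
average (the same rule used for stitching), untouched voxels are `NA`,
never 0 — an intensity of zero is data.

## The altitude control loop

The regulated quantity is the normalized surface depth of the highest
detected surface point, `mu = 1 - h_tis/H_OCT`, driven to the setpoint
`mu_ref = 0.75` by

    v_z[t] = w_s K_p (mu_ref - mu[t]) + (1 - w_s) v_z[t-1]

Sign convention (the source material leaves it implicit): positive `v_z`
moves the probe *toward* the sample, i.e. `z <- z - v_z dt`. A positive
error (surface too deep in the image, probe too high) must command descent;
the opposite sign is unstable.

Parameters, with units and defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| `mu_ref` | NSD setpoint | 0.75 | keeps the surface near focus with FOV headroom |
| `K_p` | gain, mm/s per unit NSD | 1 | stable at desk scale; see bound below |
| `w_s` | low-pass weight | 0.5 | halves velocity jitter without much lag |
| `v_land` | landing speed, mm/s | 1 | landing overshoot <= `v_land/(fps*H_OCT)` ~ 0.03 NSD |
| `fps` | frame rate, 1/s | 20 | the imaging rate; the control loop runs once per frame |

The simulator collapses the robot's fast control rate onto the imaging
rate: one controller step per frame. Linearizing the loop on a flat
sample, the NSD error contracts by `(1 - w_s K_p dt / H_OCT)` per frame;
stability therefore requires `w_s K_p dt < 2 H_OCT`, amply satisfied by
the defaults (0.025 mm per unit error vs 3.2 mm). On a ramp of slope s the
steady-state NSD offset is `s * v_x / K_p`: the controller must output a
constant climb velocity `s*v_x`, which a proportional law only produces at
a proportional error. (A published variant of this expression with an
extra `1/H_OCT` does not survive the derivation — the controller output is
a velocity in mm/s, so the FOV normalization cancels; the test asserts
against the discrete-time recursion evaluated numerically.)

Surface detection is a per-column intensity threshold; when no threshold
is given it is estimated per frame as mean + 5 sd of the top 5 % of rows
(assumed background), floored at 1e-6 so noiseless images still detect.
`h_tis` is the minimum detected depth over columns; a frame is surfaceless
only if every column fails, in which case the scanline holds altitude and
logs a warning.

## The B-scan synthesizer

Columns are ideal pencil rays. Below the surface the intensity is

    I(k) = I0 * exp(-2 * alpha_ax * sum_{m<k} mu_t(m)) * f_lumen * speckle

a per-axial-pixel cumulative-sum discretization of the single-scattering
model `I(z) ~ exp(-2 mu_t z)`. Speckle is multiplicative unit-mean gamma
(shape 16 by default when enabled — the standard OCT speckle abstraction);
background is additive folded Gaussian. No confocal/defocus point-spread
and no depth-dependent roll-off are modelled: the attenuation fit is
windowed to ~1 mm below the surface where the single-scattering term
dominates, and the depth-of-field motivation of altitude control is
captured behaviourally by the NSD loop, not by optics.

Lumens are tubes along x with two per-lumen knobs: `factor` multiplies
backscatter inside the tube (fluid lumens image dark — what the segmenter
sees) and `mu_scale` multiplies the local extinction (fluid attenuates
less than parenchyma — what the attenuation map sees). The intensity
factor alone would *not* move the fitted extinction: a multiplicative
notch shifts the log-intensity curve down and back up, leaving the
window's least-squares slope nearly unchanged. Physically vessels appear
in attenuation maps precisely because they attenuate less, hence the
second knob.

Desk-scale defaults (chosen once, not tuned): 180 x 160 px B-scans at
`alpha = (0.03, 0.01, v_x/fps)` mm/px, so `W_OCT = 5.4` mm and
`H_OCT = 1.6` mm; `v_x = 0.6` mm/s at 20 fps gives 0.03 mm frame spacing.
These keep full multi-scanline scans in seconds while preserving every
geometric relationship; true-scale parameters (1800 x 700 px at ~2.7 um)
remain valid configuration. One geometric consequence worth knowing: with
`mu_ref = 0.75` the probe rides `0.25 * H_OCT` above the highest surface,
so phantom extrusions taller than that margin poke above the image top at
a step edge and vanish until the controller reacts. Scan fixtures use
0.3 mm extrusions (< 0.4 mm margin) for this physical reason.

## Parameter maps

All maps are lateral x elevational grids in the base frame with explicit
per-pixel validity; "no data" is never conflated with 0.

**DEPM** projects each column's detected surface point through the frame's
pose and stores absolute base-frame altitude, so the probe's own altitude
motion cancels by construction — the map shows sample topography, not
probe trajectory. **ATCM** fits `ln I(z) = c - 2 mu_t z` by ordinary least
squares in a 1 mm window anchored 2 px below the detected surface
(skipping the specular peak). Non-positive intensities are floored to the
smallest positive double before the log; fits with r² < 0.2 are invalid;
negative slopes clamp to `mu_t = 0` and flag. OLS on the log is
closed-form, scale-invariant (slope-only), and exactly inverts the
noiseless synthesizer. **DIAM** averages measured lumen diameters on a
10 x 10 grid over the mask-volume projection and upsamples bicubically
(Keys kernel, a = -0.5); empty cells are invalid, filled from the nearest
valid cell before interpolation only so that the interpolation has
support, then masked back.

The elevational map pitch is the mean |Δx| of the pose log rather than a
stated constant — the printed elevational resolutions of the original
system do not equal `v_x/fps` exactly, so the pose log is treated as the
single source of truth. The mean (not median) matters for decimated logs,
whose frame spacings alternate between neighbouring integers.

Stitching places per-scanline maps by origin and takes the unweighted mean
of valid contributors in overlaps (running sum + count, hence commutative
and associative); no feathering.

## Lumen segmentation and diameters

The original system used a trained network for lumen segmentation; its
weights are not available, so `roctscan` substitutes a classical detector
behind the same interface, and `build_mask_volume()` accepts precomputed
per-frame masks verbatim as the escape hatch. The detector: CLAHE contrast
enhancement; normalize each pixel by the slice-median intensity at the
same depth below the surface (without this, exponential decay makes all
deep pixels "dark"); threshold at `rel_threshold = 0.35` of that local
background; gate components on depth band, area, eccentricity, and
(default) contact with the lateral image border, since clipped lumens
measure short. Cleanup is area closing then area opening, in that order.

Diameter per component is `2 x mean(EDT over the skeleton)` (Zhang-Suen
thinning, exact Euclidean distance transform), with `2 x max(EDT)` as the
degenerate fallback and `2 x alpha` for single pixels. This equals the
maximum-inscribed-circle diameter for near-circular cross sections — the
case that matters for tubule lumens — and the tests hold it to 1 px
against a brute-force inscribed-circle oracle on such fixtures; for
strongly elongated shapes the mean-over-skeleton definition is smaller by
construction. Measurement assumes near-isotropic in-slice pixels (the real
system's 2.73 vs 2.68 um/px is; fixtures use 0.01 mm isotropic).

## Velocity sweep

Scanning faster at fixed frame rate yields `floor(n0 v0 / v)` frames over
the same trajectory. Decimation (per scanline, fractional stride with an
accumulator starting at frame 0) is the surrogate for physically faster
scans — motion blur is not modelled, matching the original analysis. Map
quality is the mean local SSIM (uniform 7-px window, constants from the
baseline map's range) between the rebuilt decimated map and the baseline,
normalized so the baseline point is exactly 1 (a config switch exposes the
raw curve, since the original normalization is not defined precisely).
Before comparison the decimated map is resampled to the baseline geometry
by nearest neighbour *in base-frame coordinates*, and elevational columns
that received no frame take the nearest sampled column: a decimated scan
has fewer columns, not holes, and index-based resizing would add a
spurious drift penalty. The implementation was cross-checked against
scikit-image's SSIM (agreement to ~2e-4; border conventions differ).

## What the synthetic world does and does not establish

The generator reproduces the geometry and the signal model: surface
topography, pose bookkeeping, exponential depth decay, region-wise
extinction, dark low-attenuation tubes, gamma speckle. It does not
reproduce real OCT physics beyond that — no interferometric signal chain,
no defocus, no depth roll-off, no motion blur, no biological texture — and
no real kidney data ships with the package. A green test therefore
establishes internal consistency (the estimator inverts the generator; the
controller tracks; the maps respect the geometry) and algorithmic
correctness against independent oracles, not clinical performance.
Quantities tied to the physical system — encoder-level localization
errors, the human-kidney maps, measured lumen diameters vs histology, the
~0.25 quality plateau, the network's Dice/IoU — are out of reach by
construction and are deliberately not asserted.

## Numerical conventions

Pixel indices are 0-based in the coordinate conventions (R storage is
1-based internally). Ties in voxel binning resolve by `floor` with a 1e-9
slack so exact-boundary points stay put. Determinism: every random draw
sits behind an explicit seed (`withr::with_seed`), per-frame seeds derive
from the sample seed plus the frame counter, and identical configs produce
byte-identical text artifacts — asserted in the acceptance suite.
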