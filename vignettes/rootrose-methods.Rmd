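---
title: "Quantifying root system architecture from four-sided box images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying root system architecture from four-sided box images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootrose)
```

## The measurement problem

A single *Arabidopsis thaliana* plant carrying an ER-localized GFP marker
grows in the centre of a transparent culture box filled with 33 mm of clear
gel, surrounded by unlabelled neighbours. Fluorescence photographs are taken
through the four vertical faces of the box (A--D, clockwise) at several days
after planting (DAP). Two opposite faces (A, C) image the root system in the
X--Y plane (X horizontal, Y depth), the other two (B, D) in the Z--Y plane.
From these four 2-D views, `rootrose` derives quantitative descriptors of
the root system's architecture:

* **vertical**: the depth profile of root pixel counts, summarized by the
  depth of maximum density, the weighted skewness $g_1$, and the weighted
  excess kurtosis $g_2$;
* **horizontal**: the distribution of root quantity by azimuth around the
  hypocotyl, summarized by the mean resultant length $\bar R$ (with the
  Rayleigh uniformity test), Watson's $U^2$, the mean direction, and a
  windrose.

Because the original study's photographs are not public, the package ships a
synthetic root-system simulator that renders the same four views with known
voxel-level ground truth; every pipeline stage is validated against it.

## The synthetic root generator

`sim_params()` / `simulate_root_system()` implement a discrete-step biased
random walk per root tip, reproducing the qualitative growth phenomenology
of gel-grown *Arabidopsis*:

* the **primary root** starts at the hypocotyl (box centre, depth 0) and
  drifts straight down at 2.5 mm/day, so it reaches the 33 mm gel bottom
  near 14 DAP, where it is clamped;
* **laterals** (8 by default) emerge at uniformly random arc positions
  within the upper third of the primary root (`lateral_emergence_span =
  1/3`), at uniformly random azimuths fixed at emergence, between roughly
  10 and 16 DAP. Each grows at 2 mm/day, initially horizontally outward and
  rotating to vertical over a turn length of
  `10 mm * lateral_outward_then_down_ratio`;
* **tertiaries** (Poisson, mean `tertiary_rate = 1` per lateral) attach
  1--4 mm from the lateral's base -- hence close to the primary root -- and
  appear late in the run (roughly 18--24 DAP for a 26-day horizon).

Each step adds isotropic Gaussian jitter (`angle_jitter_sd = 0.12` rad) to
the drift direction. Every root draws its jitter from a dedicated seeded
substream, so the system at an earlier day is exactly a geometric prefix of
the system at a later day, and artifact placement in the renderer never
perturbs root geometry. Lateral counts, rates and the turn length are free
parameters of the model -- no quantitative branching data exist for the
study system -- and were fixed once at values a root biologist would accept
as a plausible gel-grown plant; they are deliberately not fitted to any
statistic.

Systems are rasterized into a voxel grid (0.5 mm voxels by default); a voxel
accumulates one count per root-path traversal. Projection to a face is
binary ("any occupancy along the viewing ray"): a camera sees a root once
regardless of thickness, and whatever is behind it is occluded. Side C is
the horizontal mirror of side A, D of B. `render_fluorescence()` adds a
Gaussian point-spread (sigma 0.5 px), additive sensor noise, and optional
small bright artifact blobs placed away from the root, emulating labels and
box reflections.

### What the simulator does not emulate

Real photographs contain gel autofluorescence gradients, neighbouring
plants' faint silhouettes, refraction at the gel--plastic interface, uneven
illumination, and roots thicker than one voxel. Passing the synthetic tests
therefore demonstrates correctness of the geometry and statistics under
idealized imaging, not robustness to every field artifact; the detector
parameters are exposed in `canny_params()` precisely because real images
will need retuning.

## Digitization: Canny detection and cleanup

`canny_skeleton()` runs the classic chain -- Gaussian smoothing (sigma 0.6
px), Sobel gradients, non-maximum suppression, hysteresis -- with two
data-driven choices:

* hysteresis thresholds are the 50th/85th percentiles of the *nonzero
  suppressed* gradient magnitudes, which makes detection invariant to
  global illumination and exposure scaling;
* an **intensity gate**: an edge candidate must itself lie on fluorescence,
  i.e. its smoothed intensity must exceed background + 8% of the
  (background-subtracted) bright reference level (99.9th percentile). The
  gate is measured relative to the median, so adding a constant offset to
  the image changes nothing. Without it, the outline of several
  blur-merged roots acquires phantom contours on its dark outer foot.

`clean_skeleton()` automates the study's manual cleanup: morphological
closing (disk radius 2 px) bridges breaks and fills between the paired edge
contours of each root trace; the same intensity gate then removes closed-in
pixels that carry no fluorescence (closing cannot tell the bright interior
of a thick trace from the dark gap between two nearby roots, but the image
can); finally 8-connected components below 20 px are discarded. The result
is always a subset of the closing of the input and the operation is
idempotent. On rendered ground truth with the default noise (sd 0.02, three
sub-threshold artifacts) the cleaned masks achieve recall and precision
above 0.99 at a 1-px tolerance.

These five parameters were calibrated once on synthetic renders; the
original study's thresholds are unpublished, so defaults here make no claim
of matching them. A Zhang--Suen thinning utility (`thin_skeleton()`) is
provided for users who want 1-px centerlines, but the default pipeline does
not thin: where blur merges neighbouring roots into one blob, thinning
collapses their multiplicity into a single line and distorts depth profiles
far more than the extra trace width does.

## From masks to matrices

`combine_opposing_views()` mirrors the back mask into the front frame and
averages the two binary masks (values 0, 0.5, 1, kept as fractional
weights). Results are expressed canonically in the A (or B) frame, making
the operation symmetric in its arguments. `vertical_profile()` averages the
XY and ZY row sums per depth bin; depths are bin centres,
$d_j = (j - \tfrac12)/n \times 33\ \mathrm{mm}$.

`collapse_to_xz()` reduces the Y axis to an overhead X--Z matrix from the
two column-sum marginals $c_X$ and $c_Z$, rescaled to a common total $T$.
The default `outer` method uses the independence back-projection
$XZ(x,z) = c_X(x)\,c_Z(z)/T$, which reproduces both marginals exactly and
localizes mass where both views see roots; the `additive` method
$(c_X + c_Z)/2$ is the literal "average pixel count" alternative and is
retained as an option because the original computation cannot be recovered
from the text. The hypocotyl centre is taken from configuration when known
(for synthetic boxes it always is), otherwise `locate_center()` uses the
weighted centroid column of the topmost nonzero row of each view.

## Vertical statistics

All moments are population (frequency-weighted) moments of bin-centre depth
with the profile counts as weights: pixel counts run into the hundreds or
thousands, so small-sample corrections would be noise, and the excess
convention ($g_2 = m_4/m_2^2 - 3$, zero for a normal distribution) matches
the platykurtic/mesokurtic vocabulary used for these root systems. For
integer weights both $g_1$ and $g_2$ equal the population statistics of the
expanded sample to machine precision, which the tests assert against an
independent expansion oracle. The location of maximum density is the bin
centre of the argmax with ties resolved toward the shallowest bin; no
within-bin interpolation is attempted, since the binning *is* the data.
Degenerate profiles (all weight in one bin) raise errors rather than
returning NaN.

## Circular statistics

`polar_transform()` converts each positive X--Z cell into an (angle, weight)
pair about the centre, excluding cells within 1 px of it (the hypocotyl cell
itself has no defined azimuth). The compass convention is $\theta = 0$ east
(+X), $\pi/2$ north (+Z), counterclockwise; the original study's mapping of
compass words to box corners is undocumented, so this convention is a
package definition, recorded with the outputs.

* $\bar R$ (`mean_resultant_length()`) and the mean direction are direct
  weighted trigonometric moments.
* The Rayleigh test uses $z = n_\mathrm{eff}\bar R^2$ with the standard
  second-order correction series, $n_\mathrm{eff}$ being the rounded total
  weight. Under simulated uniformity ($n = 1000$) its empirical type-I
  error at $\alpha = 0.05$ sits within $5\% \pm 2\%$ over 2000 replicates.
* Watson's $U^2$ is an order-statistic test defined for unweighted samples,
  and the study fed per-pixel counts to an unweighted implementation; the
  package reproduces that by integer expansion -- each angle is repeated
  `round(w * scale)` times with the scale chosen so the expanded size is
  about $n_\mathrm{eff}$, capped at $10^5$ (integer weights below the cap
  expand exactly; a degenerate expansion falls back to seeded weighted
  resampling with a warning). P-values are reported as censored bounds from
  the asymptotic critical values (0.152 / 0.187 / 0.221 / 0.267 at
  $\alpha$ = .10 / .05 / .025 / .01) rather than extrapolating beyond the
  table.
* `windrose()` bins weight into equal half-open sectors, sector 1 centred
  on east, boundary angles assigned to the higher sector; total weight is
  conserved exactly.

## The orchestrated run

`run_experiment()` processes every (box, day) combination of a
configuration -- synthetic or a directory of `<box>_<side>_<DAP>.png`
images -- into per-stage TSV matrices, windrose and heatmap figures, a
JSON-lines log of every processing decision (thresholds, pixels removed,
centre used), and a summary CSV with one row per box and day. A failing
(box, day) yields NA statistics and the run continues. Everything derives
from one master seed, and reruns are byte-identical. `generate_fixture()`
writes the synthetic image tree plus ground-truth files; at the study's
scale (16 boxes, 5 days, 4 sides) that is 320 images.

## Known limitations of the two-view collapse

Two orthogonal view pairs cannot reconstruct a 3-D density, and the
package's ground-truth comparisons quantify the cost honestly:

* **Occlusion of shallow mass.** Lateral bases and tertiary roots cluster
  around the primary root's column and hide behind it (and each other) in
  both view pairs, while a lateral's initial horizontal run is foreshortened
  to a few pixels in one of the two averaged views. Both effects remove
  proportionally more *shallow* than deep mass, so the image-derived
  vertical skewness is systematically below the voxel truth -- by about 0.1
  for sparse systems (2--4 laterals, no tertiaries) and 0.3 at the default
  density at 26 DAP. Within-method comparisons across treatments or days
  share this bias; absolute skewness values do not.
* **Outer-product ghosting.** The independence back-projection lights up
  cells at every combination of occupied $x$ and $z$, so mass leaks into
  azimuths where no root is, deflating $\bar R$ for strongly directional
  systems (error up to $\approx$ 0.1--0.15 at realistic densities; smaller
  as systems fill in). The additive method is worse in this respect.
* The windrose and mean direction, being driven by the dominant marginal
  structure, are considerably more stable than $\bar R$'s magnitude.

These are properties of the imaging geometry, not of noise: they persist on
noise-free renders with a perfectly known centre. The acceptance checks
encode the idealized recovery bounds as stated ($|\Delta g_1| \le 0.15$,
$|\Delta \bar R| \le 0.05$) and the recovery block therefore fails at the
default density; the measured errors are reported by
`scripts/acceptance.R` as `recovery_abs_skewness_error` and
`recovery_abs_rbar_error` so the distortion is visible rather than hidden.

## Problem sizes and numerical choices

The test-suite simulations use the default 0.5 mm voxels (grids of
$153 \times 66 \times 153$), ten seeds for recovery and detection checks,
2000 replicates of $n = 1000$ for the Rayleigh calibration, and the
study-scale 320-image fixture -- sizes chosen so the full suite runs in
about a minute while every statistic still operates in its intended regime.
Numerical conventions worth knowing: angle reduction to $[0, 2\pi)$ is by
modulo; $\bar R$ is clamped to $[0, 1]$ against floating-point overshoot;
`mean_direction()` errors (rather than returning 0) when the resultant is
numerically zero; the Watson expansion cap and the component-size filter
are the only deliberate discretizations, both configurable.
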