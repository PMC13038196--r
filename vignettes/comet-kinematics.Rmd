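---
title: "Quantifying microtubule plus-end comet kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule plus-end comet kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometkin)
library(dplyr)
```

## The problem

End-binding protein 1 (EB1) fused to GFP accumulates at the growing plus
end of microtubules and appears in live-cell time-lapse movies as a moving
"comet". Tracking these comets reports where and how fast microtubules
grow. In differentiating alveolar epithelial cultures the growth regime
changes qualitatively: early cells (cuboidal, around day 7 of culture)
show unidirectional comet movement along radial spokes from the cell
centre to the cortex, while late, flattened cells (around day 14) show
bidirectional movement along thick bundled tracks, with comets of both
polarities sharing a bundle. `cometkin` implements the full quantitative
chain needed to measure that switch — comet detection, track linking,
calibrated kinematic statistics, kymographs, and the group-comparison
protocol — together with a synthetic movie generator that emulates both
regimes with known ground truth, so that every stage can be validated
without any microscope data.

## Per-track statistics

For a track with positions $p_1, \dots, p_n$ (pixels, converted to
micrometres by the imaging scale) observed at the frame interval
$\Delta t$:

* **Velocity** ($\mu$m/min): total path length $\sum_i \lVert p_{i+1} -
  p_i \rVert$ divided by the duration $(n-1)\Delta t$. This is the mean
  instantaneous speed. The description "XY displacement over duration" is
  ambiguous between path length and net displacement; we use path length
  because it matches common tracker output and remains meaningful for
  tracks that reverse direction — the hallmark of the bundled regime,
  where a net-displacement velocity would conflate speed with
  straightness. The net-displacement variant is emitted as the auxiliary
  column `velocity_net_um_min`.
* **Movement angle** (degrees): direction of the net start-to-end
  displacement, counterclockwise from $+x$ with the image row axis
  negated, in $[0^\circ, 360^\circ)$.
* **Angle fluctuation** (degrees): the standard deviation of
  frame-to-frame heading changes, each change wrapped into
  $(-180^\circ, 180^\circ]$ (so $170^\circ \to -170^\circ$ is a
  $+20^\circ$ change). The sample ($n-1$) denominator is the default; a
  population variant is available. At least two heading changes (three
  steps) are required, otherwise the statistic is reported absent.
* **Straightness**: net displacement over path length, in $[0, 1]$.
* **Directionality concentration (DC)**: the circular-statistics mean
  resultant length $R = \lVert \tfrac1n \sum (\cos\theta_i, \sin\theta_i)
  \rVert$ of a set of angles; $R = 1$ for perfectly coherent directions
  and $R \to 0$ for balanced or opposed directions.

### At which level is DC aggregated?

The mean resultant length can be taken over different angle sets, and the
choice matters. `summarize_movie()` reports the movie-level DC over the
per-track net movement angles (with a `per_step` flag to pool step
headings instead). But note a structural fact about the radial regime: a
cell whose comets all move outward from the centre has movement angles
distributed over the full circle, so the *pooled* DC is near zero even
though each individual track is perfectly coherent. Pooled DC therefore
measures whether a field of view has one dominant growth direction, not
whether growth is directionally persistent. The statistic that separates
the regimes — and the one the pipeline uses when contrasting conditions —
is the **per-track DC** (`track_dc`): the resultant length of each
track's own step headings. A radial comet with small heading noise has
`track_dc` near 1; a comet rattling along a curved bundle with larger
heading noise scores lower. For step headings with wrapped-Gaussian noise
of SD $\sigma$ (radians) the expected resultant length is
$e^{-\sigma^2/2}$, which the tests verify at $n = 1000$.

## The synthetic movie generator

`simulate_trajectories()` draws comet births from a Poisson process
(`birth_rate_per_frame`), lifetimes from a geometric distribution with
the configured mean (memoryless; no lifetime model is prescribed by the
biology we emulate), and advances each comet by a fixed step of
`comet_speed_um_s * frame_interval_s / pixel_size_um` pixels per frame.
Heading noise is wrapped-Gaussian and applied to direction only — speed
is never rescaled — so directionality statistics can be studied
independently of speed statistics. In the radial regime a comet's base
heading points outward along its spawn spoke; in the bundled regime each
comet follows a polyline of the bundle skeleton with polarity $\pm 1$
chosen with equal probability, its nominal heading being the local
tangent. Comets terminate when they leave the field of view or run off
their polyline, as in real acquisition. `render_movie()` adds an
isotropic Gaussian PSF of SD `psf_sigma_px` with peak `amplitude` per
comet, a constant background, and Gaussian read noise or Poisson shot
noise; rendering consumes an RNG stream derived deterministically from
the configuration seed, so a fixed seed reproduces trajectories and
pixels bit for bit.

Defaults mirror the study conditions where those are stated: the frame
interval defaults to 1.5 s. The pixel size is deliberately a required
argument with no default, because the acquisition scale is not something
a simulation should assume; the package's own fixtures and demo use
0.16 µm/px (a 6.5 µm camera pixel behind 40× effective magnification, a
common live-imaging configuration). Comet density, movie duration and
SNR are exposed as parameters; the bundled demo uses speeds of 0.15 vs
0.20 µm/s and heading noise of 10° vs 25° for the early/late conditions.

What the generator does *not* emulate: photobleaching, stage drift, 3-D
optics, camera gain, comet shape anisotropy, catastrophe/rescue cycles,
or whole-cell morphology. Passing tests on synthetic movies therefore
validate the measurement chain — detection accuracy, linking fidelity,
statistic definitions — not the biological realism of any particular
movie.

## Detection

Linear comet signals are enhanced with a Hessian ridge ("tubeness")
filter: the image is convolved with Gaussian-derivative kernels at scale
$\sigma$ (`scale_px`), the $2 \times 2$ Hessian is formed per pixel, and
the response is $\sigma^2 \max(-\lambda_1, 0)$ where $\lambda_1$ is the
smaller eigenvalue. Bright ridges and spots give positive response; flat
background gives zero (the truncated second-derivative kernel is
re-centred to sum exactly to zero so constants map to zero response).
Borders use reflect padding, and maxima within $\lceil\sigma\rceil$
pixels of the border are suppressed. Intensities are cast to float in
$[0, 1]$ first — 8-bit input is accepted and scaled, never re-quantised
internally.

Detections are 8-connected local maxima of the response above a quality
threshold (default `median(response) + 5 * mad(response)`, a robust rule
chosen because no threshold rule is prescribed; it is overridable), each
refined to subpixel precision by an intensity-weighted centroid in a
$(2\lceil\sigma\rceil + 1)^2$ window on the enhanced image with the
window minimum subtracted (which removes the centroid shrinkage bias a
constant offset would cause). An optional simple-polygon ROI restricts
detections to the cell interior. Thresholding happens on the enhanced
response rather than raw intensity; the raw pixel value at the peak is
carried along as `raw_intensity` for users who prefer the alternative.

## Linking

Frame-to-frame linking is a rectangular linear assignment problem with
cost equal to squared Euclidean distance, links beyond
`max_link_dist_px` forbidden, and non-link cost `max_link_dist_px`²
(`alt_cost_factor` scales the cutoff, default 1). The non-link cost
doubles as a cutoff inside the solver: a link costing more than it is
never made, which is exactly the distance-cutoff-as-cost convention of
simple LAP particle trackers. The solver is a Jonker–Volgenant shortest
augmenting path solve on the standard augmented matrix; rows are
augmented in index order and ties broken by the first minimal column, so
results are deterministic (detections are canonically ordered within
each frame first, making the track set independent of input row order).
Cost ties between distinct optimal matchings have measure zero for
distance costs; the solver's deterministic order stands in for an
explicit lexicographic tie-break.

Gap closing, when enabled, is a second assignment pass joining track
ends to later track starts within `gap_frames` skipped frames and
`max_gap_dist_px`. It is off by default because no gap setting is
prescribed. Merging and splitting are out of scope (the "simple" LAP
variant). `min_track_len` defaults to 4 detections so that angle
fluctuation — which needs two direction changes, hence three steps — is
computable on every retained track.

## Kymographs

`reslice_kymograph()` resamples a user polyline at unit arc-length steps
and averages `width_px` bilinear samples along the local normal (the
"wide" reslice convention; `max` across the width is available as an
option), stacking one row per frame. A comet moving at constant speed
$v$ px/frame along the path appears as a line of slope $1/v$ frames per
position unit; `kymograph_trace_speed()` recovers the speed by least
squares on per-row peak positions. An optional tubeness pre-filter
reproduces the filter-then-reslice order used for background removal.
The exact width and interpolation of the original analysis tool are not
documented; width 3 with bilinear interpolation is the default here.

## Group comparisons

`compare_two_groups()` implements the gated protocol: Shapiro–Wilk on
each group; if both pass at `alpha_normality` (default 0.05 — the gate
is stated without an α, so the conventional level is used), an unpaired
two-tailed Student's t test with pooled variance (Welch via a flag);
otherwise a Mann–Whitney U test, exact when the smaller group has at
most 8 observations and no ties, normal approximation with tie and
continuity correction otherwise. `compare_multi_groups()` is fixed-effects
one-way ANOVA for three or more groups. No post-hoc or multiplicity
correction is applied, as none is part of the protocol.

## ChIP signal enrichment

`filter_enriched_intervals()` restricts the Input control signal to
intervals overlapping the analyzed gene regions (half-open overlap, any
shared base), takes its 95th percentile (configurable) as the threshold,
and keeps ChIP intervals that overlap a region *and* exceed the
threshold strictly. The percentile uses linear interpolation between
closest order statistics ($h = (n-1)q/100$); published thresholds depend
on this convention, which is why it is documented and fixed. Values are
one-per-interval by default; a per-base weighting and a genome-wide
Input scope are available, as is a minimum-value pre-filter, since the
upstream filtering applied to deposited tracks before percentile
computation is not fully specified.

## Numerical and degenerate-input choices

* Angle wrapping interval is $(-180^\circ, 180^\circ]$ with the boundary
  assigned to $+180^\circ$.
* Zero-length steps contribute no heading; tracks with zero net
  displacement have no movement angle and are excluded from pooled DC.
* A single-detection track has no defined statistics; `summarize_movie()`
  errors when no track clears `min_steps` (default 3).
* Bilinear sampling clamps at the image edge; reslice paths that leave
  the image raise an error listing the offending arc positions.
* Pipeline CSV output is written with 6 significant digits, which is the
  comparison tolerance for golden-file reproduction.

## Problem sizes used by the test-suite demonstrations

The two-condition demonstration simulates 160 × 160 px movies of 100
frames at 2.5 births/frame (about 160–190 usable tracks per condition);
tracking/localization checks use a 224 × 224 px, 50-frame sparse movie
plus 200 isolated spots at peak-to-noise 10; the DC analytic check uses
1000 headings per noise level. These sizes keep every run comfortably
reproducible on a laptop while leaving the statistical conclusions
unambiguous.

## Known limitations

Detection assumes isotropic spots, so strongly elongated comets are
localized at their intensity centroid rather than their tip. Linking has
no motion model; very dense fields with crossing trajectories will show
identity swaps (visible as a link-recovery fraction below 1 in dense
simulations). The movie-level pooled DC depends on field geometry, as
discussed above. The ChIP module reproduces the percentile rule, not
peak calling; applying it to deposited data requires the same upstream
processing as the original tracks, so the printed threshold of any given
dataset is reproducible only up to that processing.
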