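---
title: "Quantifying MTOC repositioning and motor-cluster dynamics from live-cell movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MTOC repositioning and motor-cluster dynamics from live-cell movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrack)
library(dplyr)
```

When a T cell recognises antigen on an opposing surface, its
microtubule-organising centre (MTOC, the centrosome) translocates toward
the contact interface — the immunological synapse. The movement is
driven by cytoplasmic dynein anchored near the synapse pulling on
microtubules, and plus-end tracking proteins such as CLIP-170 regulate
where dynein accumulates. synaptrack implements the quantitative imaging
pipeline used to measure this process in TIRF/HILO live-cell movies:
channel registration for dual-camera imaging, kymograph-based comet
velocimetry, refraction-corrected axial MTOC positioning with
centre/periphery classification, punctate cluster
detection/tracking/motion classification, dual-colour track
colocalisation statistics, and comparative-C~T~ expression for the IL-2
functional readout. Because no raw movies are publicly available, the
package also ships a synthetic-movie module that generates every input
with exact ground truth; all validation rests on parameter recovery
from these movies plus the analytic anchors printed alongside the
original measurements.

## The acquisition model

All defaults emulate the imaging setup being reproduced: 80 nm/pixel,
1 frame/s, two EMCCD cameras. `acquisition_spec()` bundles frame
geometry with a camera noise model: Poisson shot noise on signal plus
background, then additive Gaussian read noise. The original camera
gain, exposure and background statistics are not published, so
`background_level` (default 100 counts) and `gaussian_noise_sd`
(default 4 counts) are free parameters of the simulation, not claims
about the original data. Spot and comet brightnesses are specified as
signal-to-noise ratios (peak amplitude over the per-pixel background
noise sd); the validation suite uses SNR 8, with SNR 5 as the lower
bound at which recovery guarantees are tested.

## Channel registration

Dual-colour images come from two cameras whose magnification, shift and
rotation differ slightly. Those three corrections define a similarity
transform, fitted from a calibration image of a 10 µm square lattice
(125 px pitch at 80 nm/px):

1. `detect_lattice_nodes()` finds intersections coarsely as local
   maxima of the smoothed image (nodes of an additive line lattice are
   its brightest points), then refines each with an iterative centroid
   under a radially symmetric Gaussian window. Because the intensity
   around an intersection is point-symmetric, the centroid is exact in
   the noise-free limit; measured node error is below 0.05 px.
2. `fit_channel_transform()` pairs nodes across channels by nearest
   neighbour (inter-camera displacements are far below half a pitch,
   so pairing is unambiguous) and solves the least-squares similarity
   problem in closed form (orthogonal Procrustes with scale). On
   noise-free lattices the fit residual is ~0.03 px RMS, within the
   0.1 px engineering budget that keeps registration error negligible
   against the 2 px colocalisation gate.
3. `apply_channel_transform()` resamples channel B at the
   forward-mapped positions with bicubic (Catmull–Rom) interpolation,
   the interpolation named by the original correction procedure.
   Pixels mapping outside the source get the frame's border-median
   background. The interpolation itself (`bicubic_sample()`) is
   written in the package because no installed R package provides
   bicubic image sampling.

The transform family is deliberately similarity, not affine: the three
named corrections are magnification, shift and rotation, and a wider
family could absorb noise into shear that the hardware cannot produce.
Channel A (shorter wavelength) is always the fixed reference.

## Kymograph comet analysis

A kymograph resamples a hand-traced microtubule path at exactly 1 px
arc spacing (bicubic interpolation, perpendicular averaging when a
line width above 1 px is requested) and stacks one row per frame, so
the pitches are 80 nm/pixel horizontally and 1 s/row vertically. A
comet moving at constant velocity appears as a straight streak whose
slope, converted by those pitches, is the velocity; `trace_velocity()`
does exactly that arithmetic for manually read segments, signed
positive toward the path's plus end.

`detect_traces()` automates the manual line reading: per-row local
maxima above `baseline + 4·sd` (robust estimates; parabolic subpixel
refinement) are linked across consecutive rows within a 6 px gate, and
runs of at least 5 rows are fitted by least squares. Two numerical
choices matter. First, within a row, maxima closer than ~one comet
length (12 px default) are reduced to the brightest: a comet's
exponential tail otherwise spawns slow "shadow" traces behind the tip.
Second, when a kymograph is built along one traced microtubule, the
comet belonging to that microtubule is the *dominant* (longest) trace;
shorter streaks are usually comets from crossing paths seen obliquely
and should not enter that path's velocity estimate.

Comet length uses the rise-to-baseline rule: scanning outward from the
intensity peak toward the steeper flank (the tip), the comet begins at
the first position where the smoothed derivative magnitude exceeds
3× its baseline sd; scanning outward along the tail, it ends at the
first position below baseline + 1 sd, with the baseline estimated as
the median of the profile's lowest quartile. Both thresholds carry
small relative floors (20% of the peak derivative; 2% of peak height)
so the rule stays defined on noise-free profiles where the sd
estimates vanish. Derivatives are central differences, which keeps the
measured length exactly invariant under path reversal. Lengths are
measured on single-frame profiles (kymograph rows).

## MTOC positioning

Perpendicular to the synapse, the MTOC's distance from the contact
surface is read off the microscope's focusing stage. Because specimen
(n = 1.37, Jurkat cytoplasm) and immersion/coverslip (n = 1.52) have
different refractive indices, the mechanical shift z₀ overestimates
the true distance; `correct_axial_distance()` applies

  z = z₀ · n_specimen / n_glass ,

an exact one-line evaluation tested for linearity and for the
shrinking property (z < z₀ with the default indices). The synthetic
through-focus stack (`sim_mtoc_stack()`) renders the MTOC spot with a
Gaussian whose width grows linearly with defocus and whose integrated
intensity is conserved; this is sufficient for best-focus
localisation — the only use the pipeline makes of it — and is not a
physical point-spread-function model. `find_best_focus()` maximises
peak/width with parabolic refinement and recovers the programmed
mechanical shift to better than half a z-step.

Parallel to the synapse, each cell's footprint is an ellipse
(`fit_cell_geometry()`: direct least-squares conic fit from boundary
points, or exact second-moment equivalent ellipse from a filled mask;
outlines may equally be drawn by hand and entered directly, which is
how the original analysis worked). The "centre" region is the
concentric ellipse with half the cell's diameters; a point is centre
when its normalised elliptical radius is at most 0.5, *inclusive* —
the original rule does not state the tie convention, so the boundary
counts as centre here. The half-diameter ellipse covers a quarter of
the cell area, so uniformly placed MTOCs centre at 25%: the suite
checks this calibration at n = 5000 and checks classification against
an independent brute-force oracle on 10⁴ points for 20 random
geometries. `centring_fraction()` reports the fraction with a Wilson
95% interval. `compare_conditions()` provides a two-proportion test
and a Welch test as plain descriptive utilities: the original
p-values come from unnamed tests and are not reproduction targets.

## Cluster detection, tracking and motion classes

`detect_clusters()` implements the two selection criteria for protein
clusters verbatim: the diameter must exceed 240 nm (3 pixels), and the
cluster-to-surrounding intensity difference must exceed the sd of the
surrounding. Both criteria need operational definitions the original
text leaves open: diameter is the FWHM of a least-squares 2D Gaussian
fit, and "surrounding" is an annulus from 1.5× to 3× the fitted
radius. Candidates come from local maxima of the lightly smoothed
frame above a robust 4-sd threshold; every returned detection carries
its criteria flags, and the suite verifies each criterion is
*individually* necessary (bright-but-small and large-but-dim spots are
both rejected).

`link_tracks()` is greedy nearest-neighbour linking on consecutive
frames with a 5 px gate (0.4 µm/s at the default calibration, above
the fastest expected population at 0.28 µm/s) and no gap closing;
tracks shorter than 3 frames are dropped, aligning the tracking unit
with the colocalisation rule's 3-frame window.

Track speed is the magnitude of the mean per-frame displacement vector
(net displacement over elapsed frames). For directed motion this is
the unbiased estimator: a per-step average of unsigned step lengths
inflates slow velocities by ~25% at SNR 8 through localisation noise
alone, which would be a measurement artifact, not biology. Lifetime
uses the inclusive convention n_detections × frame interval (a
9-frame track at 1 fps lives 9 s).

`classify_motion()` assigns exactly one class per track: immobile if
mean speed < 0.02 µm/s (well under the slowest directed population at
0.054 µm/s), otherwise plus or minus by the sign of the mean
projection of per-frame displacements onto the local microtubule
direction field. The default field is radial-outward from the cell
centre — in this geometry plus ends grow from the MTOC toward the
periphery — and a comet-derived field can be supplied when a CLIP-170
channel exists. The original analysis judged directions manually
against visible microtubules; the radial default is an explicit,
recorded stand-in for that judgement.

## Colocalisation statistics

Two clusters from different (registered) channels count as colocalised
when they stay within 2 px (~160 nm) and share the same movement
category for at least three consecutive frames. The persistence and
shared-category parts are the stated rule; the 2 px gate is this
package's operational distance, chosen comfortably above the
registration residual and localisation noise but below typical
inter-cluster spacing. Pairing is one-to-one by closest mean distance,
and `match_tracks()` is symmetric in its channels. Unpaired tracks
become per-channel non-colocalised records. `build_fraction_table()`
normalises counts over *both* regions so the grand total is 100%, and
warns below 100 records, the stated minimum sampling. Velocity and
lifetime summaries group by (colocalised × motion class × region) and
carry the exact 1/60 conversion between µm/min and µm/s.

## Comparative C~T~

`relative_expression()` averages technical replicates at the C~T~
level, forms ΔC~T~ = C~T~(target) − C~T~(reference) per sample,
ΔΔC~T~ against the mean ΔC~T~ of a user-named calibrator condition,
and reports 2^−ΔΔC~T~. Amplification efficiency is fixed at 2, the
comparative-C~T~ assumption; efficiency calibration is out of scope.
The calibrator is a required argument because the original analysis
does not name one. The generator writes triplicate tables whose
expected ΔΔC~T~ is −log₂(fold), so folds are recovered exactly at zero
noise and within sampling error otherwise.

## What the simulators emulate — and what they do not

Comets are rendered as a Gaussian leading edge (σ = 120 nm) with an
exponential intensity tail (decay 0.4 µm by default) advected along
straight paths; clusters are 2D Gaussian spots (FWHM 400 nm default)
in three motion states placed inside the cell ellipse; colocalised
pairs share one trajectory across both channels; the calibration
lattice is warped through the known transform; every random draw
flows from one explicit seed, and identical seeds give bit-identical
movies.

Programmed speeds are single per-class values by default (optional
lognormal dispersion with exact mean). The published ±sd on the
population velocities mixes biological and measurement spread, so it
is not imposed on the ground truth; recovery tests would otherwise be
dominated by sampling error of the mean rather than by the pipeline
under test. Two behavioural details: comet paths are sampled to lie
fully inside the frame so kymographs along truth paths are always
valid, and minus-end clusters stop (their trajectory is truncated)
when they arrive within one step of the cell centre — recomputing the
inward direction across the centre would make them oscillate there, an
artifact with no biological counterpart.

The simulators do **not** model photobleaching, a physical defocus
PSF, cell-shape dynamics, microtubule curvature (paths are straight by
default, though polyline paths are supported throughout), motion-state
switching within a track, or camera-specific gain registers. Passing
recovery tests therefore demonstrates the *analysis* is correct and
well-calibrated on data matching its assumptions; it does not certify
performance on real movies with those additional effects.

## Problem sizes and numerical choices

The validation suite runs movies between 128² and 512² pixels with
25–60 frames, 10–100 clusters or comets per movie, 20-geometry ×
10⁴-point region oracles, and n = 5000 calibration draws; these sizes
give sampling error well below the tolerances tested while keeping
the suite quick to run. Degenerate inputs fail loudly with classed
conditions: paths leaving the frame, blank calibration images, fewer
than 4 nodes, collinear ellipse points, empty groups, single-detection
tracks, missing calibrator or gene. Ties: the centre-region boundary
is inclusive; equal-distance track pairing resolves by scan order of
ascending mean distance; the region of a colocalisation record is the
region of its channel-A (or first-overlap) track start.

## A worked example

```{r example, eval = FALSE}
spec <- acquisition_spec(frame_shape = c(384, 384), n_frames = 50)
geom <- cell_geometry(c(192.5, 192.5), c(170, 150))
sim <- sim_cluster_movie(100, spec, geom, snr = 8, seed = 7,
                         coloc_fraction = 0,
                         speeds_um_per_s = c(plus = 16.8 / 60,
                                             minus = 0.054, immobile = 0))
tracks <- detect_clusters_movie(sim$movie_a) |> link_tracks()
classes <- classify_motion(tracks, geom)
classes |>
  dplyr::group_by(motion_class) |>
  dplyr::summarise(n = dplyr::n(), mean_speed = mean(speed_um_per_s))
```

On this synthetic cell the plus-end population returns a mean speed
within a few percent of the programmed 0.28 µm/s and the minus-end
population of 0.054 µm/s, matching the reported microtubule growth
rate and the weakly processive dynein rate respectively — the same
computation `scripts/acceptance.R` performs at full size.

## Known limitations

Tracking is greedy rather than globally optimal and forbids gaps, so a
single missed detection splits a track; split fragments inherit the
right class but add variance to per-track speed means. The radial
direction field misclassifies directed motion that is locally
tangential. Comet length depends on the stated threshold
operationalisations; alternative smoothing or baselines shift absolute
lengths by ~1 px, which is why the recovery test compares against the
same rule applied to the clean kernel. The defocus model supports
best-focus search only. None of the original condition-level numbers
(centring fractions per mutant, per-condition velocity tables,
p-values) are recomputable without the original movies; the package
reproduces the *measurement machinery* and validates it on ground
truth.
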