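---
title: "Projection-based automatic sample alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-based automatic sample alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projalign)
```

## The problem

High-throughput tomographic microscopy of many near-cylindrical specimens
(the motivating case: mouse femurs of roughly 12 × 1.1 × 1.2 mm imaged in a
1.5 mm field of view) requires every specimen to be centered on the rotation
axis and oriented vertically before it is scanned, and the scanned
sub-volume to sit at a biologically meaningful fractional height of the
specimen (56% of femur length). Doing this by hand takes minutes per sample
and does not scale to thousand-sample studies. `projalign` implements the
image-based alignment pipeline that automates this — segmentation, per-row
center-of-mass statistics, an axis fit, and closed-loop stage feedback —
together with a complete virtual beamline (projection simulator plus
motorized-stage model) so that every algorithm can be exercised and
validated with known ground truth and no hardware.

## The projection model

The virtual detector records flat-field-corrected absorption images: each
pixel holds the Beer–Lambert line integral $\int \mu \, ds$ along a parallel
beam through the scene. The scene has three phases, as the segmentation
assumes: the specimen (an elliptical cylinder of absorption $\mu_s$, default
1.5 mm$^{-1}$), a wax mound at its base (weakly absorbing, $\mu_w = 0.1$
mm$^{-1}$ — below the sample threshold, i.e. "air" to the classifier), and a
metal holder pin ($\mu_h = 50$ mm$^{-1}$, saturating the detector). The
line integral through the posed elliptical cylinder is evaluated in closed
form from the quadratic ray–cylinder intersection, so noiseless projections
are exact to machine precision — this is what makes the simulator usable as
an oracle for parameter-recovery tests.

Three degradations are added on top of the clean integral:

* **Edge-enhancement fringes.** Propagation-based edge enhancement is
  modeled as a difference-of-Gaussians band straddling every phase boundary
  (widths $\sigma$ and $2\sigma$, $\sigma$ = `fringe_width_px`), normalized
  so a straight edge peaks at ±`fringe_amplitude`. The default amplitude
  (0.5) deliberately exceeds the default sample threshold (0.3) so that wax
  edges are misclassified as sample — reproducing the failure mode that the
  row-cleaning step exists to fix. The physical artifact is only known
  qualitatively, so the amplitude is a free simulator parameter.
* **Noise.** Zero-mean Gaussian noise in absorption units
  (`noise_sigma`, default 0.02). The analysis operates after flat-field
  correction, where a Gaussian model is appropriate; Poisson counting
  statistics in the raw frames are not modeled.
* **Saturation.** Values are clipped at `saturation_level` (default 3,
  about the dynamic range of a 16-bit detector after the logarithm), with a
  boolean mask recorded before clipping; the mask defines the per-row
  saturated fraction, for which no prior definition exists.

Pixel centers sit at $i - (n+1)/2$ for 1-based index $i$, so the coordinate
origin is exactly at the image center and an even-sized detector has no
pixel at 0. All tests and studies keep the physical field of view at
1.5 mm (the reference configuration: 2048 px at 0.74 µm) and vary only the
sampling: 512 px at 2.93 µm for study-scale runs, 128–256 px for unit
tests. Because thresholds act on absorption values and the fit works in
fractional row statistics, results transfer across detector samplings.

## The stage model

The x and z specimen motors and the two-axis goniometer ride on top of the
rotation stage (angle $\omega$); the y motor carries the whole assembly.
Commands are issued in the lab frame of the projection image and converted
to motor coordinates by rotating by $-\omega$, so a request "move the image
content 10 µm right" works identically at any rotation — at $\omega=90°$ it
is the z motor that moves. The goniometer axes are taken parallel to the 0°
and 90° image planes (axis *u* visible at 0°, *v* at 90°), which makes the
two-plane alignment procedure exactly decoupled; the real instrument's axis
orientation at $\omega = 0$ is not documented, so this convention is a
design choice. The goniometer radius of rotation is aligned with the bottom
of the specimen: tilting by $\Delta\theta$ displaces a point at height $h$
above the base by $h \sin \Delta\theta$ — which is why tilt corrections
shift the apparent offset and a single open-loop correction is not enough.
Travel is limited to ±10° per axis; motors are ideal (no quantization),
matching their role as the reference standard for position measurements.

A robot load (`load_sample()`) perturbs the pose with Gaussian
kinematic-mount noise (σ = 0.38 µm, the measured repeatability of the
magnet-and-three-balls mount) and uniform wax-placement tilts (±2° by
default, the spread expected from rapid hand-mounting), then commands the
stage to a random position. The random displacement emulates the
repeat-precision protocol, in which each reload is deliberately moved up to
one field of view away from the aligned position *by the motors* — that is
the point of the protocol, since the motor readback is the absolute
reference against which alignment repeatability is judged. The commanded
offset is uniform within ±FOV for y and ±FOV/2 for x and z, so that part of
the specimen remains detectable; a specimen displaced laterally by a full
field of view would simply not be in the image. The nominal vertical
position views mid-specimen (stage y starts at −length/2 with the pivot at
the specimen base), as a specimen much longer than the field of view is
visible at any height near its middle.

## Segmentation and quantification

Segmentation is a fixed two-threshold rule: air below `t_sample`, sample
between `t_sample` and `t_holder`, holder above. Equality is resolved
upward (a pixel exactly at `t_sample` is sample); the rule's verbal
definition does not fix the boundary, and any consistent choice works
because thresholds sit in wide gaps between phase absorption levels. Row
cleaning then resets to air every row in which fewer than 5% (strictly less)
of pixels are above the sample threshold, removing rows whose only
above-threshold content is wax fringe; rows are cleared rather than deleted
so that row coordinates remain valid for the fit. Cleaning is idempotent.

For each remaining row the classifier reports the phase fractions, the
saturated fraction, and the mean and population variance of the
sample-pixel x coordinates. The axis fit is unweighted ordinary least
squares of the per-row centers of mass against the row coordinate,
$\bar{x}(y) = c_1 y + c_2$: $c_2$ (scaled by the pixel size) is the
centering offset at the image mid-height and $\theta_s = \arctan(c_1 \,
\mathrm{pix}_x/\mathrm{pix}_y)$ the deviation from vertical. The variance is
computed and exported as a diagnostic but not used to weight the fit (the
`weight_by_var` switch of `fit_axis()` stays off by default), matching the
original procedure. Rows qualify for the fit when their sample fraction exceeds
`p_min` = 0.05 — the same constant used for cleaning and for the vertical
extent $Y_{max}/Y_{min}$, which is computed after cleaning.

## Calibration

Effective pixel sizes are recovered by imaging a cone-shaped tip at known
stage displacements and regressing the measured image shifts (subpixel
cross-correlation: FFT correlation, three-point parabolic peak refinement)
on the commanded distances. Two numerical details matter. First, the Hann
window that `subpixel_shift()` offers against wrap-around artifacts is
disabled for calibration, because windowing a target that moves across the
frame biases the measured shift. Second, the simulated tip carries a
chirped (zone-plate-like) internal texture and a ~1-pixel smooth rolloff at
its base: a perfectly smooth, sharp-edged solid has almost no correlation
curvature along one axis and aliases under subpixel sampling along the
other, while a *periodic* texture produces correlation peaks at every
multiple of its period and mislocates large shifts — a chirp's
autocorrelation has a single sharp peak. Real tips have texture and a
finite detector point-spread function; the simulated texture's finest zone
is kept at about six pixels so it samples cleanly at any detector
resolution. The
round-trip requirement is 0.5% on noiseless images and 2% at noise
σ = 0.05; the feedback loop is in any case insensitive to calibration
errors of this size, which is one of the reasons the original procedure
iterates rather than correcting open-loop.

## Feedback alignment

One `align_once()` pass at the current rotation: acquire, segment, clean,
fit; if the measured offset or tilt exceeds tolerance, command a goniometer
correction of $-\theta_s$ on the plane's axis and a lab-frame translation of
$-c_2 \cdot \mathrm{pix}_x$. The translation additionally subtracts the
first-order lateral shift that the commanded tilt will induce at the image
center, $h \tan\Delta\theta$, where $h$ is the height of the image center
above the goniometer pivot. This pivot height is exactly known to the
controller — it is the y-motor readback plus a hardware constant — so the
compensation uses stage knowledge only, never the hidden specimen pose. With
it, a fully visible specimen is corrected in a single pass and verified in
the next, giving the canonical two iterations per plane; without it, every
tilted load would spend an extra pass purely on the pivot shift. Residual
errors of the compensation (second-order tilt terms, fit error on clipped
silhouettes) are picked up by the next feedback pass, so the loop retains
the robustness that motivates feedback in the first place.

The angle the fit can actually resolve is bounded by the pixel grid: one
pixel of lateral drift across the rows used, about
$\arctan(1/n_\mathrm{rows})$ — 0.028° on a 2048-row detector but 0.11° on
the 512-row desk-scale one. Commands below this resolution chase the
quantization staircase of the labeled silhouette (see the limitations
section), and each spurious tilt command injects a pivot-lever translation
error of $h\tan\theta$ (∼12 µm at a 6 mm lever), which would eat the whole
centering budget. The controller therefore never commands a tilt smaller
than twice the current fit's angular resolution, and judges angular
convergence at the same effective tolerance,
$\max(\texttt{tol\_angle},\ 2\,\rho)$; on the reference detector this
reduces exactly to the nominal tolerance.

`align_sample()` iterates at 0° until both $|c_2 \cdot \mathrm{pix}_x| <$
`tol_offset` (default 10 µm) and $|\theta_s|$ is inside the effective
angular tolerance (`tol_angle` default 0.1°, chosen as the angle that
displaces a 6 mm half-length by about 10 µm — the instrument's angular
tolerance is not documented), then repeats at 90°, then
re-checks 0° once if the 90° pass commanded any motion. With the goniometer
axis convention above the two planes are exactly decoupled, so the re-check
is a verification pass; it exists because the protocol description does not
say whether planes are revisited, and one verification is cheap insurance.
An *iteration* is one acquire–measure pass: a perfectly placed specimen
converges in one iteration per plane with no moves. Loads whose silhouette
is partially clipped by the field of view need a third (occasionally fourth
or fifth) pass, because a clipped center-of-mass fit underestimates both
offset and tilt; this is the regime responsible for degraded precision on
specimens wider than the field of view, flagged via the per-fit
`clipped_frac` diagnostic. Specimens that vertically fill the detector
(`out_of_fov`) are the *normal* case for femur-length samples and fit fine.

## Length measurement and region of interest

The specimen length is measured entirely from y-motor positions: step the
stage in half-image increments until the top edge of the sample region
enters the view, center that edge with fine moves of
$-Y_{max} \cdot \mathrm{pix}_y$, record the absolute motor position, and
repeat downward for the bottom edge; the length is the difference of the
two motor readings. The fine centering iterates (up to five times) until
the measured edge is within 0.5 rows of the image center: terminating on
the measured edge position rather than on a fixed move count keeps the
result insensitive to the assumed pixel size (a 5% pixel-size error changes
the measured length by well under a pixel), which is the design goal of a
stage-referenced measurement. `goto_roi()` then places the image center at
`roi_fraction` (default 0.56) of the measured length above the bottom-edge
motor position.

Two known biases: the edge-enhancement band at the wax top extends the
qualifying sample region downward by roughly the fringe width (a constant
offset of order 10–40 µm in the bottom-edge position, which cancels in
repeatability statistics but appears in absolute length under fringed
conditions); and the edge detector quantizes to whole rows, bounding the
noiseless length error by about two pixels in total.

## The sequencer and the precision harness

`run_batch()` executes a minimal line-oriented script (`load`, `align`,
`roi`, `scan`, `unload`, `wait`, `repeat … end` — the original scripting
language's grammar is not published, so this grammar is original to the
package) against the virtual system, logging every step exactly once with a
terminal status, a stage snapshot, a per-step seed for replay, and a
simulated clock (waits advance the clock; nothing sleeps). Step failures
follow a configurable policy: abort, skip to the next sample, or continue.

`precision_study()` is the repeat-loading harness: n times load-with-random-
displacement, align, measure length, move to the region of interest, and
record the final x, y, z motor positions; the standard deviations of those
positions over repetitions are the alignment precision, because the stage is
the absolute reference. Non-convergent repetitions are excluded with a
warning. At study conditions (512 px detector, noise 0.02, fringe on, full
one-FOV displacements, 20 repetitions) the virtual system reproduces the
qualitative behavior expected of the instrument: sub-15 µm spread on all
three axes for specimens that fit the field of view, with the spread driven
by mount noise, edge quantization and fit jitter; specimens wider than the
field of view degrade gracefully rather than failing.

## Known numerical limitations

One behavior of the threshold pipeline deserves explicit mention: at
near-zero noise combined with a strong edge fringe, the labeled silhouette
boundary coincides with the pixel-quantized phase edge, and the resulting
staircase in the per-row centers of mass can bias the fitted tilt by several
tenths of a degree with a sign that flips after each correction — a limit
cycle in which the loop chases its own quantization error and convergence
on the angle may fail. Realistic noise levels (σ ≳ 0.01) dither the edge and
break the lock; the degenerate regime only arises in noise-free simulation
with the fringe amplitude above the sample threshold. The repeat-precision
and batch studies run at σ = 0.02, where the effect is absent.

## What the synthetic data does and does not show

The phantom captures the features the algorithms actually consume —
three-phase absorption contrast, near-cylindrical geometry with elliptical
cross-section, wax fringes that defeat naive thresholding, noise,
saturation, partial visibility — under exactly known pose, so tests can
assert recovery of truth (tilt to 0.05°, offset to one pixel, length to two
pixels). It does not model Fresnel propagation beyond the heuristic fringe
band, polychromatic beam hardening, anisotropic real bone shape (a femur is
not an ellipse, so center-of-mass alignment and edge alignment genuinely
differ on real data), specimen motion, or detector defects. Passing tests
therefore validate the *algorithms and their closed-loop logic*, not the
segmentation thresholds for any particular real material — those remain the
user-tunable parameters they are on the instrument.

## Problem sizes used in the shipped studies

The packaged tests run the precision study at 20 repetitions on a 512 px
detector, the convergence study at 50 routine loads on 256 px, and the
20-sample batch-centering study on 512 px; unit tests use 64–256 px
detectors and a 2048-row strip for the extent convention. These sizes were
chosen so the full suite completes in minutes on a laptop while keeping the
study-scale geometry (field of view, specimen dimensions, noise and fringe
levels) identical to the reference configuration.
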