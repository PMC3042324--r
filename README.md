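# projalign

Projection-image-based automatic sample alignment for tomographic
microscopy, with a complete virtual beamline for hardware-free testing.

## The problem

High-throughput tomographic microscopy measures hundreds to thousands of
near-cylindrical specimens (the motivating case: mouse femurs, about
12 × 1.1 × 1.2 mm, imaged in a 1.5 mm field of view at sub-micrometre pixel
size). Every specimen must be centered on the rotation axis, oriented
vertically, and scanned at a consistent fractional height (e.g. 56% of
femur length) so results are comparable across animals. `projalign`
implements the image-based pipeline that automates this:

1. **Segmentation** — three-component threshold labeling of each projection
   into air, sample and holder, plus cleaning of rows where fewer than 5% of
   pixels are above threshold (removes wax edge-enhancement artifacts).
2. **Quantification** — per-row statistics (phase fractions
   *P<sub>s</sub>*, *P<sub>a</sub>*, *P<sub>m</sub>*, *P<sub>sat</sub>*;
   mean and variance of the sample-pixel x positions) and an ordinary
   least-squares fit of the per-row centers of mass,
   x̄(y) = c₁·y + c₂, giving the centering offset c₂·pix_x and the tilt
   θ_s = atan(c₁·pix_x/pix_y).
3. **Feedback alignment** — at 0° and 90°, translate by −c₂·pix_x and tilt
   the base-pivoted goniometer by −θ_s, re-measure, and repeat until both
   residuals are inside tolerance (10 µm, 0.1° by default).
4. **Length & ROI** — step the y motor in half-image increments until the
   specimen's top (then bottom) edge sits at the image center; the length is
   the difference of the two absolute motor positions, and the field of view
   is then moved to a fraction of that length.
5. **Calibration** — effective pixel sizes (mm/pixel) from subpixel
   cross-correlation of a cone-tip target moved known distances.
6. **Sequencer** — a scripted batch runner (`load / align / roi / scan /
   unload / wait / repeat`) and a repeat-loading precision harness that
   reports the standard deviation of final stage positions.

Everything runs against a **virtual beamline**: a Beer–Lambert projection
simulator for mounted cylindrical phantoms (edge-enhancement fringes,
Gaussian noise, saturation) and a motorized-stage model (rotation-aware x/z
motor commands, ±10° two-axis goniometer pivoting at the sample base,
0.38 µm kinematic-mount placement noise). The simulator knows the true pose,
so every algorithm is testable against ground truth.

## Worked example

```r
library(projalign)

# the study conditions at desk scale: 1.5 mm field of view on 512 px
det <- detector_config(512, 512, pix_x = 1500/512, pix_y = 1500/512,
                       noise_sigma = 0.02, fringe_amplitude = 0.5,
                       fringe_width_px = 4)
femur <- phantom_sample()        # 12 x 1.1 x 1.2 mm, wax + holder mount

# robot load with a random displacement up to one field of view
st <- load_sample(femur, placement_model(seed = 7))
bl <- virtual_beamline(femur, st, det)

res <- align_sample(bl)
res$result
#> <alignment_result> converged | iterations (0/90 deg): 3/3 |
#>   residual offset -0.00/-0.00 um | residual angle -0.0000/-0.0000 deg

lm_ <- measure_length(res$bl)
lm_$length_mm
#> [1] 12.03662
bl <- lm_$bl
bl$stage <- goto_roi(bl$stage, lm_$length_mm, lm_$state_bottom)
bl$stage
#> <stage_state> x=-1.32 y=-6702.06 z=0.12 um | omega=0.0 deg | gonio u=0.644 v=-1.887 deg
```

The alignment measured the specimen offset and tilt from the projections,
drove the motors until both were inside the 10 µm / 0.1° tolerances
(three measure–correct passes per plane here, because the initial random
offset clipped the silhouette at the image border), measured the length by
scanning the y stage (12.037 mm vs the true 12 mm; the ~37 µm excess is the
constant wax-fringe bias discussed in the vignette), and parked the field of
view at 56% of the measured length above the bottom edge. The final motor
positions (within a few µm of zero, cancelling the hidden placement offset;
the goniometer holding the wax-placement tilts) are what the precision
harness records across repeated loads:

```r
ps <- precision_study(femur, n_reps = 20, det = det, seed = 101)
ps
#> <precision_study> n=20 | length 12.04 +/- 0.001 mm | X 0.9 +/- 3.62 um |
#>   Y -6703.0 +/- 0.82 um | Z 0.8 +/- 4.38 um
```

The instrument-scale benchmark for in-FOV specimens is a sub-15 µm spread
on all axes; the virtual system sits at a few µm because only mount noise,
edge quantization, fit jitter and the centering tolerance itself remain.

Command-line wrappers live in `inst/cli/` (`align.R`, `seq.R`); both read
phantom/detector/parameter YAML files written by `write_config_yaml()`.

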