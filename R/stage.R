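#' Virtual motorized stage state
#'
#' Models the sample stage: x and z sample motors and the two-axis goniometer
#' ride on top of the rotation stage (angle `omega`), while the y motor moves
#' the whole assembly vertically. The goniometer pivots about a horizontal
#' axis at the sample base, so tilting re-orients the specimen without moving
#' its base. The hidden `true_pose` carries the placement error of the current
#' load (mount noise and wax tilts) and exists only so the simulator can act
#' as a ground-truth oracle; alignment code never reads it.
#'
#' Sign conventions: positive x is rightward on the 0-degree image, positive y
#' upward, positive z along the beam at 0 degrees. A positive fitted offset
#' `c2` (sample right of image center) is corrected by a negative lab-frame
#' x move.
#'
#' @param x,y,z Motor positions (micrometres).
#' @param omega Rotation-stage angle (degrees).
#' @param gonio_u,gonio_v Goniometer tilts (degrees), `u` acting in the
#'   0-degree image plane and `v` in the 90-degree plane; each limited to
#'   +/-10 degrees.
#' @param pivot_y Lab height of the goniometer pivot (sample bottom) when the
#'   y motor reads 0 (micrometres).
#' @param true_pose List with hidden placement error: `dx`, `dy`, `dz`
#'   (micrometres, stage frame) and `tilt_x`, `tilt_z` (degrees).
#' @return An object of class `stage_state`.
#' @export
stage_state <- function(x = 0, y = 0, z = 0, omega = 0,
                        gonio_u = 0, gonio_v = 0, pivot_y = 0,
                        true_pose = NULL) {
  if (is.null(true_pose))
    true_pose <- list(dx = 0, dy = 0, dz = 0, tilt_x = 0, tilt_z = 0)
  stopifnot(all(is.finite(c(x, y, z, omega, gonio_u, gonio_v, pivot_y))),
            all(is.finite(unlist(true_pose))))
  if (abs(gonio_u) > 10 || abs(gonio_v) > 10)
    stop("goniometer tilts must be within +/-10 degrees")
  structure(list(x = x, y = y, z = z, omega = omega,
                 gonio_u = gonio_u, gonio_v = gonio_v,
                 pivot_y = pivot_y, true_pose = true_pose),
            class = "stage_state")
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf(
    "<stage_state> x=%.2f y=%.2f z=%.2f um | omega=%.1f deg | gonio u=%.3f v=%.3f deg\n",
    x$x, x$y, x$z, x$omega, x$gonio_u, x$gonio_v))
  invisible(x)
}

#' Robot placement model
#'
#' Describes how a robot load perturbs the sample: sub-micrometre kinematic
#' mount repeatability, a commanded random initial stage offset (emulating the
#' repeat-precision protocol where each load is moved up to one field of view
#' away from the aligned position), and random wax-placement tilts.
#'
#' @param mount_sigma Kinematic-mount repeatability (micrometres, 1 sigma).
#' @param max_initial_offset Maximum commanded initial offset (micrometres);
#'   the default is one 1.5 mm field of view.
#' @param tilt_range Placement tilts are drawn uniformly in
#'   `[-tilt_range, tilt_range]` degrees per load.
#' @param seed Optional integer seed used by [load_sample()].
#' @return An object of class `placement_model`.
#' @export
placement_model <- function(mount_sigma = 0.38, max_initial_offset = 1500,
                            tilt_range = 2, seed = NULL) {
  stopifnot(mount_sigma >= 0, max_initial_offset >= 0, tilt_range >= 0)
  structure(list(mount_sigma = mount_sigma,
                 max_initial_offset = max_initial_offset,
                 tilt_range = tilt_range, seed = seed),
            class = "placement_model")
}

rot_y <- function(v, omega_deg) {
  om <- omega_deg * pi / 180
  c(cos(om) * v[1] + sin(om) * v[3], v[2],
    -sin(om) * v[1] + cos(om) * v[3])
}

# Lab-frame geometry of the posed specimen: base point (um), unit axis and
# cross-section basis vectors. The specimen axis combines the intrinsic wax
# tilt, the per-load placement tilt and the goniometer correction as slopes
# about the base pivot, then everything on the rotation stage is rotated by
# omega about the vertical rotation axis (lab origin).
sample_pose <- function(sample, stage) {
  tp <- stage$true_pose
  tx <- (sample$axis_tilt_x + tp$tilt_x + stage$gonio_u) * pi / 180
  tz <- (sample$axis_tilt_z + tp$tilt_z + stage$gonio_v) * pi / 180
  ax <- c(tan(tx), 1, tan(tz))
  ax <- ax / sqrt(sum(ax^2))
  e2 <- c(0, ax[3], -ax[2])
  e2 <- e2 / sqrt(sum(e2^2))
  e1 <- c(e2[2] * ax[3] - e2[3] * ax[2],
          e2[3] * ax[1] - e2[1] * ax[3],
          e2[1] * ax[2] - e2[2] * ax[1])
  base <- c(stage$x + sample$base_offset_x + tp$dx,
            stage$y + stage$pivot_y + tp$dy,
            stage$z + sample$base_offset_z + tp$dz)
  om <- stage$omega
  list(base = rot_y(base, om), axis = rot_y(ax, om),
       e1 = rot_y(e1, om), e2 = rot_y(e2, om))
}

#' Move a stage axis by a lab-frame displacement
#'
#' The x and z sample motors sit on the rotation stage, so a displacement
#' requested in the lab frame (the frame of the projection image) is converted
#' to motor coordinates by rotating it by `-omega` before being applied. This
#' is the command library that "takes the vertical rotation of the stage into
#' account": a lab-frame request moves the projected image predictably at any
#' rotation angle. The y motor is applied directly.
#'
#' @param state A [stage_state()].
#' @param axis One of `"x"`, `"y"`, `"z"` (lab-frame axes; `"x"` is transverse
#'   to the beam at 0 degrees, `"z"` along it).
#' @param delta Displacement in micrometres (finite).
#' @return The updated `stage_state`.
#' @export
move_axis <- function(state, axis = c("x", "y", "z"), delta) {
  axis <- match.arg(axis)
  if (!is.finite(delta)) stop("move delta must be finite")
  if (axis == "y") {
    state$y <- state$y + delta
    return(state)
  }
  lab <- if (axis == "x") c(delta, 0) else c(0, delta)
  om <- state$omega * pi / 180
  # rotate the lab-frame request by -omega into motor coordinates
  state$x <- state$x + cos(om) * lab[1] - sin(om) * lab[2]
  state$z <- state$z + sin(om) * lab[1] + cos(om) * lab[2]
  state
}

#' Tilt a goniometer axis about the sample-base pivot
#'
#' The goniometer radius of rotation is aligned with the bottom of the sample,
#' so a tilt changes the specimen orientation without moving its base; a point
#' at height `h` above the pivot displaces laterally by about `h * sin(dtheta)`.
#' Travel is limited to +/-10 degrees per axis.
#'
#' @param state A [stage_state()].
#' @param axis `"u"` (acts in the 0-degree image plane) or `"v"` (90-degree
#'   plane).
#' @param dtheta Tilt increment (degrees).
#' @return The updated `stage_state`.
#' @export
tilt_goniometer <- function(state, axis = c("u", "v"), dtheta) {
  axis <- match.arg(axis)
  if (!is.finite(dtheta)) stop("tilt increment must be finite")
  cur <- if (axis == "u") state$gonio_u else state$gonio_v
  target <- cur + dtheta
  if (abs(target) > 10) {
    room <- 10 * sign(dtheta) - cur
    stop(sprintf("goniometer %s range exceeded: remaining travel %.3f degrees",
                 axis, room))
  }
  if (axis == "u") state$gonio_u <- target else state$gonio_v <- target
  state
}

#' Set the rotation-stage angle
#'
#' @param state A [stage_state()].
#' @param omega_new New rotation angle (degrees).
#' @return The updated `stage_state`; the projected geometry follows from the
#'   unchanged true pose.
#' @export
rotate_stage <- function(state, omega_new) {
  if (!is.finite(omega_new)) stop("omega must be finite")
  state$omega <- omega_new
  state
}

#' Load a sample onto the virtual stage
#'
#' Emulates a robot load followed by the repeat-precision protocol's random
#' initial displacement: the hidden true pose receives Gaussian kinematic-
#' mount noise (`mount_sigma`) and uniform placement tilts (`tilt_range`),
#' while the stage motors are commanded to a random position within
#' `max_initial_offset` of the nominal pose. The commanded offset is uniform
#' in `[-max/2, max/2]` for x and z (so part of the specimen remains in the
#' field of view) and `[-max, max]` for y. The nominal vertical position views
#' mid-specimen: stage y starts at `-length/2`, with the goniometer pivot at
#' the sample base (`pivot_y = 0`).
#'
#' @param sample A [phantom_sample()].
#' @param pm A [placement_model()].
#' @param seed Optional integer seed (defaults to `pm$seed`); `NULL` uses the
#'   current RNG stream.
#' @return A [stage_state()] describing the freshly loaded sample.
#' @export
load_sample <- function(sample, pm = placement_model(), seed = pm$seed) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  m <- pm$max_initial_offset
  tp <- list(dx = stats::rnorm(1, 0, pm$mount_sigma),
             dy = stats::rnorm(1, 0, pm$mount_sigma),
             dz = stats::rnorm(1, 0, pm$mount_sigma),
             tilt_x = stats::runif(1, -pm$tilt_range, pm$tilt_range),
             tilt_z = stats::runif(1, -pm$tilt_range, pm$tilt_range))
  stage_state(
    x = stats::runif(1, -m / 2, m / 2),
    y = -sample$length * 1000 / 2 + stats::runif(1, -m, m),
    z = stats::runif(1, -m / 2, m / 2),
    omega = 0, gonio_u = 0, gonio_v = 0, pivot_y = 0,
    true_pose = tp)
}
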