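#' Alignment parameters
#'
#' Tolerances and protocol constants for the feedback alignment, length
#' measurement and region-of-interest placement.
#'
#' @param tol_offset Centering tolerance (micrometres, default 10).
#' @param tol_angle Angular tolerance (degrees, default 0.1 -- the angle that
#'   displaces a 6 mm half-length by about 10 um).
#' @param max_iter Maximum feedback iterations per plane (default 5).
#' @param p_min Minimum per-row sample fraction shared by row cleaning,
#'   axis-fit qualification and extent detection (default 0.05).
#' @param roi_fraction Region of interest as a fraction of specimen length
#'   from the bottom end (default 0.56).
#' @param step_fraction Vertical scan step during length measurement, as a
#'   fraction of the image height (default 0.5: half-image steps).
#' @return An object of class `align_params`.
#' @export
align_params <- function(tol_offset = 10, tol_angle = 0.1, max_iter = 5,
                         p_min = 0.05, roi_fraction = 0.56,
                         step_fraction = 0.5) {
  stopifnot(tol_offset > 0, tol_angle > 0, max_iter >= 1,
            p_min >= 0, p_min <= 1,
            roi_fraction > 0, roi_fraction < 1,
            step_fraction > 0, step_fraction <= 1)
  structure(list(tol_offset = tol_offset, tol_angle = tol_angle,
                 max_iter = as.integer(max_iter), p_min = p_min,
                 roi_fraction = roi_fraction, step_fraction = step_fraction),
            class = "align_params")
}

#' Assemble a virtual beamline
#'
#' Bundles a phantom, stage state, detector, segmentation thresholds and
#' pixel calibration into one object that the alignment and sequencing
#' routines drive. When no calibration is given the detector's nominal pixel
#' sizes are used.
#'
#' @param sample A [phantom_sample()].
#' @param stage A [stage_state()].
#' @param det A [detector_config()].
#' @param th A [thresholds()] object.
#' @param cal A [calibration()] (mm/pixel), or `NULL` for nominal.
#' @return An object of class `virtual_beamline`.
#' @export
virtual_beamline <- function(sample, stage, det, th = thresholds(),
                             cal = NULL) {
  if (is.null(cal)) cal <- calibration(det$pix_x / 1000, det$pix_y / 1000)
  structure(list(sample = sample, stage = stage, det = det, th = th,
                 cal = cal), class = "virtual_beamline")
}

#' Acquire a projection at the current stage position
#'
#' @param bl A [virtual_beamline()].
#' @param seed Optional seed forwarded to [render_projection()].
#' @return A [projection_image()].
#' @export
acquire <- function(bl, seed = NULL) {
  render_projection(bl$sample, bl$stage, bl$det, seed = seed)
}

# acquire + segment + clean + row statistics at the current pose
measure_profiles <- function(bl, params) {
  img <- acquire(bl)
  lab <- clean_rows(segment(img, bl$th), params$p_min)
  row_statistics(lab)
}

# which goniometer axis (and projection coefficient) corrects the tilt seen
# at the current rotation angle; u acts in the 0-degree plane, v at 90
plane_gonio <- function(omega) {
  cu <- cos(omega * pi / 180)
  cv <- sin(omega * pi / 180)
  if (abs(cu) >= abs(cv)) list(axis = "u", coef = cu) else list(axis = "v", coef = cv)
}

clamp_gonio_delta <- function(state, axis, dtheta) {
  cur <- if (axis == "u") state$gonio_u else state$gonio_v
  target <- max(-10, min(10, cur + dtheta))
  list(delta = target - cur, limited = (target != cur + dtheta))
}

#' One feedback alignment step at the current rotation angle
#'
#' Acquires a projection, segments and cleans it, fits the specimen axis, and
#' (if outside tolerance) commands a goniometer correction of `-theta_s` on
#' the axis associated with the current plane together with a lab-frame
#' translation of `-c2 * pix_x`. The translation additionally compensates, to
#' first order, the lateral shift that the commanded tilt induces at the
#' image center, using the exactly-known height of the image center above the
#' goniometer pivot (stage readback plus a hardware constant); residual
#' errors are picked up by the next feedback pass.
#'
#' @param bl A [virtual_beamline()].
#' @param params An [align_params()].
#' @return A list with the updated beamline `bl`, the `fit` used
#'   ([fit_axis()] output), `offset_um` (the measured lab-frame offset),
#'   `within_tol` (whether the measurement was already inside both
#'   tolerances, in which case nothing was commanded), the commanded
#'   `moves` (`dx_um`, `dtheta`), and `gonio_limited`.
#' @export
align_once <- function(bl, params = align_params()) {
  prof <- measure_profiles(bl, params)
  fit <- fit_axis(prof, bl$cal, params$p_min)
  offset_um <- fit$c2 * bl$cal$pix_x * 1000
  # angular resolution of the center-of-mass fit: one pixel of lateral
  # drift across the rows used. Commanding tilts below it chases the
  # pixel-quantization staircase of the labeled silhouette, and each such
  # command injects a pivot-lever translation error, so the effective
  # angle tolerance is never tighter than twice this resolution. At the
  # reference 2048-row detector it reduces to the nominal tolerance.
  ang_res <- atan((bl$cal$pix_x / bl$cal$pix_y) / fit$n_rows_used) * 180 / pi
  tol_angle_eff <- max(params$tol_angle, 2 * ang_res)
  within <- abs(offset_um) < params$tol_offset &&
    abs(fit$theta_s) < tol_angle_eff
  moves <- list(dx_um = 0, dtheta = 0)
  limited <- FALSE
  if (!within) {
    pg <- plane_gonio(bl$stage$omega)
    dtheta <- 0
    if (abs(fit$theta_s) >= tol_angle_eff) {
      want <- -fit$theta_s / pg$coef
      cl <- clamp_gonio_delta(bl$stage, pg$axis, want)
      dtheta <- cl$delta
      limited <- cl$limited
      if (dtheta != 0)
        bl$stage <- tilt_goniometer(bl$stage, pg$axis, dtheta)
    }
    # pivot height is below the image center by (stage y + pivot constant)
    h <- -(bl$stage$y + bl$stage$pivot_y)
    dx <- -offset_um - h * tan(dtheta * pg$coef * pi / 180)
    bl$stage <- move_axis(bl$stage, "x", dx)
    moves <- list(dx_um = dx, dtheta = dtheta)
  }
  list(bl = bl, fit = fit, offset_um = offset_um, within_tol = within,
       moves = moves, gonio_limited = limited)
}

#' Full feedback alignment at 0 and 90 degrees
#'
#' Repeats [align_once()] at 0 degrees until both the centering offset and
#' the tilt are within tolerance (or `max_iter` passes), rotates to 90
#' degrees and repeats, then re-checks the 0-degree plane once if the
#' 90-degree pass commanded any correction. An iteration is one
#' acquire-fit pass; a perfectly placed sample therefore converges in one
#' iteration per plane with no moves.
#'
#' @param bl A [virtual_beamline()].
#' @param params An [align_params()].
#' @return A list with the aligned `bl` and `result`, an `alignment_result`
#'   containing `final_state`, `iterations_per_plane` (0- and 90-degree
#'   feedback passes), `residual_offset_um` and `residual_angle` per plane,
#'   `converged`, `out_of_fov`, `clipped_frac` and the full per-pass `trace`.
#' @export
align_sample <- function(bl, params = align_params()) {
  planes <- c(0, 90)
  iters <- integer(2)
  resid_off <- resid_ang <- rep(NA_real_, 2)
  plane_ok <- c(FALSE, FALSE)
  trace <- list()
  any_limited <- FALSE
  out_of_fov <- FALSE
  clipped <- 0
  run_plane <- function(bl, omega, count_iters = TRUE, idx) {
    bl$stage <- rotate_stage(bl$stage, omega)
    moved_any <- FALSE
    for (it in seq_len(params$max_iter)) {
      step <- align_once(bl, params)
      bl <- step$bl
      if (count_iters) iters[idx] <<- it
      trace[[length(trace) + 1]] <<- list(
        omega = omega, pass = it, recheck = !count_iters, fit = step$fit,
        offset_um = step$offset_um, moves = step$moves)
      any_limited <<- any_limited || step$gonio_limited
      out_of_fov <<- out_of_fov || step$fit$out_of_fov
      clipped <<- max(clipped, step$fit$clipped_frac)
      resid_off[idx] <<- step$offset_um
      resid_ang[idx] <<- step$fit$theta_s
      plane_ok[idx] <<- step$within_tol
      if (step$within_tol) break
      moved_any <- TRUE
    }
    list(bl = bl, moved = moved_any)
  }
  p0 <- run_plane(bl, 0, TRUE, 1)
  p90 <- run_plane(p0$bl, 90, TRUE, 2)
  bl <- p90$bl
  if (p90$moved) {            # one verification pass back at 0 degrees
    chk <- run_plane(bl, 0, FALSE, 1)
    bl <- chk$bl
  }
  converged <- all(plane_ok)
  result <- structure(list(
    final_state = bl$stage,
    iterations_per_plane = iters,
    residual_offset_um = resid_off,
    residual_angle = resid_ang,
    converged = converged,
    gonio_limited = any_limited,
    out_of_fov = out_of_fov,
    clipped_frac = clipped,
    trace = trace), class = "alignment_result")
  list(bl = bl, result = result)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %s | iterations (0/90 deg): %d/%d | residual offset %.2f/%.2f um | residual angle %.4f/%.4f deg\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations_per_plane[1], x$iterations_per_plane[2],
    x$residual_offset_um[1], x$residual_offset_um[2],
    x$residual_angle[1], x$residual_angle[2]))
  invisible(x)
}

# step the y motor until the requested specimen edge is inside the field of
# view, then center it with fine moves of -edge * pix_y. The fine loop stops
# on the measured edge position (0.5 rows), so the final accuracy is set by
# the stage moves, not by the assumed pixel size.
seek_edge <- function(bl, params, which = c("top", "bottom"), max_travel) {
  which <- match.arg(which)
  fov_h <- bl$det$n_rows * bl$det$pix_y
  top_row <- (bl$det$n_rows - 1) / 2
  dir <- if (which == "top") -1 else 1     # sample down to reveal its top
  get_edge <- function() {
    ext <- find_extent(measure_profiles(bl, params), params$p_min)
    unname(if (which == "top") ext["y_max"] else ext["y_min"])
  }
  travel <- 0
  repeat {
    edge <- get_edge()
    at_border <- if (which == "top") edge >= top_row else edge <= -top_row
    if (!at_border) break
    bl$stage <- move_axis(bl$stage, "y", dir * params$step_fraction * fov_h)
    travel <- travel + params$step_fraction * fov_h
    if (travel > max_travel)
      stop(sprintf("%s edge of the sample not found within the travel budget (%g um)",
                   which, max_travel))
  }
  for (k in 1:5) {
    if (abs(edge) <= 0.5) break
    bl$stage <- move_axis(bl$stage, "y", -edge * bl$det$pix_y)
    edge <- get_edge()
  }
  bl
}

#' Measure the specimen length with the y stage
#'
#' Steps the y motor in `step_fraction`-image increments until the top edge of
#' the specimen enters the field of view, applies fine moves of
#' `-Y_max * pix_y` until the edge sits at the image center (within 2 rows),
#' and records the absolute motor position; then repeats in the opposite
#' direction for the bottom edge. The length is the difference of the two
#' absolute y motor positions, so its accuracy rests on the stage rather than
#' on the pixel-size estimate. Specimens shorter than the field of view are
#' handled without coarse steps.
#'
#' @param bl An aligned [virtual_beamline()].
#' @param params An [align_params()].
#' @param max_travel Travel budget per edge search (micrometres).
#' @return A list with `length_mm`, the [stage_state()]s `state_top` and
#'   `state_bottom` at the two edge positions, and the beamline `bl` left at
#'   the bottom-edge position.
#' @export
measure_length <- function(bl, params = align_params(), max_travel = 50000) {
  bl <- seek_edge(bl, params, "top", max_travel)
  state_top <- bl$stage
  bl <- seek_edge(bl, params, "bottom", max_travel)
  state_bottom <- bl$stage
  list(length_mm = (state_bottom$y - state_top$y) / 1000,
       state_top = state_top, state_bottom = state_bottom, bl = bl)
}

#' Move the field of view to a fractional-length region of interest
#'
#' Positions the y motor so the image center sits at `roi_fraction` of the
#' measured specimen length above the bottom (reference) end;
#' `roi_fraction = 0` centers the field of view on the reference edge itself.
#'
#' @param state A [stage_state()] (typically the beamline's current state).
#' @param length_mm Measured specimen length (mm).
#' @param edge_state The [stage_state()] recorded with the bottom edge at the
#'   image center (`state_bottom` of [measure_length()]).
#' @param params An [align_params()] supplying `roi_fraction`.
#' @param max_travel Motor travel limit (micrometres).
#' @return The updated `stage_state` at the region of interest.
#' @export
goto_roi <- function(state, length_mm, edge_state, params = align_params(),
                     max_travel = 50000) {
  y_target <- edge_state$y - params$roi_fraction * length_mm * 1000
  if (abs(y_target) > max_travel)
    stop("region of interest lies outside the motor travel limit")
  move_axis(state, "y", y_target - state$y)
}
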