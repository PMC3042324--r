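#' Define an approximately cylindrical mounted specimen phantom
#'
#' Describes a specimen of elliptical cross-section (a mouse-femur-like rod,
#' default 12 x 1.1 x 1.2 mm) glued with wax onto a high-absorbing metal holder
#' pin. The three phases (sample, wax-as-air, holder) are what the threshold
#' segmentation distinguishes. All geometry is in mm; absorption coefficients
#' are optical depth per mm of path.
#'
#' @param length Specimen length along its axis (mm).
#' @param radius_x,radius_z Semi-axes of the elliptical cross-section (mm);
#'   `radius_x` lies in the 0-degree image plane, `radius_z` along the beam at
#'   0 degrees.
#' @param axis_tilt_x,axis_tilt_z True tilt of the specimen axis from vertical
#'   (degrees), in the two stage-frame planes. Must be within +/-45 degrees.
#' @param base_offset_x,base_offset_z True displacement of the specimen base
#'   from the rotation axis (micrometres); a fixed property of how the specimen
#'   was waxed onto its holder.
#' @param mu_sample,mu_wax,mu_holder Absorption coefficients (per mm). Must
#'   satisfy `mu_holder > mu_sample > mu_wax >= 0`.
#' @param wax_height,wax_radius Wax mound below the specimen base (mm).
#' @param holder_radius,holder_height Metal holder pin below the wax (mm).
#' @param marker_fraction Optional axial position (fraction of `length`) of a
#'   dense embedded marker band, used as a ground-truth landmark in
#'   region-of-interest tests. `NULL` for no marker.
#' @param marker_mu,marker_height Extra absorption (per mm) and axial height
#'   (mm) of the marker band.
#' @return An object of class `phantom_sample`.
#' @seealso [render_projection()], [detector_config()]
#' @export
phantom_sample <- function(length = 12, radius_x = 0.55, radius_z = 0.6,
                           axis_tilt_x = 0, axis_tilt_z = 0,
                           base_offset_x = 0, base_offset_z = 0,
                           mu_sample = 1.5, mu_wax = 0.1, mu_holder = 50,
                           wax_height = 1, wax_radius = 0.9,
                           holder_radius = 0.4, holder_height = 2,
                           marker_fraction = NULL, marker_mu = 3,
                           marker_height = 0.05) {
  stopifnot(length > 0, radius_x > 0, radius_z > 0,
            wax_height >= 0, wax_radius >= 0,
            holder_radius >= 0, holder_height >= 0)
  if (!(mu_holder > mu_sample && mu_sample > mu_wax && mu_wax >= 0))
    stop("absorption coefficients must satisfy mu_holder > mu_sample > mu_wax >= 0")
  if (abs(axis_tilt_x) > 45 || abs(axis_tilt_z) > 45)
    stop("|axis_tilt_x| and |axis_tilt_z| must be <= 45 degrees")
  if (!is.null(marker_fraction))
    stopifnot(marker_fraction > 0, marker_fraction < 1, marker_mu > 0)
  structure(list(
    length = length, radius_x = radius_x, radius_z = radius_z,
    axis_tilt_x = axis_tilt_x, axis_tilt_z = axis_tilt_z,
    base_offset_x = base_offset_x, base_offset_z = base_offset_z,
    mu_sample = mu_sample, mu_wax = mu_wax, mu_holder = mu_holder,
    wax_height = wax_height, wax_radius = wax_radius,
    holder_radius = holder_radius, holder_height = holder_height,
    marker_fraction = marker_fraction, marker_mu = marker_mu,
    marker_height = marker_height
  ), class = "phantom_sample")
}

#' Virtual detector configuration
#'
#' Detector geometry and image-degradation model for the virtual beamline.
#' Defaults describe the reference microscope configuration: 2048 x 2048
#' pixels at 0.74 um pixel size (1.5 mm field of view). For desk-scale
#' simulation, shrink `n_rows`/`n_cols` and scale the pixel size up so the
#' field of view is preserved.
#'
#' @param n_rows,n_cols Detector size in pixels (>= 8).
#' @param pix_x,pix_y Effective pixel size (micrometres per pixel).
#' @param noise_sigma Standard deviation of Gaussian detector noise, in
#'   absorption units (post flat-field correction).
#' @param fringe_amplitude Peak amplitude (absorption units) of the
#'   edge-enhancement fringe straddling each phase boundary; 0 disables it.
#' @param fringe_width_px Width scale (pixels) of the fringe band.
#' @param saturation_level Absorption value at which pixels saturate (clip).
#' @param seed Optional integer; when set, [render_projection()] renders
#'   deterministically with this seed unless overridden per call.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(n_rows = 2048, n_cols = 2048,
                            pix_x = 0.74, pix_y = 0.74,
                            noise_sigma = 0.02, fringe_amplitude = 0.5,
                            fringe_width_px = 4, saturation_level = 3,
                            seed = NULL) {
  stopifnot(n_rows >= 8, n_cols >= 8, pix_x > 0, pix_y > 0,
            noise_sigma >= 0, fringe_width_px >= 0, saturation_level > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pix_x = pix_x, pix_y = pix_y,
                 noise_sigma = noise_sigma,
                 fringe_amplitude = fringe_amplitude,
                 fringe_width_px = fringe_width_px,
                 saturation_level = saturation_level,
                 seed = seed),
            class = "detector_config")
}

#' Construct a projection image
#'
#' A 2D absorption image (-log transmission, dimensionless) with pixel-size
#' metadata. The coordinate origin is at the image center, x rightward and y
#' upward; pixel centers sit at `i - (n + 1)/2` for 1-based index `i`, so an
#' even-sized detector has no pixel exactly at 0.
#'
#' @param pixels Numeric matrix of absorption values (rows = detector rows,
#'   row 1 at the top of the image).
#' @param pix_x,pix_y Pixel size (micrometres per pixel).
#' @param sat_mask Optional logical matrix marking saturated pixels
#'   (recorded before clipping).
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, pix_x, pix_y, sat_mask = NULL) {
  stopifnot(is.matrix(pixels), pix_x > 0, pix_y > 0)
  if (is.null(sat_mask)) sat_mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  stopifnot(identical(dim(sat_mask), dim(pixels)))
  structure(list(pixels = pixels, pix_x = pix_x, pix_y = pix_y,
                 sat_mask = sat_mask),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, %.3f x %.3f um/px, range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pix_x, x$pix_y,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# center-origin pixel coordinates (x rightward in um for columns,
# y upward in um for rows; row 1 is the top of the image)
pixel_x_um <- function(det) (seq_len(det$n_cols) - (det$n_cols + 1) / 2) * det$pix_x
pixel_y_um <- function(det) ((det$n_rows + 1) / 2 - seq_len(det$n_rows)) * det$pix_y

# Path length (um) of the z-directed ray through each pixel across a finite
# elliptical cylinder: base point `base` (um, lab frame), unit axis `axis`,
# cross-section basis e1/e2 with semi-axes r1/r2 (um), axial range [s0, s1]
# (um along the axis from the base). Vectorized over the pixel grids X, Y.
ray_path_cylinder <- function(X, Y, base, axis, e1, e2, r1, r2, s0, s1) {
  wx <- X - base[1]; wy <- Y - base[2]; wz <- -base[3]
  we1 <- wx * e1[1] + wy * e1[2] + wz * e1[3]
  we2 <- wx * e2[1] + wy * e2[2] + wz * e2[3]
  wu  <- wx * axis[1] + wy * axis[2] + wz * axis[3]
  d1 <- e1[3]; d2 <- e2[3]; du <- axis[3]
  a <- d1^2 / r1^2 + d2^2 / r2^2
  if (a < .Machine$double.eps)    # beam parallel to the axis: outside scope
    stop("ray parallel to the cylinder axis; tilt out of supported range")
  b <- 2 * (we1 * d1 / r1^2 + we2 * d2 / r2^2)
  cc <- we1^2 / r1^2 + we2^2 / r2^2 - 1
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  tlo <- (-b - sq) / (2 * a)
  thi <- (-b + sq) / (2 * a)
  if (abs(du) > 1e-12) {
    ta <- (s0 - wu) / du
    tb <- (s1 - wu) / du
    alo <- pmin(ta, tb); ahi <- pmax(ta, tb)
  } else {
    inside <- wu >= s0 & wu <= s1
    alo <- ifelse(inside, -Inf, Inf)
    ahi <- -alo
  }
  len <- pmax(0, pmin(thi, ahi) - pmax(tlo, alo))
  len[!hit] <- 0
  len
}

# chord (um) through a vertical circular cylinder centered at x = cx,
# occupying lab heights [y0, y1]
ray_path_vertical_cylinder <- function(X, Y, cx, r, y0, y1) {
  if (r <= 0 || y1 <= y0) return(0 * X)
  chord <- 2 * sqrt(pmax(r^2 - (X - cx)^2, 0))
  chord * (Y >= y0 & Y <= y1)
}

# Difference-of-Gaussians fringe field of a phase-indicator image, normalized
# so a straight boundary produces a band peaking at +/- `amplitude`.
fringe_field <- function(phase_mask, amplitude, width_px) {
  if (amplitude == 0 || width_px <= 0) return(0)
  d <- seq(-8 * width_px, 8 * width_px, length.out = 2001)
  peak <- max(stats::pnorm(d / width_px) - stats::pnorm(d / (2 * width_px)))
  b1 <- EBImage::gblur(phase_mask, width_px, boundary = "replicate")
  b2 <- EBImage::gblur(phase_mask, 2 * width_px, boundary = "replicate")
  amplitude * (b1 - b2) / peak
}

#' Render a flat-field-corrected projection of the posed phantom
#'
#' Computes, for every detector pixel, the Beer-Lambert line integral of the
#' absorption coefficients along the (parallel) beam through the posed
#' specimen, wax mound and holder pin, then adds an edge-enhancement fringe
#' band at each phase boundary, Gaussian detector noise, and clips at the
#' saturation level. The saturation mask is recorded before clipping.
#'
#' The beam travels along lab +z; the detector records lab (x, y) with the
#' origin on the rotation axis at the vertical center of the field of view.
#'
#' @param sample A [phantom_sample()].
#' @param stage A [stage_state()]; the true pose is derived from the motor
#'   positions, goniometer tilts, stage rotation and hidden placement error.
#' @param det A [detector_config()].
#' @param seed Optional integer seed making the noise draw reproducible;
#'   defaults to `det$seed`. When `NULL` the current RNG stream is used.
#' @return A [projection_image()]. A warning is raised if the specimen
#'   projects entirely outside the detector.
#' @export
render_projection <- function(sample, stage, det, seed = det$seed) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  pose <- sample_pose(sample, stage)
  X <- matrix(pixel_x_um(det), det$n_rows, det$n_cols, byrow = TRUE)
  Y <- matrix(pixel_y_um(det), det$n_rows, det$n_cols)

  L <- sample$length * 1000
  path_s <- ray_path_cylinder(X, Y, pose$base, pose$axis, pose$e1, pose$e2,
                              sample$radius_x * 1000, sample$radius_z * 1000,
                              0, L)
  A <- sample$mu_sample * path_s / 1000
  if (!is.null(sample$marker_fraction)) {
    h <- sample$marker_height * 1000
    s0 <- sample$marker_fraction * L - h / 2
    path_m <- ray_path_cylinder(X, Y, pose$base, pose$axis, pose$e1, pose$e2,
                                sample$radius_x * 1000, sample$radius_z * 1000,
                                s0, s0 + h)
    A <- A + sample$marker_mu * path_m / 1000
  }
  by <- pose$base[2]
  path_w <- ray_path_vertical_cylinder(X, Y, pose$base[1],
                                       sample$wax_radius * 1000,
                                       by - sample$wax_height * 1000, by)
  A <- A + sample$mu_wax * path_w / 1000
  path_h <- ray_path_vertical_cylinder(X, Y, pose$base[1],
                                       sample$holder_radius * 1000,
                                       by - (sample$wax_height + sample$holder_height) * 1000,
                                       by - sample$wax_height * 1000)
  A <- A + sample$mu_holder * path_h / 1000

  if (!any(path_s > 0) && !any(path_h > 0) && !any(path_w > 0))
    warning("specimen projects entirely outside the detector: empty image")

  if (det$fringe_amplitude != 0 && det$fringe_width_px > 0) {
    phases <- (path_s > 0) + (path_w > 0) + (path_h > 0)
    A <- A + fringe_field(phases, det$fringe_amplitude, det$fringe_width_px)
  }
  if (det$noise_sigma > 0)
    A <- A + matrix(stats::rnorm(length(A), 0, det$noise_sigma),
                    det$n_rows, det$n_cols)

  sat <- A >= det$saturation_level
  A <- pmin(A, det$saturation_level)
  projection_image(A, det$pix_x, det$pix_y, sat_mask = sat)
}

#' Flat-field correction of a raw projection triplet
#'
#' Converts a raw transmission image into absorption units using beam (flat)
#' and dark-current (dark) reference images:
#' `-log((raw - dark) / (flat - dark))`, optionally clipped to a floor and
#' ceiling.
#'
#' @param raw,flat,dark [projection_image()] objects of matching dimensions.
#' @param floor,ceiling Clipping bounds in absorption units (defaults: none).
#' @return A [projection_image()] in absorption units.
#' @export
flat_field_correct <- function(raw, flat, dark, floor = -Inf, ceiling = Inf) {
  stopifnot(inherits(raw, "projection_image"),
            identical(dim(raw$pixels), dim(flat$pixels)),
            identical(dim(raw$pixels), dim(dark$pixels)))
  den <- flat$pixels - dark$pixels
  n_bad <- sum(den <= 0)
  if (n_bad > 0)
    stop(sprintf("flat <= dark at %d pixel(s); references unusable", n_bad))
  ratio <- (raw$pixels - dark$pixels) / den
  val <- -log(pmax(ratio, .Machine$double.xmin))
  val <- pmin(pmax(val, floor), ceiling)
  projection_image(val, raw$pix_x, raw$pix_y)
}

#' Simulate a raw/flat/dark acquisition triplet
#'
#' Converts the absorption image of [render_projection()] back into detector
#' counts so the flat-field correction path can be exercised end to end:
#' `raw = dark + i0 * exp(-A)`.
#'
#' @inheritParams render_projection
#' @param i0 Incident beam intensity (counts).
#' @param dark_level Dark-current level (counts).
#' @return A list with elements `raw`, `flat` and `dark`.
#' @export
render_raw_triplet <- function(sample, stage, det, i0 = 4e4, dark_level = 100,
                               seed = det$seed) {
  a <- render_projection(sample, stage, det, seed = seed)
  mk <- function(v) projection_image(v, det$pix_x, det$pix_y)
  ones <- matrix(1, det$n_rows, det$n_cols)
  list(raw = mk(dark_level + i0 * exp(-a$pixels)),
       flat = mk(ones * (dark_level + i0)),
       dark = mk(ones * dark_level))
}

# save/restore the global RNG state so seeded renders do not disturb the
# caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
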