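#' Pixel-size calibration result
#'
#' Effective detector pixel sizes in mm per pixel, as recovered by
#' [calibrate_pixel_size()] from known stage displacements.
#'
#' @param pix_x,pix_y Effective pixel sizes (mm/pixel); `NA` if the
#'   corresponding axis was not calibrated.
#' @param residual Root-mean-square regression residual (mm).
#' @return An object of class `calibration`.
#' @export
calibration <- function(pix_x, pix_y, residual = 0) {
  if (!is.na(pix_x)) stopifnot(pix_x > 0)
  if (!is.na(pix_y)) stopifnot(pix_y > 0)
  structure(list(pix_x = pix_x, pix_y = pix_y, residual = residual),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> pix_x=%.6f pix_y=%.6f mm/px (residual %.2g mm)\n",
              x$pix_x, x$pix_y, x$residual))
  invisible(x)
}

wrap_offset <- function(idx1, n) ((idx1 - 1 + floor(n / 2)) %% n) - floor(n / 2)

parabolic_refine <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (is.finite(den) && den < 0) 0.5 * (cm - cp) / den else 0
}

#' Subpixel image registration by cross-correlation
#'
#' Finds the translation `(dx, dy)` that best maps image `a` onto image `b`
#' (i.e. `b` is `a` shifted by `dx` pixels rightward and `dy` pixels upward,
#' in the center-origin image convention). The images are mean-subtracted,
#' optionally Hann-windowed to suppress wrap-around edge effects, cross-
#' correlated via FFT, and the correlation peak is refined to subpixel
#' precision with a three-point parabolic interpolation per axis.
#'
#' @param a,b Projection images ([projection_image()]) or plain matrices of
#'   matching dimensions.
#' @param window Apply a Hann window before correlating (default `TRUE`).
#' @return Named numeric vector `c(dx = ..., dy = ...)` in pixels.
#' @export
subpixel_shift <- function(a, b, window = TRUE) {
  A <- if (inherits(a, "projection_image")) a$pixels else a
  B <- if (inherits(b, "projection_image")) b$pixels else b
  stopifnot(is.matrix(A), identical(dim(A), dim(B)))
  if (stats::sd(A) == 0 || stats::sd(B) == 0)
    stop("flat (zero-variance) image: cross-correlation undefined")
  A <- A - mean(A); B <- B - mean(B)
  nr <- nrow(A); nc <- ncol(A)
  if (window) {
    wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
    wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
    w <- outer(wr, wc)
    A <- A * w; B <- B * w
  }
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  at <- function(i, j) cc[((i - 1) %% nr) + 1, ((j - 1) %% nc) + 1]
  drow <- wrap_offset(pk[1], nr) +
    parabolic_refine(at(pk[1] - 1, pk[2]), at(pk[1], pk[2]), at(pk[1] + 1, pk[2]))
  dcol <- wrap_offset(pk[2], nc) +
    parabolic_refine(at(pk[1], pk[2] - 1), at(pk[1], pk[2]), at(pk[1], pk[2] + 1))
  # row index grows downward while y grows upward
  c(dx = unname(dcol), dy = unname(-drow))
}

#' Render a cone-tip calibration target
#'
#' A single cone-shaped tip (apex up) of uniform absorption: the
#' high-contrast feature traditionally moved by the stage motors to calibrate
#' effective pixel sizes by cross-correlation. The slanted sides sample well
#' at subpixel positions; the horizontal cut at the base is smoothed over
#' about one pixel (a detector point-spread rolloff) so that a subpixel
#' translation of the target moves the sampled image faithfully.
#'
#' @param det A [detector_config()].
#' @param dx_um,dy_um Lab-frame position of the cone apex (micrometres).
#' @param radius Base radius of the cone (mm).
#' @param height Height of the cone, apex to base (mm).
#' @param mu Absorption coefficient (per mm).
#' @param edge_px Gaussian rolloff scale of the base cut (pixels).
#' @param texture_contrast Relative amplitude of a band-limited internal
#'   texture that moves rigidly with the tip (0 for a featureless cone).
#' @param seed Optional seed for the noise draw (defaults to `det$seed`).
#' @return A [projection_image()].
#' @export
render_cone_target <- function(det, dx_um = 0, dy_um = 0, radius = 0.15,
                               height = 0.5, mu = 2, edge_px = 1.2,
                               texture_contrast = 0.3, seed = det$seed) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  X <- matrix(pixel_x_um(det), det$n_rows, det$n_cols, byrow = TRUE)
  Y <- matrix(pixel_y_um(det), det$n_rows, det$n_cols)
  r_local <- pmax(radius / height * (dy_um - Y), 0) * 1000
  A <- mu * 2 * sqrt(pmax(r_local^2 - (X - dx_um)^2, 0)) / 1000
  y_base <- dy_um - height * 1000
  A <- A * stats::pnorm((Y - y_base) / (edge_px * det$pix_y))
  # chirped (zone-plate-like) internal texture moving rigidly with the tip:
  # aperiodic, so the correlation peak is unique (a periodic texture would
  # alias at multiples of its period), with the finest zone kept at ~6
  # pixels so it samples cleanly at any detector resolution
  u <- X - dx_um; v <- Y - dy_um
  rho_max <- sqrt((radius * 1000)^2 + (height * 1000)^2)
  zone_b <- 2 * rho_max * 6 * min(det$pix_x, det$pix_y)
  tex <- 1 + texture_contrast * sin(2 * pi * (u^2 + v^2) / zone_b)
  A <- A * tex
  if (det$noise_sigma > 0)
    A <- A + matrix(stats::rnorm(length(A), 0, det$noise_sigma),
                    det$n_rows, det$n_cols)
  projection_image(A, det$pix_x, det$pix_y)
}

#' Calibrate effective pixel sizes from stage displacements
#'
#' Regresses measured image shifts (pixels, from [subpixel_shift()] against
#' the first image) on the commanded stage displacements (converted to mm) to
#' recover the effective pixel sizes in mm per pixel, one regression per axis.
#' An axis whose commanded displacements have zero range is rejected (`NA`
#' with a warning); at least two distinct displacements are required on the
#' calibrated axis.
#'
#' @param images List of [projection_image()]s of a high-contrast target.
#' @param moves_um Data frame (or matrix) with columns `dx` and `dy`: the
#'   commanded lab-frame stage position (micrometres) at each acquisition.
#' @param window Passed to [subpixel_shift()]; off by default because a
#'   fixed window biases the shift of a target that moves across the frame.
#' @return A [calibration()].
#' @export
calibrate_pixel_size <- function(images, moves_um, window = FALSE) {
  moves_um <- as.data.frame(moves_um)
  stopifnot(length(images) >= 2, nrow(moves_um) == length(images),
            all(c("dx", "dy") %in% names(moves_um)))
  shifts <- t(vapply(images[-1], function(im)
    subpixel_shift(images[[1]], im, window = window), numeric(2)))
  d_mm <- cbind(dx = (moves_um$dx[-1] - moves_um$dx[1]) / 1000,
                dy = (moves_um$dy[-1] - moves_um$dy[1]) / 1000)
  fit_one <- function(shift_px, disp_mm, label) {
    if (diff(range(disp_mm)) == 0) {
      warning(sprintf("pix_%s not recoverable: commanded %s displacements have zero range",
                      label, label))
      return(list(pix = NA_real_, resid = numeric(0)))
    }
    fit <- stats::lm(shift_px ~ disp_mm)
    slope <- unname(stats::coef(fit)[2])      # px per mm
    if (!is.finite(slope) || slope == 0)
      stop(sprintf("degenerate %s calibration: zero measured shift slope", label))
    list(pix = 1 / abs(slope), resid = stats::resid(fit) / abs(slope))
  }
  rx <- fit_one(shifts[, "dx"], d_mm[, "dx"], "x")
  ry <- fit_one(shifts[, "dy"], d_mm[, "dy"], "y")
  if (is.na(rx$pix) && is.na(ry$pix))
    stop("degenerate calibration: all commanded displacements are equal")
  res <- c(rx$resid, ry$resid)
  calibration(rx$pix, ry$pix,
              residual = if (length(res)) sqrt(mean(res^2)) else 0)
}
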