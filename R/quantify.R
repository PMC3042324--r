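#' Per-row statistics of a labeled projection
#'
#' Processes the label image row by row. For each row (center-origin y
#' coordinate, positive upward) it reports the fractions of pixels labeled
#' sample, air and holder (`p_sample + p_air + p_holder = 1`), the saturated
#' fraction, and the mean and population variance of the center-origin x
#' coordinates of the sample-labeled pixels (the per-row center of mass;
#' `NA` where the row has no sample pixels).
#'
#' @param lab A `label_image` from [segment()] / [clean_rows()].
#' @return A data frame of class `row_profiles`, one row per detector row,
#'   with columns `y`, `p_sample`, `p_air`, `p_holder`, `p_sat`, `n_sample`,
#'   `mean_x`, `var_x` and `edge_touch` (whether the sample run reaches the
#'   left/right image border, a horizontal-truncation diagnostic). Pixel
#'   sizes are carried as attributes.
#' @export
row_statistics <- function(lab) {
  stopifnot(inherits(lab, "label_image"))
  m <- lab$labels
  nr <- nrow(m); nc <- ncol(m)
  xs <- seq_len(nc) - (nc + 1) / 2
  is_s <- m == 1L
  n_s <- rowSums(is_s)
  sx <- as.vector(is_s %*% xs)
  sxx <- as.vector(is_s %*% xs^2)
  mean_x <- ifelse(n_s > 0, sx / n_s, NA_real_)
  var_x <- ifelse(n_s > 0, pmax(sxx / n_s - (sx / n_s)^2, 0), NA_real_)
  out <- data.frame(
    y = (nr + 1) / 2 - seq_len(nr),
    p_sample = n_s / nc,
    p_air = rowSums(m == 0L) / nc,
    p_holder = rowSums(m == 2L) / nc,
    p_sat = rowMeans(lab$sat_mask),
    n_sample = n_s,
    mean_x = mean_x,
    var_x = var_x,
    edge_touch = is_s[, 1] | is_s[, nc])
  attr(out, "pix_x") <- lab$pix_x
  attr(out, "pix_y") <- lab$pix_y
  class(out) <- c("row_profiles", "data.frame")
  out
}

#' Fit the specimen axis through the per-row centers of mass
#'
#' Ordinary least squares of `mean_x` against `y` over the rows whose sample
#' fraction exceeds `p_min`, giving the axis slope `c1` (pixels of x per pixel
#' of y), the horizontal offset `c2` at image mid-height (pixels), and the
#' deviation from vertical `theta_s = atan(c1 * pix_x / pix_y)` in degrees.
#' The extreme qualifying rows are reported as `Y_max` / `Y_min`, and
#' `out_of_fov` flags a specimen that vertically fills the detector
#' (qualifying rows touching both the top and bottom image edges).
#'
#' @param profiles A `row_profiles` data frame from [row_statistics()].
#' @param cal Optional [calibration()] supplying the pixel aspect ratio;
#'   defaults to the pixel sizes carried by `profiles`.
#' @param p_min Minimum sample fraction for a row to enter the fit
#'   (default 0.05, strict inequality).
#' @param weight_by_var Weight rows by the inverse of their center-of-mass
#'   sampling variance (`var_x / n_sample`). Off by default: the reference
#'   procedure computes `var_x` as a diagnostic but fits unweighted.
#' @return An object of class `alignment_fit` with elements `c1`, `c2`,
#'   `theta_s`, `y_max`, `y_min`, `n_rows_used`, `out_of_fov` and
#'   `clipped_frac` (fraction of used rows truncated at the lateral image
#'   borders).
#' @export
fit_axis <- function(profiles, cal = NULL, p_min = 0.05,
                     weight_by_var = FALSE) {
  stopifnot(inherits(profiles, "row_profiles"))
  pix_x <- if (is.null(cal)) attr(profiles, "pix_x") else cal$pix_x
  pix_y <- if (is.null(cal)) attr(profiles, "pix_y") else cal$pix_y
  use <- profiles$p_sample > p_min & is.finite(profiles$mean_x)
  if (sum(use) < 2)
    stop("no sample found: fewer than two rows with sample fraction above p_min")
  w <- NULL
  if (weight_by_var) {
    v <- profiles$var_x[use] / pmax(profiles$n_sample[use], 1)
    w <- 1 / pmax(v, 1e-6)
  }
  fit <- stats::lm(mean_x ~ y, data = profiles[use, ], weights = w)
  co <- stats::coef(fit)
  c1 <- unname(co["y"])
  c2 <- unname(co["(Intercept)"])
  structure(list(
    c1 = c1, c2 = c2,
    theta_s = atan(c1 * pix_x / pix_y) * 180 / pi,
    y_max = max(profiles$y[use]),
    y_min = min(profiles$y[use]),
    n_rows_used = sum(use),
    out_of_fov = use[1] && use[length(use)],
    clipped_frac = mean(profiles$edge_touch[use])
  ), class = "alignment_fit")
}

#' @export
print.alignment_fit <- function(x, ...) {
  cat(sprintf(
    "<alignment_fit> c1=%.5f c2=%.2f px | theta_s=%.3f deg | y in [%g, %g] | rows=%d%s\n",
    x$c1, x$c2, x$theta_s, x$y_min, x$y_max, x$n_rows_used,
    if (x$out_of_fov) " | fills FOV vertically" else ""))
  invisible(x)
}

#' Vertical extent of the sample in a projection
#'
#' Returns the center-origin row coordinates of the topmost and bottommost
#' rows whose sample fraction exceeds `p_min`; used to detect when the top or
#' bottom edge of the specimen has entered the field of view.
#'
#' @inheritParams fit_axis
#' @return Named numeric vector `c(y_max = ..., y_min = ...)` in pixels.
#' @export
find_extent <- function(profiles, p_min = 0.05) {
  stopifnot(inherits(profiles, "row_profiles"))
  use <- profiles$p_sample > p_min
  if (!any(use))
    stop("no sample found: no row with sample fraction above p_min")
  c(y_max = max(profiles$y[use]), y_min = min(profiles$y[use]))
}
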