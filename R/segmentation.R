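#' Segmentation thresholds
#'
#' Fixed absorption thresholds for the three-component labeling: air is any
#' pixel absorbing less than `t_sample`, sample anything between `t_sample`
#' and `t_holder`, holder anything at or above `t_holder`. The sample
#' threshold is the user-tunable parameter that adapts the routine to the
#' material and beam energy.
#'
#' @param t_sample Air/sample boundary (absorption units).
#' @param t_holder Sample/holder boundary (absorption units).
#' @param sat_level Saturation level (absorption units).
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(t_sample = 0.3, t_holder = 2.5, sat_level = 3) {
  if (!(t_sample >= 0 && t_sample < t_holder && t_holder <= sat_level))
    stop("thresholds must satisfy 0 <= t_sample < t_holder <= sat_level")
  structure(list(t_sample = t_sample, t_holder = t_holder,
                 sat_level = sat_level), class = "thresholds")
}

#' Construct a label image
#'
#' Container for a per-pixel phase classification, normally produced by
#' [segment()] but also constructible directly (e.g. for externally
#' segmented data).
#'
#' @param labels Integer matrix with values 0 (air), 1 (sample), 2 (holder).
#' @param sat_mask Optional logical matrix of saturated pixels.
#' @param pix_x,pix_y Pixel sizes (micrometres per pixel).
#' @return An object of class `label_image`.
#' @export
label_image <- function(labels, sat_mask = NULL, pix_x = 1, pix_y = 1) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  if (is.null(sat_mask)) sat_mask <- matrix(FALSE, nrow(labels), ncol(labels))
  stopifnot(identical(dim(sat_mask), dim(labels)))
  structure(list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
                 sat_mask = sat_mask, pix_x = pix_x, pix_y = pix_y),
            class = "label_image")
}

#' Three-component threshold segmentation of a projection
#'
#' Labels every pixel as air (0), sample (1) or holder (2) by the fixed
#' threshold rule: `air` if value < `t_sample`; `sample` if
#' `t_sample <= value < t_holder`; `holder` if value >= `t_holder`.
#' A saturation mask (`value >= sat_level`) is recorded alongside.
#'
#' @param img A [projection_image()].
#' @param th A [thresholds()] object.
#' @return An object of class `label_image` with integer `labels`
#'   (0 = air, 1 = sample, 2 = holder), logical `sat_mask`, and the source
#'   pixel geometry.
#' @export
segment <- function(img, th) {
  stopifnot(inherits(img, "projection_image"), inherits(th, "thresholds"))
  px <- img$pixels
  n_bad <- sum(!is.finite(px))
  if (n_bad > 0)
    stop(sprintf("projection contains %d non-finite pixel(s)", n_bad))
  lab <- matrix(0L, nrow(px), ncol(px))
  lab[px >= th$t_sample] <- 1L
  lab[px >= th$t_holder] <- 2L
  structure(list(labels = lab, sat_mask = px >= th$sat_level,
                 pix_x = img$pix_x, pix_y = img$pix_y),
            class = "label_image")
}

#' Remove spurious rows from a label image
#'
#' Image cleaning against edge-enhancement artifacts (fringes on the wax
#' occasionally crossing the sample threshold): every row in which the
#' fraction of pixels labeled above the sample threshold (sample or holder)
#' is strictly less than `min_frac` has its non-air labels reset to air.
#' Rows are cleared, not deleted, so row coordinates stay intact for the
#' downstream axis fit. The operation is idempotent.
#'
#' @param lab A `label_image` from [segment()].
#' @param min_frac Minimum above-threshold fraction for a row to be kept
#'   (default 0.05). A row with exactly `min_frac` is retained.
#' @return The cleaned `label_image` (saturation mask untouched).
#' @export
clean_rows <- function(lab, min_frac = 0.05) {
  stopifnot(inherits(lab, "label_image"), min_frac >= 0, min_frac <= 1)
  if (min_frac == 0) return(lab)
  frac <- rowMeans(lab$labels >= 1L)
  lab$labels[frac < min_frac, ] <- 0L
  lab
}

#' @export
print.label_image <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<label_image> %d x %d px | air %.1f%% sample %.1f%% holder %.1f%% | saturated %.2f%%\n",
              nrow(x$labels), ncol(x$labels),
              100 * sum(x$labels == 0L) / n, 100 * sum(x$labels == 1L) / n,
              100 * sum(x$labels == 2L) / n, 100 * mean(x$sat_mask)))
  invisible(x)
}
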