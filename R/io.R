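#' Write a projection image as 16-bit grayscale TIFF
#'
#' Absorption values are linearly mapped onto the 16-bit integer range; the
#' scale/offset of the mapping and the pixel sizes are stored in a plain-text
#' YAML sidecar (`<path>.yaml`) so the image round-trips to absorption units.
#'
#' @param img A [projection_image()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_projection_tiff <- function(img, path) {
  stopifnot(inherits(img, "projection_image"))
  lo <- min(img$pixels); hi <- max(img$pixels)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img$pixels - lo) / scale, path,
                  bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(offset = lo, scale = scale,
                        pix_x = img$pix_x, pix_y = img$pix_y),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a projection image written by [write_projection_tiff()]
#'
#' @param path Path to the `.tif` file (its `.yaml` sidecar must exist).
#' @return A [projection_image()] in absorption units.
#' @export
read_projection_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  px <- tiff::readTIFF(path)
  projection_image(px * meta$scale + meta$offset, meta$pix_x, meta$pix_y)
}

#' Export a label image as 8-bit indexed TIFF
#'
#' Labels are written as 0 = air, 1 = sample, 2 = holder (8-bit values
#' 0/1/2), for visual inspection in any image viewer.
#'
#' @param lab A `label_image` from [segment()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(lab, path) {
  stopifnot(inherits(lab, "label_image"))
  tiff::writeTIFF(lab$labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#'
#' @param path Path to the `.tif` file.
#' @param pix_x,pix_y Pixel sizes to attach (micrometres per pixel).
#' @return A `label_image`.
#' @export
read_label_tiff <- function(path, pix_x = 1, pix_y = 1) {
  m <- round(tiff::readTIFF(path) * 255)
  structure(list(labels = matrix(as.integer(m), nrow(m), ncol(m)),
                 sat_mask = matrix(FALSE, nrow(m), ncol(m)),
                 pix_x = pix_x, pix_y = pix_y),
            class = "label_image")
}

config_kinds <- c(phantom_sample = "phantom_sample",
                  detector_config = "detector_config",
                  align_params = "align_params",
                  placement_model = "placement_model",
                  thresholds = "thresholds",
                  stage_state = "stage_state",
                  calibration = "calibration")

#' Write a configuration object to YAML
#'
#' Serializes any of the package's parameter objects ([phantom_sample()],
#' [detector_config()], [align_params()], [placement_model()],
#' [thresholds()], [stage_state()], [calibration()]) with a `kind` field so
#' [read_config_yaml()] can rebuild it through the validating constructor.
#'
#' @param x A supported configuration object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(x, path) {
  kind <- intersect(class(x), names(config_kinds))
  if (length(kind) != 1)
    stop("unsupported configuration object of class ",
         paste(class(x), collapse = "/"))
  yaml::write_yaml(c(list(kind = kind), unclass(x)), path)
  invisible(path)
}

#' Read a configuration object written by [write_config_yaml()]
#'
#' @param path YAML path.
#' @return The reconstructed configuration object.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  kind <- y$kind
  if (is.null(kind) || !kind %in% names(config_kinds))
    stop("not a recognised configuration file: ", path)
  y$kind <- NULL
  y <- y[!vapply(y, is.null, logical(1))]
  do.call(get(kind, envir = asNamespace("projalign")), y)
}

#' Export row profiles as CSV
#'
#' @param profiles A `row_profiles` data frame from [row_statistics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

#' Export an axis fit (or alignment result) as JSON
#'
#' @param x An `alignment_fit` or `alignment_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  stopifnot(inherits(x, "alignment_fit") || inherits(x, "alignment_result"))
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
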