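#' En-face OCTA image
#'
#' Wraps a 2-D grid of 8-bit intensities together with the acquisition
#' metadata used by the quantification stage. Images follow R's matrix
#' convention: the first index is the row (axial/vertical position `y`), the
#' second the column (`x`). En-face angiograms are bright-vessel-on-dark.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`, at least 16x16.
#' @param mm_per_pixel optional physical scale (millimetres per pixel).
#' @param quality_index optional device quality score; images below the
#'   configured gate (default 30) are rejected by [quantify()].
#' @param plexus_label one of `"SVP"`, `"ICP"`, `"DCP"` or `"unlabeled"`:
#'   which retinal vascular plexus the en-face projection belongs to.
#' @return an object of class `en_face_image`.
#' @seealso [quantify()], [read_enface_png()]
#' @export
en_face_image <- function(pixels, mm_per_pixel = NULL, quality_index = NULL,
                          plexus_label = "unlabeled") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop_octalens("en-face image must be at least 16x16 pixels",
                  "octalens_shape_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_octalens("intensities must lie in [0, 255] with no missing values",
                  "octalens_range_error")
  plexus_label <- match.arg(plexus_label, c("SVP", "ICP", "DCP", "unlabeled"))
  structure(list(pixels = pixels,
                 height = nrow(pixels), width = ncol(pixels),
                 mm_per_pixel = mm_per_pixel,
                 quality_index = quality_index,
                 plexus_label = plexus_label),
            class = "en_face_image")
}

#' @export
print.en_face_image <- function(x, ...) {
  cat(sprintf("<en_face_image> %dx%d px, plexus %s, quality %s\n",
              x$height, x$width, x$plexus_label,
              if (is.null(x$quality_index)) "NA" else format(x$quality_index)))
  invisible(x)
}

#' @describeIn en_face_image display the image with the conventional
#'   orientation (row 1 on top) on a gray scale.
#' @param x an `en_face_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.en_face_image <- function(x, ...) {
  px <- x$pixels
  graphics::image(t(px)[, nrow(px):1], col = grDevices::gray.colors(256,
                  start = 0, end = 1), axes = FALSE, asp = nrow(px) / ncol(px),
                  zlim = c(0, 255), ...)
  invisible(x)
}

#' AS-OCT B-scan of the crystalline lens
#'
#' A single anterior-segment OCT cross section. A full densitometry
#' measurement uses a radial series of such scans (15 by default), indexed
#' by their position in the radial pattern.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param scan_index position in the radial series (1-based).
#' @return an object of class `asoct_scan`.
#' @seealso [lens_opacity_from_series()]
#' @export
asoct_scan <- function(pixels, scan_index = 1L) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_octalens("intensities must lie in [0, 255] with no missing values",
                  "octalens_range_error")
  scan_index <- as.integer(scan_index)
  if (scan_index < 1L)
    stop_octalens("scan_index must be a positive integer",
                  "octalens_parameter_error")
  structure(list(pixels = pixels,
                 height = nrow(pixels), width = ncol(pixels),
                 scan_index = scan_index),
            class = "asoct_scan")
}

#' @export
print.asoct_scan <- function(x, ...) {
  cat(sprintf("<asoct_scan> %dx%d px, scan %d\n",
              x$height, x$width, x$scan_index))
  invisible(x)
}

# Accept either a bare matrix or a wrapped image and return the pixel matrix.
#' @noRd
as_pixel_matrix <- function(x) {
  if (inherits(x, "en_face_image") || inherits(x, "asoct_scan")) x$pixels
  else as.matrix(x)
}

# Coerce/validate a logical pixel map (binary vessel map, skeleton, perimeter).
#' @noRd
as_binary_matrix <- function(x) {
  if (is.list(x) && !is.null(x$pixels)) x <- x$pixels
  x <- as.matrix(x)
  if (!is.logical(x)) {
    if (!all(x %in% c(0, 1)))
      stop_octalens("binary map must be logical or 0/1", "octalens_type_error")
    x <- x > 0
  }
  x
}
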