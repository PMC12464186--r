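# Synthetic AS-OCT lens scenes: a crystalline lens bounded by two quartic
# surfaces, a brighter elliptical nucleus, multiplicative speckle and
# optional artifact columns, with the generating parameters kept as ground
# truth for validating the opacimetry stage.

#' Describe a synthetic lens scene
#'
#' Ground-truth container for [generate_lens_bscan()]. Surfaces are
#' degree-4 polynomials `y(x)` in pixel coordinates (`x` = column, `y` =
#' row, row indices grow downwards), with the anterior surface strictly
#' above (smaller row than) the posterior over the lens extent.
#'
#' @param anterior_coeffs,posterior_coeffs numeric length-5 vectors of
#'   polynomial coefficients, constant term first.
#' @param cortex_intensity,nucleus_intensity mean intensities (0-255) of
#'   the lens body and of the nucleus.
#' @param nucleus_ellipse `NULL` or a list with `center` (x, y), `semi_axes`
#'   (a, b) and `rotation` (radians).
#' @param speckle_sd relative standard deviation of the multiplicative
#'   speckle (0 disables).
#' @param background_intensity mean background level outside the lens.
#' @param artifact_columns integer vector of columns zeroed in the rendered
#'   scan (signal-falloff artifacts).
#' @return an object of class `lens_scene_truth`.
#' @export
lens_scene_truth <- function(anterior_coeffs, posterior_coeffs,
                             cortex_intensity = 40, nucleus_intensity = 60,
                             nucleus_ellipse = NULL,
                             speckle_sd = 0, background_intensity = 4,
                             artifact_columns = integer(0)) {
  if (length(anterior_coeffs) != 5L || length(posterior_coeffs) != 5L)
    stop_octalens("surface polynomials need exactly 5 coefficients",
                  "octalens_parameter_error")
  for (v in c(cortex_intensity, nucleus_intensity))
    if (v < 0 || v > 255)
      stop_octalens("intensities must lie in [0, 255]",
                    "octalens_parameter_error")
  structure(list(anterior_coeffs = anterior_coeffs,
                 posterior_coeffs = posterior_coeffs,
                 cortex_intensity = cortex_intensity,
                 nucleus_intensity = nucleus_intensity,
                 nucleus_ellipse = nucleus_ellipse,
                 speckle_sd = speckle_sd,
                 background_intensity = background_intensity,
                 artifact_columns = as.integer(artifact_columns)),
            class = "lens_scene_truth")
}

#' Default synthetic lens scene
#'
#' A gently curved lens filling most of a `height x width` canvas: both
#' surfaces are genuine quartics (vertex form with a small quartic term),
#' the nucleus is a centered axis-aligned ellipse. Intensity defaults
#' follow the opacimetry scale: cortex 40, nucleus 60, dark background.
#'
#' @param height,width canvas size in pixels.
#' @param cortex_intensity,nucleus_intensity,speckle_sd,artifact_columns
#'   passed to [lens_scene_truth()].
#' @return a `lens_scene_truth`.
#' @export
default_lens_scene <- function(height = 180, width = 240,
                               cortex_intensity = 40,
                               nucleus_intensity = 60,
                               speckle_sd = 0,
                               artifact_columns = integer(0)) {
  cx <- (width + 1) / 2
  # vertex form a + b (x - cx)^2 + c (x - cx)^4, expanded to raw coeffs
  expand_vertex <- function(a, b, c4) {
    # a + b (x-cx)^2 + c4 (x-cx)^4
    c(a + b * cx^2 + c4 * cx^4,
      -2 * b * cx - 4 * c4 * cx^3,
      b + 6 * c4 * cx^2,
      -4 * c4 * cx,
      c4)
  }
  half <- width / 2
  ant <- expand_vertex(0.20 * height, 0.25 * height / half^2,
                       0.05 * height / half^4)
  pos <- expand_vertex(0.85 * height, -0.28 * height / half^2,
                       -0.04 * height / half^4)
  lens_scene_truth(ant, pos,
                   cortex_intensity = cortex_intensity,
                   nucleus_intensity = nucleus_intensity,
                   nucleus_ellipse = list(center = c(cx, 0.52 * height),
                                          semi_axes = c(0.28 * width,
                                                        0.16 * height),
                                          rotation = 0),
                   speckle_sd = speckle_sd,
                   artifact_columns = artifact_columns)
}

# Evaluate the true anterior/posterior surface rows at the given columns.
#' @noRd
scene_surfaces <- function(truth, cols) {
  list(anterior = polyval_asc(truth$anterior_coeffs, cols),
       posterior = polyval_asc(truth$posterior_coeffs, cols))
}

# True between-surfaces mask of a scene on a height x width canvas.
#' @noRd
scene_lens_mask <- function(truth, height, width) {
  s <- scene_surfaces(truth, seq_len(width))
  row <- matrix(seq_len(height), height, width)
  ant <- matrix(s$anterior, height, width, byrow = TRUE)
  pos <- matrix(s$posterior, height, width, byrow = TRUE)
  row > ant & row < pos
}

# Mask of the nucleus ellipse (intersected with nothing else).
#' @noRd
scene_nucleus_mask <- function(truth, height, width) {
  e <- truth$nucleus_ellipse
  if (is.null(e)) return(matrix(FALSE, height, width))
  ellipse_mask(height, width, e$center, e$semi_axes, e$rotation %||% 0)
}

#' @noRd
ellipse_mask <- function(height, width, center, semi_axes, rotation = 0) {
  x <- matrix(seq_len(width), height, width, byrow = TRUE) - center[1]
  y <- matrix(seq_len(height), height, width) - center[2]
  u <- x * cos(rotation) + y * sin(rotation)
  v <- -x * sin(rotation) + y * cos(rotation)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

#' Render a synthetic AS-OCT lens B-scan
#'
#' Pixels strictly between the two quartic surfaces take the cortex
#' intensity, or the nucleus intensity inside the nucleus ellipse;
#' everything else is dim background. Multiplicative speckle of relative
#' standard deviation `truth$speckle_sd` is applied to the whole frame,
#' listed artifact columns are zeroed, and intensities are rounded and
#' clamped to the 8-bit range.
#'
#' @param truth a [lens_scene_truth()].
#' @param height,width canvas size in pixels.
#' @param seed integer seed for the speckle draw.
#' @param scan_index radial-series position recorded on the scan.
#' @return an [asoct_scan()].
#' @export
generate_lens_bscan <- function(truth, height = 180, width = 240,
                                seed = NULL, scan_index = 1L) {
  stopifnot(inherits(truth, "lens_scene_truth"))
  s <- scene_surfaces(truth, seq_len(width))
  if (any(s$anterior >= s$posterior))
    stop_octalens("anterior surface must lie strictly above the posterior",
                  "octalens_geometry_error")
  if (min(s$anterior) < 1 || max(s$posterior) > height)
    stop_octalens("surfaces leave the canvas", "octalens_geometry_error")
  img <- matrix(truth$background_intensity, height, width)
  lens <- scene_lens_mask(truth, height, width)
  img[lens] <- truth$cortex_intensity
  nuc <- scene_nucleus_mask(truth, height, width) & lens
  img[nuc] <- truth$nucleus_intensity
  if (truth$speckle_sd > 0) {
    img <- with_seed(seed, img * (1 + truth$speckle_sd *
                                    matrix(stats::rnorm(height * width),
                                           height, width)))
  }
  ac <- truth$artifact_columns
  ac <- ac[ac >= 1L & ac <= width]
  if (length(ac)) img[, ac] <- 0
  asoct_scan(round(pmax(pmin(img, 255), 0)), scan_index = scan_index)
}

#' Render a radial series of lens B-scans from one scene
#'
#' Renders `n_scans` B-scans of the same scene with independent speckle
#' draws (seeds derived deterministically from `seed`), emulating a radial
#' acquisition pattern over an approximately rotationally symmetric lens.
#'
#' @param truth a [lens_scene_truth()].
#' @param n_scans number of scans in the series (15 by default).
#' @param height,width canvas size.
#' @param seed integer seed.
#' @return list of [asoct_scan()] objects.
#' @export
generate_lens_series <- function(truth, n_scans = 15L, height = 180,
                                 width = 240, seed = NULL) {
  lapply(seq_len(n_scans), function(i)
    generate_lens_bscan(truth, height = height, width = width,
                        seed = if (is.null(seed)) NULL else
                          as.integer((as.numeric(seed) * 131 + i) %% 2147483647),
                        scan_index = i))
}
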