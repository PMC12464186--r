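# AS-OCT lens densitometry: threshold segmentation of the crystalline
# lens, robust quartic surface fitting with correction of deviating edge
# points, whole-lens mean intensity (pixel intensity units, PIU, 0-255),
# an elliptical nuclear region of interest, and averaging over a radial
# B-scan series.

#' Opacimetry configuration
#'
#' @param threshold binarization threshold for edge detection; `"otsu"`
#'   (default) computes it per scan, or a fixed numeric value.
#' @param deviation_k robust multiplier: edge samples whose fit residual
#'   exceeds `deviation_k` times the robust residual scale (1.4826 x median
#'   absolute residual) are replaced by their fitted value.
#' @param max_iterations maximum refit iterations of the correction loop.
#' @param roi_width_frac,roi_thickness_frac semi-axes of the automatic
#'   nuclear ellipse as fractions of the lens lateral extent and of the
#'   central lens thickness.
#' @param n_scans expected number of B-scans in a radial series.
#' @return an object of class `opacimetry_config`.
#' @export
opacimetry_config <- function(threshold = "otsu", deviation_k = 3,
                              max_iterations = 10L,
                              roi_width_frac = 0.25,
                              roi_thickness_frac = 0.30,
                              n_scans = 15L) {
  if (deviation_k <= 0)
    stop_octalens("deviation_k must be positive", "octalens_config_error")
  structure(list(threshold = threshold, deviation_k = deviation_k,
                 max_iterations = as.integer(max_iterations),
                 roi_width_frac = roi_width_frac,
                 roi_thickness_frac = roi_thickness_frac,
                 n_scans = as.integer(n_scans)),
            class = "opacimetry_config")
}

#' Detect lens surface edges in an AS-OCT B-scan
#'
#' Binarizes the scan (Otsu threshold by default) and records, per column,
#' the first foreground row from the top (anterior edge) and the last
#' foreground row (posterior edge). Columns with no foreground — e.g.
#' artifact or signal-falloff columns — are marked missing.
#'
#' @param scan an [asoct_scan()] or plain matrix.
#' @param threshold `"otsu"` or a numeric threshold.
#' @return data frame with columns `col`, `anterior_y`, `posterior_y`
#'   (`NA` where missing).
#' @export
detect_lens_edges <- function(scan, threshold = "otsu") {
  px <- as_pixel_matrix(scan)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(px)
         else as.numeric(threshold)
  fg <- px > thr
  if (!any(fg))
    stop_octalens("segmentation failure: no foreground after thresholding",
                  "octalens_segmentation_error")
  ant <- apply(fg, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
  pos <- apply(fg, 2, function(col) if (any(col)) max(which(col)) else NA_integer_)
  data.frame(col = seq_len(ncol(px)), anterior_y = ant, posterior_y = pos)
}

#' Robust quartic surface fit with correction of deviating points
#'
#' Fits a 4th-order polynomial `y(x)` to per-column edge samples by least
#' squares, then iteratively corrects substantially deviating points:
#' samples whose absolute residual exceeds `deviation_k` times the robust
#' residual scale (1.4826 x median absolute residual) are replaced by their
#' fitted value and the curve is refit, until no sample is replaced or
#' `max_iterations` is reached. Replacing (rather than dropping) corrected
#' points keeps full column coverage. Fitting uses a centered and scaled
#' abscissa for conditioning; the returned coefficients are in the raw
#' column coordinate (constant term first).
#'
#' @param x,y numeric vectors of column positions and edge rows (`NA`
#'   samples are ignored).
#' @param order polynomial order (4).
#' @param deviation_k robust multiplier.
#' @param max_iterations maximum refit iterations.
#' @return an object of class `surface_fit`: list with `coeffs` (length
#'   `order + 1`), `inlier_count`, `residual_scale`, `corrected_points`,
#'   `converged`, and `x_range`.
#' @export
fit_surface_polynomial <- function(x, y, order = 4L, deviation_k = 3,
                                   max_iterations = 10L) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  if (length(x) < order + 1L)
    stop_octalens(sprintf(
      "underdetermined fit: %d samples for order %d", length(x), order),
      "octalens_underdetermined_error")
  ctr <- mean(x); scl <- stats::sd(x)
  if (scl == 0)
    stop_octalens("degenerate abscissa: all samples in one column",
                  "octalens_underdetermined_error")
  xs <- (x - ctr) / scl
  V <- outer(xs, 0:order, `^`)
  # iterated correction: deviating points (judged against the ORIGINAL
  # samples each round, so a point can be re-admitted once the curve
  # recovers) are replaced by their fitted value before the refit
  bad <- rep(FALSE, length(x))
  converged <- FALSE
  beta <- qr.solve(V, y)
  scale <- 0
  scale_floor <- max(1e-8 * max(diff(range(y)), 1), .Machine$double.eps^0.5)
  for (it in seq_len(max(1L, max_iterations))) {
    yw <- y
    yw[bad] <- drop(V[bad, , drop = FALSE] %*% beta)
    beta <- qr.solve(V, yw)
    fit <- drop(V %*% beta)
    res <- y - fit
    scale <- 1.4826 * stats::median(abs(res))
    new_bad <- if (scale > scale_floor) abs(res) > deviation_k * scale
               else rep(FALSE, length(res))
    if (identical(new_bad, bad)) { converged <- TRUE; break }
    bad <- new_bad
  }
  if (any(bad)) {
    # replacement iterated to its fixed point: the fit whose corrected
    # points sit exactly on the curve, i.e. least squares on the inliers
    beta <- qr.solve(V[!bad, , drop = FALSE], y[!bad])
    scale <- 1.4826 * stats::median(abs(y - drop(V %*% beta)))
  }
  structure(list(coeffs = rescale_poly(beta, ctr, scl),
                 inlier_count = sum(!bad),
                 residual_scale = scale,
                 corrected_points = sum(bad),
                 converged = converged,
                 x_range = range(x)),
            class = "surface_fit")
}

# Convert coefficients of p(((x - ctr) / scl)) into raw-x coefficients.
#' @noRd
rescale_poly <- function(beta, ctr, scl) {
  order <- length(beta) - 1L
  out <- numeric(order + 1L)
  # ((x - ctr)/scl)^j expanded binomially
  for (j in 0:order) {
    bj <- beta[j + 1L] / scl^j
    for (k in 0:j) {
      out[k + 1L] <- out[k + 1L] +
        bj * choose(j, k) * (-ctr)^(j - k)
    }
  }
  out
}

#' Evaluate a fitted surface
#'
#' @param object a [fit_surface_polynomial()] result.
#' @param x column positions.
#' @param ... unused.
#' @return fitted edge rows at `x`.
#' @export
predict.surface_fit <- function(object, x, ...) {
  polyval_asc(object$coeffs, as.numeric(x))
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf(
    "<surface_fit> order %d, %d inliers, %d corrected, residual scale %.3g\n",
    length(x$coeffs) - 1L, x$inlier_count, x$corrected_points,
    x$residual_scale))
  invisible(x)
}

#' Build the lens mask between two fitted surfaces
#'
#' The mask is true exactly for pixels whose row lies strictly between the
#' anterior and posterior fitted curves at their column, restricted to the
#' given lateral extent.
#'
#' @param anterior,posterior [fit_surface_polynomial()] results (or any
#'   object with a `predict` method over columns).
#' @param lateral_extent integer vector of columns, or `NULL` for the
#'   intersection of the two fits' sample ranges.
#' @param height,width canvas size of the target scan.
#' @return logical matrix (`lens_mask`).
#' @export
build_lens_mask <- function(anterior, posterior, height, width,
                            lateral_extent = NULL) {
  cols <- if (is.null(lateral_extent)) {
    lo <- max(anterior$x_range[1], posterior$x_range[1])
    hi <- min(anterior$x_range[2], posterior$x_range[2])
    seq(ceiling(lo), floor(hi))
  } else as.integer(lateral_extent)
  cols <- cols[cols >= 1L & cols <= width]
  if (!length(cols))
    stop_octalens("empty lateral extent", "octalens_geometry_error")
  ant <- predict(anterior, cols)
  pos <- predict(posterior, cols)
  if (any(ant >= pos))
    stop_octalens("fitted surfaces cross within the lateral extent",
                  "octalens_geometry_error")
  mask <- matrix(FALSE, height, width)
  rows <- seq_len(height)
  tol <- 1e-6    # strict comparison, robust to rounding at integer curves
  for (i in seq_along(cols))
    mask[rows > ant[i] + tol & rows < pos[i] - tol, cols[i]] <- TRUE
  mask
}

#' Mean intensity under a mask (lens opacity, PIU)
#'
#' @param scan an [asoct_scan()] or matrix.
#' @param mask logical matrix of the same shape.
#' @return mean pixel intensity (0-255) over the mask.
#' @export
mean_opacity <- function(scan, mask) {
  px <- as_pixel_matrix(scan)
  mask <- as_binary_matrix(mask)
  if (!any(mask))
    stop_octalens("empty mask: opacity undefined", "octalens_degenerate_error")
  mean(px[mask])
}

#' Nuclear opacity from an elliptical region of interest
#'
#' In automatic mode the ellipse is centered at the lens-mask centroid with
#' semi-axes set to fixed fractions of the lens lateral extent and of the
#' central lens thickness (the manual ROI correction of a clinical workflow
#' is replaced by these explicit parameters). Returns the mean intensity
#' over the intersection of the ellipse and the lens mask.
#'
#' @param scan an [asoct_scan()] or matrix.
#' @param mask lens mask from [build_lens_mask()].
#' @param roi `"auto"` or a list with `center`, `semi_axes`, `rotation`.
#' @param config an [opacimetry_config()] (for the auto ROI fractions).
#' @return mean nuclear intensity (PIU), with the ROI used as attribute
#'   `roi`.
#' @export
nucleus_roi <- function(scan, mask, roi = "auto",
                        config = opacimetry_config()) {
  px <- as_pixel_matrix(scan)
  mask <- as_binary_matrix(mask)
  if (!any(mask))
    stop_octalens("empty lens mask", "octalens_degenerate_error")
  if (identical(roi, "auto")) {
    idx <- which(mask, arr.ind = TRUE)
    ctr <- c(mean(idx[, 2]), mean(idx[, 1]))            # (x, y)
    width_px <- diff(range(idx[, 2])) + 1L
    ctr_col <- round(ctr[1])
    col_rows <- which(mask[, ctr_col])
    thickness <- if (length(col_rows)) diff(range(col_rows)) + 1L
                 else diff(range(idx[, 1])) + 1L
    roi <- list(center = ctr,
                semi_axes = c(config$roi_width_frac * width_px,
                              config$roi_thickness_frac * thickness),
                rotation = 0)
  }
  if (any(unlist(roi$semi_axes) <= 0))
    stop_octalens("ellipse semi-axes must be positive",
                  "octalens_parameter_error")
  emask <- ellipse_mask(nrow(px), ncol(px), roi$center, roi$semi_axes,
                        roi$rotation %||% 0)
  inter <- emask & mask
  if (!any(inter))
    stop_octalens("ROI does not intersect the lens mask",
                  "octalens_roi_error")
  structure(mean(px[inter]), roi = roi)
}

# Segment one scan end-to-end: edges -> two robust quartic fits -> mask.
#' @noRd
segment_lens_scan <- function(scan, config = opacimetry_config()) {
  px <- as_pixel_matrix(scan)
  edges <- detect_lens_edges(px, config$threshold)
  ant <- fit_surface_polynomial(edges$col, edges$anterior_y,
                                deviation_k = config$deviation_k,
                                max_iterations = config$max_iterations)
  pos <- fit_surface_polynomial(edges$col, edges$posterior_y,
                                deviation_k = config$deviation_k,
                                max_iterations = config$max_iterations)
  ok <- !is.na(edges$anterior_y) & !is.na(edges$posterior_y)
  mask <- build_lens_mask(ant, pos, nrow(px), ncol(px),
                          lateral_extent = edges$col[ok])
  list(edges = edges, anterior = ant, posterior = pos, mask = mask)
}

#' Lens and nuclear opacity from a radial B-scan series
#'
#' Segments every scan (threshold, robust quartic surfaces, between-surface
#' mask), measures whole-lens and nuclear opacity per scan, and averages
#' across the series: the final lens density is the arithmetic mean of the
#' per-scan values (no inter-scan normalization — intensity variation
#' between B-scans is handled purely by averaging). Per-scan values are
#' retained for audit.
#'
#' @param scans list of [asoct_scan()] objects (length `config$n_scans`,
#'   15 by default).
#' @param config an [opacimetry_config()].
#' @return an object of class `lens_opacity_result`: list with
#'   `lens_opacity`, `nuclear_opacity`, `per_scan_lens`, `per_scan_nucleus`,
#'   `corrected_points`.
#' @export
lens_opacity_from_series <- function(scans, config = opacimetry_config()) {
  if (length(scans) != config$n_scans)
    stop_octalens(sprintf("expected %d scans, got %d",
                          config$n_scans, length(scans)),
                  "octalens_parameter_error")
  per_lens <- per_nuc <- corrected <- numeric(length(scans))
  failures <- character(0)
  for (i in seq_along(scans)) {
    idx <- if (inherits(scans[[i]], "asoct_scan")) scans[[i]]$scan_index else i
    res <- tryCatch({
      seg <- segment_lens_scan(scans[[i]], config)
      per_lens[i] <- mean_opacity(scans[[i]], seg$mask)
      per_nuc[i] <- as.numeric(nucleus_roi(scans[[i]], seg$mask,
                                           config = config))
      corrected[i] <- seg$anterior$corrected_points +
        seg$posterior$corrected_points
      NULL
    }, octalens_error = function(e) conditionMessage(e))
    if (!is.null(res)) failures <- c(failures, sprintf("scan %s: %s", idx, res))
  }
  if (length(failures))
    stop_octalens(paste0("unsegmentable scans (repeat the examination): ",
                         paste(failures, collapse = "; ")),
                  "octalens_segmentation_error")
  structure(list(lens_opacity = mean(per_lens),
                 nuclear_opacity = mean(per_nuc),
                 per_scan_lens = per_lens,
                 per_scan_nucleus = per_nuc,
                 corrected_points = corrected),
            class = "lens_opacity_result")
}

#' @export
print.lens_opacity_result <- function(x, ...) {
  cat(sprintf(
    "Lens opacity %.2f PIU, nuclear opacity %.2f PIU (%d scans)\n",
    x$lens_opacity, x$nuclear_opacity, length(x$per_scan_lens)))
  invisible(x)
}

#' Cumulative dissipated energy (CDE)
#'
#' `CDE (\%s) = average phacoemulsification power (\%) x
#' phacoemulsification time (s)`.
#'
#' @param avg_power average phaco power in percent (>= 0).
#' @param phaco_time phacoemulsification time in seconds (>= 0).
#' @return CDE in percent-seconds.
#' @export
compute_cde <- function(avg_power, phaco_time) {
  if (any(avg_power < 0) || any(phaco_time < 0))
    stop_octalens("power and time must be non-negative",
                  "octalens_parameter_error")
  avg_power * phaco_time
}
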