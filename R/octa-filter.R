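# Vessel enhancement and binarization: multiscale Hessian (Frangi)
# vesselness for bright-on-dark tubular structures, Otsu's histogram
# threshold, and strict binarization.

#' Quantification configuration
#'
#' Collects the tunable constants of the OCTA quantification stage.
#'
#' @param frangi_scales Gaussian scales (pixels) of the multiscale Hessian;
#'   the vesselness response is the per-pixel maximum over scales.
#' @param frangi_shape_param blob-vs-line sensitivity (the classical
#'   `beta`); 0.5 is the conventional choice.
#' @param frangi_contrast_param structureness sensitivity (the classical
#'   `c`). `NULL` (default) sets it adaptively per scale to half the maximum
#'   Hessian norm of the image at that scale.
#' @param min_quality_index acceptance gate: images whose quality index is
#'   below this value are rejected by [quantify()]. Default 30.
#' @param min_branch_length skeleton branches shorter than this geodesic
#'   length (pixels) are pruned before metric computation; 0 disables
#'   pruning (default).
#' @param hole_fill_area background pockets of at most this many pixels
#'   that are fully enclosed by vessel pixels are filled after
#'   binarization. Hessian-based vesselness is suppressed at the center of
#'   bifurcations, which can punch 1-10 px artifact holes into junctions;
#'   filling them repairs the junction topology while leaving genuine
#'   intercapillary spaces (which are far larger) untouched. 0 disables.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(frangi_scales = c(1, 2, 3, 4),
                         frangi_shape_param = 0.5,
                         frangi_contrast_param = NULL,
                         min_quality_index = 30,
                         min_branch_length = 0,
                         hole_fill_area = 10) {
  if (length(frangi_scales) == 0 || any(frangi_scales <= 0))
    stop_octalens("frangi_scales must be a non-empty set of positive scales",
                  "octalens_config_error")
  if (min_quality_index < 0)
    stop_octalens("min_quality_index must be >= 0", "octalens_config_error")
  if (hole_fill_area < 0)
    stop_octalens("hole_fill_area must be >= 0", "octalens_config_error")
  structure(list(frangi_scales = frangi_scales,
                 frangi_shape_param = frangi_shape_param,
                 frangi_contrast_param = frangi_contrast_param,
                 min_quality_index = min_quality_index,
                 min_branch_length = min_branch_length,
                 hole_fill_area = hole_fill_area),
            class = "quant_config")
}

#' Multiscale Hessian (Frangi) vesselness
#'
#' Enhances bright tubular structures on a dark background. At every scale
#' the image is convolved with Gaussian-derivative kernels to obtain the
#' scale-normalized Hessian; its eigenvalues \eqn{|\lambda_1| \le
#' |\lambda_2|} yield the blobness ratio \eqn{R_b = \lambda_1/\lambda_2}
#' and structureness \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}, combined as
#' \deqn{v = \exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))}
#' with \eqn{v = 0} wherever \eqn{\lambda_2 > 0} (dark-on-bright polarity).
#' The returned response is the per-pixel maximum over scales, in `[0, 1]`.
#'
#' @param image an [en_face_image()] or a plain intensity matrix.
#' @param config a [quant_config()].
#' @return numeric matrix of vesselness values in `[0, 1]`, same shape as
#'   the input.
#' @references Frangi-type multiscale vessel enhancement filtering.
#' @export
frangi_enhance <- function(image, config = quant_config()) {
  px <- as_pixel_matrix(image)
  if (length(config$frangi_scales) == 0)
    stop_octalens("empty scale set", "octalens_config_error")
  beta <- config$frangi_shape_param
  out <- matrix(0, nrow(px), ncol(px))
  for (sigma in config$frangi_scales) {
    k <- gaussian_kernels(sigma)
    # scale-normalized Hessian entries (gamma = 2)
    s2 <- sigma^2
    hyy <- s2 * sep_convolve(px, k$g2, k$g0)  # second derivative along rows (y)
    hxx <- s2 * sep_convolve(px, k$g0, k$g2)  # along columns (x)
    hxy <- s2 * sep_convolve(px, k$g1, k$g1)
    tr2 <- (hxx + hyy) / 2
    dlt <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    e1 <- tr2 + dlt
    e2 <- tr2 - dlt
    # order by magnitude: l2 has the larger |.|
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S <- sqrt(l1^2 + l2^2)
    cpar <- config$frangi_contrast_param
    if (is.null(cpar)) cpar <- max(S) / 2
    # a numerically flat image has only rounding-level curvature: no signal
    if (cpar <= 1e-8 * max(1, max(abs(px)))) next
    rb2 <- ifelse(l2 == 0, Inf, (l1 / l2)^2)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cpar^2)))
    v[l2 > 0] <- 0                           # bright-on-dark only
    out <- pmax(out, v)
  }
  out
}

#' Otsu's threshold
#'
#' Histogram threshold maximizing the between-class variance. Integer-valued
#' grids in `[0, 255]` use their native 0-255 bins; other grids use 256
#' equal-width bins over the value range. The returned threshold lies on the
#' input scale; binarize with the strict rule `value > threshold`.
#'
#' @param grid numeric matrix (raw intensities or vesselness values).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(grid) {
  v <- as.numeric(as_pixel_matrix(grid))
  rng <- range(v)
  if (diff(rng) == 0)
    stop_octalens("Otsu threshold is undefined for a constant grid",
                  "octalens_degenerate_error")
  if (all(v == round(v)) && rng[1] >= 0 && rng[2] <= 255) {
    edges <- 0:255                  # candidate thresholds: integer levels
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
    mids <- 0:255
  } else {
    nb <- 256L
    br <- seq(rng[1], rng[2], length.out = nb + 1L)
    idx <- pmin(nb, pmax(1L, findInterval(v, br, rightmost.closed = TRUE)))
    counts <- tabulate(idx, nbins = nb)
    mids <- (br[-1] + br[-(nb + 1L)]) / 2
    edges <- br[-1]                 # thresholds at upper bin edges
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * mids) / n
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(counts))
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  edges[which.max(sigma_b)]
}

#' Binarize a grid at a threshold
#'
#' Strict comparison: a pixel is foreground iff its value exceeds the
#' threshold. Strictness is fixed so integer-valued inputs binarize
#' reproducibly.
#'
#' @param grid numeric matrix.
#' @param threshold scalar threshold (e.g. from [otsu_threshold()]).
#' @return logical matrix of the same shape (a binary vessel map).
#' @export
binarize <- function(grid, threshold) {
  px <- as_pixel_matrix(grid)
  px > threshold
}
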