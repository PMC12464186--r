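# The nine en-face perfusion metrics. All are pixel-count based: VAD, VDI,
# VPI and VCI are exact integer-count ratios of the binary vessel map A,
# skeleton map S and perimeter map P; BVT is the mean geodesic/Euclidean
# branch-length ratio; BP/EP/TVL/AVL summarize the skeleton.

#' Vessel area density (VAD)
#'
#' Ratio between the area occupied by vessels and the total image area:
#' vessel pixel count divided by total pixel count, in `[0, 1]`.
#'
#' @param binary logical vessel map.
#' @return scalar ratio.
#' @export
compute_vad <- function(binary) {
  m <- as_binary_matrix(binary)
  if (length(m) == 0)
    stop_octalens("zero-size image", "octalens_degenerate_error")
  sum(m) / length(m)
}

#' Vessel diameter index (VDI)
#'
#' Vessel area per unit skeleton length — the vessel pixel count divided by
#' the skeleton pixel count; quantifies vascular dilation.
#'
#' @param binary logical vessel map.
#' @param skeleton logical skeleton map derived from it.
#' @return scalar ratio (>= 1 for a true skeleton of the map).
#' @export
compute_vdi <- function(binary, skeleton) {
  a <- sum(as_binary_matrix(binary))
  s <- sum(as_binary_matrix(skeleton))
  if (s == 0)
    stop_octalens("empty skeleton: VDI undefined", "octalens_degenerate_error")
  a / s
}

#' Vessel perimeter index (VPI)
#'
#' Ratio of the vessel perimeter pixel count to the vessel area pixel
#' count; sensitive to vessel dropout.
#'
#' @param perimeter logical perimeter map.
#' @param binary logical vessel map.
#' @return scalar ratio.
#' @export
compute_vpi <- function(perimeter, binary) {
  a <- sum(as_binary_matrix(binary))
  if (a == 0)
    stop_octalens("empty vessel map: VPI undefined", "octalens_degenerate_error")
  sum(as_binary_matrix(perimeter)) / a
}

#' Blood vessel tortuosity (BVT)
#'
#' Mean, over all non-loop branches, of the ratio between a branch's
#' geodesic length (its real path length along the skeleton) and the
#' Euclidean distance between its two endpoints. Always >= 1, with equality
#' iff every non-loop branch is straight. Loops (coincident endpoints) are
#' excluded; their count is reported as the `"excluded_loops"` attribute.
#'
#' @param branches list of branches from [decompose_branches()].
#' @return scalar >= 1 with attribute `excluded_loops`.
#' @export
compute_bvt <- function(branches) {
  if (length(branches) == 0)
    stop_octalens("no branches: BVT undefined", "octalens_degenerate_error")
  loops <- vapply(branches, function(b) b$is_loop || b$euclidean_length == 0,
                  logical(1))
  if (all(loops))
    stop_octalens("all branches are loops: BVT undefined",
                  "octalens_degenerate_error")
  ratios <- vapply(branches[!loops],
                   function(b) b$geodesic_length / b$euclidean_length,
                   numeric(1))
  structure(mean(ratios), excluded_loops = sum(loops))
}

#' Vessel complexity index (VCI)
#'
#' Squared perimeter pixel count over `4 * pi` times the vessel area pixel
#' count — an isoperimetric-type circularity measure (1 for a disk in the
#' continuum limit, larger for complex vasculature).
#'
#' @param perimeter logical perimeter map.
#' @param binary logical vessel map.
#' @return scalar value.
#' @export
compute_vci <- function(perimeter, binary) {
  a <- sum(as_binary_matrix(binary))
  if (a == 0)
    stop_octalens("empty vessel map: VCI undefined", "octalens_degenerate_error")
  sum(as_binary_matrix(perimeter))^2 / (4 * pi * a)
}

#' Total and average vessel length
#'
#' `tvl` is the skeleton pixel count (the pixel-sum definition consistent
#' with the VDI denominator); `avl = tvl / number of branches`. Note that
#' branch geodesic lengths weight diagonal steps by `sqrt(2)` whereas TVL is
#' a plain count; both definitions are deliberate and documented.
#'
#' @param skeleton logical skeleton map.
#' @param branches list of branches from [decompose_branches()].
#' @return list with `tvl` (integer) and `avl` (numeric).
#' @export
vessel_lengths <- function(skeleton, branches) {
  tvl <- sum(as_binary_matrix(skeleton))
  if (length(branches) == 0)
    stop_octalens("no branches: AVL undefined", "octalens_degenerate_error")
  list(tvl = as.integer(tvl), avl = tvl / length(branches))
}

# Iteratively prune spur branches (free-ended branches shorter than
# `min_len` geodesic pixels) from a skeleton.
#' @noRd
prune_spurs <- function(skel, min_len) {
  if (min_len <= 0) return(skel)
  repeat {
    deg <- neighbor_count8(skel)
    branches <- decompose_branches(skel)
    if (length(branches) == 0) return(skel)
    removed <- FALSE
    for (b in branches) {
      if (b$is_loop || b$geodesic_length >= min_len) next
      p <- b$path
      # free end = terminal pixel with skeleton degree <= 1
      d1 <- deg[p[1, 1], p[1, 2]]
      d2 <- deg[p[nrow(p), 1], p[nrow(p), 2]]
      if (d1 > 1L && d2 > 1L) next      # connector between nodes: keep
      # remove interior pixels only (degree <= 2), keep node pixels
      for (k in seq_len(nrow(p))) {
        if (deg[p[k, 1], p[k, 2]] <= 2L) skel[p[k, 1], p[k, 2]] <- FALSE
      }
      removed <- TRUE
    }
    if (!removed) return(skel)
    skel <- skeletonize_map(skel)       # re-thin freed junction pixels
  }
}

#' Quantify an en-face OCTA image
#'
#' Runs the full perfusion analysis: multiscale Hessian vessel enhancement,
#' Otsu threshold on the vesselness response, strict binarization,
#' perimeter extraction, homotopic thinning and branch decomposition, then
#' all nine metrics. Deterministic for a fixed image and configuration.
#'
#' Images carrying a quality index below `config$min_quality_index`
#' (default 30) are rejected before any computation, mirroring the
#' acquisition rule that scans with a quality index below 30 are discarded
#' and repeated.
#'
#' @param image an [en_face_image()] (or plain matrix, in which case no
#'   quality gate applies).
#' @param config a [quant_config()].
#' @return an object of class `perfusion_metrics`: list with `vad`, `vdi`,
#'   `vpi`, `bvt`, `vci`, `bp`, `ep`, `tvl`, `avl`, plus attributes
#'   `threshold` (the Otsu cut on the vesselness response),
#'   `excluded_loops`, and `config`.
#' @examples
#' tr <- generate_vascular_tree(depth = 2, density = 1, seed = 3, canvas = 128)
#' img <- render_octa_image(tr, quality_index = 50)
#' quantify(img)
#' @export
quantify <- function(image, config = quant_config()) {
  qi <- if (inherits(image, "en_face_image")) image$quality_index else NULL
  if (!is.null(qi) && qi < config$min_quality_index)
    stop_octalens(sprintf(
      "image rejected by the quality gate (quality index < %s): index %s",
      format(config$min_quality_index), format(qi)),
      "octalens_quality_error")
  v <- frangi_enhance(image, config)
  thr <- otsu_threshold(v)
  binary <- binarize(v, thr)
  binary <- fill_small_holes(binary, config$hole_fill_area)
  if (!any(binary))
    stop_octalens("no vessel pixels after binarization",
                  "octalens_degenerate_error")
  perim <- perimeter_map(binary)
  skel <- skeletonize_map(binary)
  skel <- prune_spurs(skel, config$min_branch_length)
  branches <- decompose_branches(skel)
  nodes <- count_nodes(skel)
  bvt <- compute_bvt(branches)
  len <- vessel_lengths(skel, branches)
  structure(list(vad = compute_vad(binary),
                 vdi = compute_vdi(binary, skel),
                 vpi = compute_vpi(perim, binary),
                 bvt = as.numeric(bvt),
                 vci = compute_vci(perim, binary),
                 bp = nodes$bp, ep = nodes$ep,
                 tvl = len$tvl, avl = len$avl),
            threshold = thr,
            excluded_loops = attr(bvt, "excluded_loops"),
            config = config,
            class = "perfusion_metrics")
}

#' @export
print.perfusion_metrics <- function(x, digits = 4, ...) {
  cat("Perfusion metrics\n")
  cat(sprintf("  VAD %.4f  VDI %.4f  VPI %.4f  BVT %.4f  VCI %.1f\n",
              x$vad, x$vdi, x$vpi, x$bvt, x$vci))
  cat(sprintf("  BP %d  EP %d  TVL %d  AVL %.2f\n", x$bp, x$ep, x$tvl, x$avl))
  invisible(x)
}

#' @export
as.data.frame.perfusion_metrics <- function(x, ...) {
  data.frame(vad = x$vad, vdi = x$vdi, vpi = x$vpi, bvt = x$bvt, vci = x$vci,
             bp = x$bp, ep = x$ep, tvl = x$tvl, avl = x$avl)
}
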