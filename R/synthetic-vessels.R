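# Synthetic OCTA scene generation: parametric vascular trees with exactly
# recorded topology and centerline geometry, rendered to bright-on-dark
# en-face angiograms with optional speckle. The recorded truth is what the
# perfusion metrics estimate, so the whole quantification chain can be
# validated against known answers.

#' Generate a synthetic vascular tree with known ground truth
#'
#' Builds one or several binary trees of tubular branches inside a square
#' canvas. Each branch is a polyline: a straight segment between two nodes,
#' optionally perturbed by a sinusoidal displacement along the segment
#' normal (zero at both endpoints, so the recorded topology is exact).
#' Trees are confined to disjoint vertical strips and grown with a
#' collision check so that distinct branches never merge when rendered;
#' branchpoint and endpoint counts are therefore exact by construction.
#'
#' @param depth number of bifurcation levels (>= 1 segment level; `depth`
#'   counts the splits, so a tree has up to `2^depth - 1` branchpoints).
#'   `depth = 1` with `density = 1` and zero tortuosity gives one straight
#'   branch.
#' @param density number of independent trees placed on the canvas.
#' @param tortuosity_amplitude peak normal displacement of each branch in
#'   pixels (0 = straight branches).
#' @param tortuosity_frequency number of half-waves of the sinusoidal
#'   perturbation along a branch.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param canvas canvas side length in pixels.
#' @param trunk_length root branch length in pixels; each level shrinks by
#'   `length_decay`.
#' @param length_decay,split_angle,angle_jitter,base_width,width_decay,min_width
#'   geometry controls: per-level length decay, full opening angle between
#'   sibling branches (radians), random angle jitter (radians), root stroke
#'   width, per-level width decay and minimum stroke width (pixels).
#' @param min_separation minimum clearance (pixels) enforced between the
#'   strokes of non-incident branches, beyond the sum of their half-widths
#'   and the tortuosity amplitude; keeps distinct rendered branches
#'   resolvable by a multiscale filter bank.
#' @param margin canvas border (pixels) kept clear of all centerlines.
#' @return an object of class `vessel_tree_truth`: list with `branches`
#'   (list of n x 2 matrices of (x, y) centerline points), `diameters`,
#'   `topology` (node table with realized degrees), `true_counts`
#'   (`bp`, `ep`), `true_centerline_length` (polyline arc length, pixels),
#'   `tortuosity_params`, and `canvas`.
#' @examples
#' tr <- generate_vascular_tree(depth = 2, density = 1, seed = 1)
#' tr$true_counts
#' @export
generate_vascular_tree <- function(depth = 3, density = 2,
                                   tortuosity_amplitude = 1.5,
                                   tortuosity_frequency = 2,
                                   seed = NULL,
                                   canvas = 256L,
                                   trunk_length = 48,
                                   length_decay = 0.72,
                                   split_angle = 1.1,
                                   angle_jitter = 0.1,
                                   base_width = 3,
                                   width_decay = 0.85,
                                   min_width = 2,
                                   min_separation = 8,
                                   margin = 10) {
  if (depth < 1 || density < 1)
    stop_octalens("depth and density must be >= 1", "octalens_parameter_error")
  if (tortuosity_amplitude < 0 || tortuosity_frequency < 1)
    stop_octalens("tortuosity parameters out of range", "octalens_parameter_error")
  if (canvas < 32)
    stop_octalens("canvas too small", "octalens_parameter_error")

  with_seed(seed, {
    segs <- list()        # straight skeleton of accepted segments
    branches <- list()
    diameters <- numeric(0)
    tort <- list()
    nodes <- list()       # each: x, y, degree
    branch_nodes <- list()  # (from, to) node ids per branch

    add_node <- function(x, y, degree = 0L) {
      nodes[[length(nodes) + 1L]] <<- list(x = x, y = y, degree = degree)
      length(nodes)
    }

    # trees live in a near-square grid of cells so that per-tree geometry
    # does not shrink as more trees are added
    ncx <- ceiling(sqrt(density))
    ncy <- ceiling(density / ncx)
    cell_w <- canvas / ncx
    cell_h <- canvas / ncy

    seg_clearance_ok <- function(p0, p1, w, from_node) {
      if (length(segs) == 0) return(TRUE)
      for (s in segs) {
        clear <- (w + s$w) / 2 + min_separation + 2 * tortuosity_amplitude
        if (s$from == from_node || s$to == from_node) {
          # parent or sibling: legitimately touches at the shared node, but
          # the distal parts must not fold back onto each other
          a0 <- p0 + 0.45 * (p1 - p0)
          shared_at_p0 <- sqrt(sum((s$p0 - p0)^2)) < sqrt(sum((s$p1 - p0)^2))
          if (shared_at_p0) { b0 <- s$p0 + 0.45 * (s$p1 - s$p0); b1 <- s$p1 }
          else { b1 <- s$p1 + 0.45 * (s$p0 - s$p1); b0 <- s$p0 }
          if (segment_segment_distance(a0, p1, b0, b1) < clear) return(FALSE)
        } else {
          if (segment_segment_distance(p0, p1, s$p0, s$p1) < clear)
            return(FALSE)
        }
      }
      TRUE
    }

    wrap_angle <- function(x) atan2(sin(x), cos(x))

    grow <- function(p0, node0, angle, level, xlim, ylim,
                     parent_angle = NULL) {
      len <- trunk_length * length_decay^(level - 1)
      w <- max(min_width, base_width * width_decay^(level - 1))
      lo <- ylim[1]; hi <- ylim[2]
      placed <- FALSE
      min_len <- max(10, 3 * w)     # never place stub branches
      max_turn <- 1.2               # no hairpins relative to the parent
      for (try in 1:10) {
        if (len < min_len) break
        a <- angle + stats::rnorm(1, 0, angle_jitter)
        inb <- FALSE
        for (k in 1:6) {
          if (!is.null(parent_angle))
            a <- parent_angle + max(-max_turn, min(max_turn,
                                                   wrap_angle(a - parent_angle)))
          p1 <- p0 + len * c(cos(a), sin(a))
          inb <- p1[1] >= xlim[1] && p1[1] <= xlim[2] && p1[2] >= lo && p1[2] <= hi
          if (inb) break
          # rotate towards the center of the allowed region
          ctr <- c(mean(xlim), (lo + hi) / 2)
          a <- a + 0.35 * wrap_angle(atan2(ctr[2] - p0[2], ctr[1] - p0[1]) - a)
        }
        if (!inb) { len <- len * 0.85; next }
        if (seg_clearance_ok(p0, p1, w, node0)) { placed <- TRUE; break }
        angle <- angle + stats::runif(1, -0.35, 0.35)
        len <- len * 0.92
      }
      if (!placed) return(invisible(NULL))

      node1 <- add_node(p1[1], p1[2], 0L)
      nodes[[node0]]$degree <<- nodes[[node0]]$degree + 1L
      nodes[[node1]]$degree <<- nodes[[node1]]$degree + 1L
      segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, w = w,
                                         from = node0, to = node1)
      amp <- if (tortuosity_amplitude > 0)
        tortuosity_amplitude * stats::runif(1, 0.7, 1) else 0
      branches[[length(branches) + 1L]] <<-
        tortuous_polyline(p0, p1, amp, tortuosity_frequency)
      diameters <<- c(diameters, w)
      tort[[length(tort) + 1L]] <<- c(amplitude = amp,
                                      frequency = tortuosity_frequency)
      branch_nodes[[length(branch_nodes) + 1L]] <<- c(node0, node1)

      if (level < depth) {
        # split into two children at +- split_angle / 2
        grow(p1, node1, a + split_angle / 2, level + 1, xlim, ylim,
             parent_angle = a)
        grow(p1, node1, a - split_angle / 2, level + 1, xlim, ylim,
             parent_angle = a)
      }
      invisible(NULL)
    }

    for (k in seq_len(density)) {
      ix <- (k - 1) %% ncx
      iy <- (k - 1) %/% ncx
      xlim <- c(ix * cell_w + margin, (ix + 1) * cell_w - margin)
      ylim <- c(iy * cell_h + margin, (iy + 1) * cell_h - margin)
      root <- c(stats::runif(1, xlim[1] + 0.25 * diff(xlim),
                             xlim[2] - 0.25 * diff(xlim)),
                stats::runif(1, ylim[1] + 0.25 * diff(ylim),
                             ylim[2] - 0.25 * diff(ylim)))
      node0 <- add_node(root[1], root[2], 0L)
      a0 <- stats::runif(1, 0, 2 * pi)
      grow(root, node0, a0, 1, xlim, ylim)
    }

    topo <- do.call(rbind, lapply(seq_along(nodes), function(i)
      data.frame(node = i, x = nodes[[i]]$x, y = nodes[[i]]$y,
                 degree = nodes[[i]]$degree)))
    topo <- topo[topo$degree > 0L, , drop = FALSE]  # drop roots that failed to grow
    len_total <- sum(vapply(branches, polyline_length, numeric(1)))
    structure(list(
      branches = branches,
      diameters = diameters,
      topology = topo,
      branch_nodes = branch_nodes,
      true_counts = list(bp = sum(topo$degree >= 3L),
                         ep = sum(topo$degree == 1L)),
      true_centerline_length = len_total,
      tortuosity_params = if (length(tort))
        as.data.frame(do.call(rbind, tort)) else
        data.frame(amplitude = numeric(0), frequency = numeric(0)),
      canvas = as.integer(canvas)),
      class = "vessel_tree_truth")
  })
}

#' @export
print.vessel_tree_truth <- function(x, ...) {
  cat(sprintf(
    "<vessel_tree_truth> %d branches, BP %d, EP %d, centerline %.1f px\n",
    length(x$branches), x$true_counts$bp, x$true_counts$ep,
    x$true_centerline_length))
  invisible(x)
}

# Sinusoidally perturbed polyline from p0 to p1; displacement is along the
# segment normal and vanishes at both endpoints (integer half-waves).
#' @noRd
tortuous_polyline <- function(p0, p1, amplitude, frequency) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, as.integer(ceiling(len / 1.25)) + 1L)
  t <- seq(0, 1, length.out = n)
  dir <- (p1 - p0) / len
  nrm <- c(-dir[2], dir[1])
  disp <- amplitude * sin(pi * frequency * t)
  cbind(x = p0[1] + t * (p1[1] - p0[1]) + disp * nrm[1],
        y = p0[2] + t * (p1[2] - p0[2]) + disp * nrm[2])
}

#' @noRd
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Minimum distance between two 2-D segments.
#' @noRd
segment_segment_distance <- function(a0, a1, b0, b1) {
  min(point_segment_distance(a0[1], a0[2], b0, b1),
      point_segment_distance(a1[1], a1[2], b0, b1),
      point_segment_distance(b0[1], b0[2], a0, a1),
      point_segment_distance(b1[1], b1[2], a0, a1))
}

# Distance from points (px, py) (vectorised) to segment p0-p1.
#' @noRd
point_segment_distance <- function(px, py, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return(sqrt((px - p0[1])^2 + (py - p0[2])^2))
  t <- pmin(1, pmax(0, ((px - p0[1]) * vx + (py - p0[2]) * vy) / l2))
  sqrt((px - (p0[1] + t * vx))^2 + (py - (p0[2] + t * vy))^2)
}

#' Merge vascular trees onto one canvas
#'
#' Places independently generated trees side by side (each translated by
#' its offset) on a larger canvas, summing their ground truth. Useful for
#' controlled density sweeps: adding a tree can only add vessel area.
#'
#' @param trees list of [generate_vascular_tree()] results.
#' @param offsets list of `(dx, dy)` pixel translations, one per tree.
#' @param canvas side length of the combined canvas.
#' @return a `vessel_tree_truth` covering all trees.
#' @export
merge_trees <- function(trees, offsets, canvas) {
  stopifnot(length(trees) == length(offsets))
  branches <- list(); diameters <- numeric(0); tort <- list()
  topo <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]; off <- offsets[[i]]
    for (j in seq_along(tr$branches)) {
      b <- tr$branches[[j]]
      b[, "x"] <- b[, "x"] + off[1]; b[, "y"] <- b[, "y"] + off[2]
      branches[[length(branches) + 1L]] <- b
      diameters <- c(diameters, tr$diameters[j])
      tort[[length(tort) + 1L]] <-
        as.numeric(tr$tortuosity_params[min(j, nrow(tr$tortuosity_params)), ])
    }
    tp <- tr$topology
    if (nrow(tp)) {
      tp$x <- tp$x + off[1]; tp$y <- tp$y + off[2]
      topo[[length(topo) + 1L]] <- tp
    }
  }
  topo <- do.call(rbind, topo)
  structure(list(
    branches = branches, diameters = diameters, topology = topo,
    branch_nodes = list(),
    true_counts = list(bp = sum(topo$degree >= 3L),
                       ep = sum(topo$degree == 1L)),
    true_centerline_length =
      sum(vapply(branches, polyline_length, numeric(1))),
    tortuosity_params = if (length(tort))
      as.data.frame(do.call(rbind, tort)) else
      data.frame(amplitude = numeric(0), frequency = numeric(0)),
    canvas = as.integer(canvas)), class = "vessel_tree_truth")
}

#' Rescale the tortuosity of a tree in place
#'
#' Multiplies every branch's normal displacement (relative to the straight
#' chord between its endpoints) by `factor`, leaving endpoints — and hence
#' the topology — untouched. Gives a family of trees with identical
#' geometry and strictly increasing tortuosity, for controlled sweeps.
#'
#' @param tree a `vessel_tree_truth`.
#' @param factor displacement multiplier (0 straightens every branch).
#' @return the rescaled `vessel_tree_truth`.
#' @export
scale_tree_tortuosity <- function(tree, factor) {
  stopifnot(inherits(tree, "vessel_tree_truth"), factor >= 0)
  tree$branches <- lapply(tree$branches, function(b) {
    n <- nrow(b)
    t <- seq(0, 1, length.out = n)
    straight <- cbind(x = b[1, "x"] + t * (b[n, "x"] - b[1, "x"]),
                      y = b[1, "y"] + t * (b[n, "y"] - b[1, "y"]))
    straight + factor * (b - straight)
  })
  if (nrow(tree$tortuosity_params))
    tree$tortuosity_params$amplitude <-
      tree$tortuosity_params$amplitude * factor
  tree$true_centerline_length <-
    sum(vapply(tree$branches, polyline_length, numeric(1)))
  tree
}

#' Render a vascular tree to an en-face OCTA-like image
#'
#' Rasterizes every branch polyline as an anti-aliased stroke of its
#' recorded diameter on a dark background. A pixel's vessel coverage is
#' `clamp(w/2 + 0.5 - d, 0, 1)` where `d` is the distance from the pixel
#' center to the centerline, so thresholding the coverage at 0.5 yields the
#' crisp set of pixels strictly within `w/2` of a centerline — a
#' well-defined pixel-count ground truth. Optional speckle is multiplicative
#' noise plus additive background noise, after which intensities are rounded
#' and clamped to the 8-bit range.
#'
#' @param tree a [generate_vascular_tree()] result.
#' @param size canvas side in pixels (defaults to the tree's canvas).
#' @param background,contrast background level and centerline contrast on
#'   the 0-255 scale; with noise off every centerline pixel has intensity
#'   `>= background + contrast`.
#' @param noise `NULL` for a noise-free render, otherwise a list with
#'   `speckle_sd` (multiplicative, relative) and `additive_sd` (0-255 units).
#' @param seed integer seed for the noise draw.
#' @param quality_index optional device-style quality score to attach.
#' @param plexus_label plexus label to attach.
#' @return an [en_face_image()].
#' @export
render_octa_image <- function(tree, size = NULL, background = 30,
                              contrast = 170, noise = NULL, seed = NULL,
                              quality_index = 60, plexus_label = "unlabeled") {
  stopifnot(inherits(tree, "vessel_tree_truth"))
  size <- as.integer(size %||% tree$canvas)
  for (b in tree$branches) {
    if (min(b) < 1 || max(b[, "x"]) > size || max(b[, "y"]) > size)
      stop_octalens("tree polylines do not fit inside the canvas",
                    "octalens_geometry_error")
  }
  alpha <- matrix(0, size, size)   # row = y, col = x
  for (i in seq_along(tree$branches)) {
    pts <- tree$branches[[i]]
    w <- tree$diameters[i]
    half <- w / 2
    for (s in seq_len(nrow(pts) - 1L)) {
      p0 <- pts[s, ]; p1 <- pts[s + 1L, ]
      xr <- floor(min(p0[1], p1[1]) - half - 1):ceiling(max(p0[1], p1[1]) + half + 1)
      yr <- floor(min(p0[2], p1[2]) - half - 1):ceiling(max(p0[2], p1[2]) + half + 1)
      xr <- xr[xr >= 1 & xr <= size]; yr <- yr[yr >= 1 & yr <= size]
      if (!length(xr) || !length(yr)) next
      g <- expand.grid(y = yr, x = xr)
      d <- point_segment_distance(g$x, g$y, p0, p1)
      a <- pmin(1, pmax(0, half + 0.5 - d))
      idx <- cbind(g$y, g$x)
      alpha[idx] <- pmax(alpha[idx], a)
    }
  }
  img <- background + contrast * alpha
  if (!is.null(noise)) {
    speckle_sd <- noise$speckle_sd %||% 0.2
    additive_sd <- noise$additive_sd %||% 6
    img <- with_seed(seed, {
      img * (1 + speckle_sd * matrix(stats::rnorm(size * size), size, size)) +
        additive_sd * matrix(stats::rnorm(size * size), size, size)
    })
  }
  img <- round(pmax(pmin(img, 255), 0))
  en_face_image(img, quality_index = quality_index,
                plexus_label = plexus_label)
}
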