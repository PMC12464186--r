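# Binary-map topology operations: homotopic thinning to a single-pixel
# skeleton, perimeter extraction, connected components, endpoint/branchpoint
# counting and decomposition of a skeleton into branches.

# ---- simple-point machinery ------------------------------------------------

# Neighbour offsets in fixed order (row, col), row-major around the center.
.NB_COORDS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                    dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

.octalens_cache <- new.env(parent = emptyenv())

# 256-entry lookup: is a foreground pixel with this 8-neighbour
# configuration a simple point, i.e. deletable without changing the
# topology (one 8-component of foreground neighbours, one 4-component of
# background neighbours touching a 4-neighbour of the center)?
#' @noRd
simple_point_lut <- function() {
  if (!is.null(.octalens_cache$lut)) return(.octalens_cache$lut)
  co <- .NB_COORDS
  is4 <- abs(co[, 1]) + abs(co[, 2]) == 1L
  n_components <- function(cells, four_conn) {
    if (length(cells) == 0) return(0L)
    seen <- rep(FALSE, length(cells)); ncomp <- 0L
    for (s in seq_along(cells)) {
      if (seen[s]) next
      ncomp <- ncomp + 1L
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        for (j in seq_along(cells)) {
          if (seen[j]) next
          dr <- abs(co[cells[i], 1] - co[cells[j], 1])
          dc <- abs(co[cells[i], 2] - co[cells[j], 2])
          adj <- if (four_conn) dr + dc == 1L else max(dr, dc) == 1L
          if (adj) { seen[j] <- TRUE; queue <- c(queue, j) }
        }
      }
    }
    ncomp
  }
  lut <- logical(256)
  for (m in 0:255) {
    fg <- which(bitwAnd(m, 2L^(0:7)) > 0L)
    bg <- setdiff(1:8, fg)
    a <- n_components(fg, four_conn = FALSE)
    # background 4-components touching a 4-neighbour of the center
    b <- 0L
    if (length(bg)) {
      seen <- rep(FALSE, length(bg))
      for (s in seq_along(bg)) {
        if (seen[s]) next
        comp <- s; seen[s] <- TRUE; queue <- s
        while (length(queue)) {
          i <- queue[1]; queue <- queue[-1]
          for (j in seq_along(bg)) {
            if (seen[j]) next
            dr <- abs(co[bg[i], 1] - co[bg[j], 1])
            dc <- abs(co[bg[i], 2] - co[bg[j], 2])
            if (dr + dc == 1L) { seen[j] <- TRUE; queue <- c(queue, j); comp <- c(comp, j) }
          }
        }
        if (any(is4[bg[comp]])) b <- b + 1L
      }
    }
    lut[m + 1L] <- (a == 1L) && (b == 1L)
  }
  .octalens_cache$lut <- lut
  lut
}

#' Skeletonize a binary vessel map
#'
#' Homotopic thinning: border pixels that are simple points (deletable
#' without changing the number of 8-connected foreground components or
#' 4-connected background components) and are not branch tips (pixels with a
#' single foreground neighbour) are removed sequentially in four directional
#' sub-iterations (north, south, east, west borders) until no pixel can be
#' removed. The result is a single-pixel-wide centerline that preserves the
#' connectivity of the input: same number of 8-connected components, and
#' skeleton pixels are a subset of the input map.
#'
#' @param binary logical matrix (vessel map).
#' @return logical matrix of the same shape (the skeleton map).
#' @export
skeletonize_map <- function(binary) {
  m <- as_binary_matrix(binary)
  if (!any(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # work on a padded copy so neighbour indexing never leaves the matrix
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  np <- nr + 2L
  offs <- .NB_COORDS[, 1] + .NB_COORDS[, 2] * np   # linear-index offsets
  w <- 2L^(0:7)
  lut <- simple_point_lut()
  dir_offs <- c(-1L, 1L, np, -np)                  # N, S, E, W neighbour
  repeat {
    deleted <- FALSE
    for (d in dir_offs) {
      cand <- which(P & !shift_lgl(P, d))
      for (i in cand) {
        if (!P[i]) next
        nb <- P[i + offs]
        nn <- sum(nb)
        if (nn < 2L) next                          # keep tips and isolated pixels
        if (lut[sum(w[nb]) + 1L]) { P[i] <- FALSE; deleted <- TRUE }
      }
    }
    if (!deleted) break
  }
  P[2:(nr + 1L), 2:(nc + 1L)]
}

# Logical shift by a linear-index offset on a padded matrix (helper for the
# directional border test; offset must keep indices in range for all TRUE
# cells, which padding guarantees).
#' @noRd
shift_lgl <- function(P, off) {
  out <- P
  out[] <- FALSE
  n <- length(P)
  idx <- which(P)
  src <- idx - off
  keep <- src >= 1L & src <= n
  out[idx[keep]] <- P[src[keep]]
  out
}

#' Fill small enclosed holes in a binary map
#'
#' Background pockets (4-connected components of background not touching
#' the image border) with at most `max_area` pixels are set to foreground.
#' Used to repair junction-center dropouts left by Hessian-based vessel
#' enhancement; genuine intercapillary spaces are orders of magnitude
#' larger and remain untouched at the default size.
#'
#' @param binary logical matrix.
#' @param max_area largest hole size (pixels) that is filled; 0 is a no-op.
#' @return logical matrix with small holes filled.
#' @export
fill_small_holes <- function(binary, max_area) {
  m <- as_binary_matrix(binary)
  if (max_area <= 0) return(m)
  bg <- label_components(!m, 4L)
  if (bg$n == 0L) return(m)
  border_labels <- unique(c(bg$labels[1, ], bg$labels[nrow(m), ],
                            bg$labels[, 1], bg$labels[, ncol(m)]))
  sizes <- tabulate(bg$labels[bg$labels > 0L], nbins = bg$n)
  fill <- setdiff(which(sizes <= max_area), border_labels)
  if (length(fill)) m[bg$labels %in% fill] <- TRUE
  m
}

#' Perimeter map of a binary vessel map
#'
#' A pixel belongs to the perimeter iff it is a vessel pixel with at least
#' one background 4-neighbour, where pixels beyond the image border count as
#' background. The perimeter is therefore a pixel count, not a geometric
#' contour length.
#'
#' @param binary logical matrix.
#' @return logical matrix of the same shape.
#' @export
perimeter_map <- function(binary) {
  m <- as_binary_matrix(binary)
  m & (neighbor_count4(m) < 4L)
}

# 8- or 4-connected component labelling of a logical matrix.
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  np <- nr + 2L
  offs <- if (connectivity == 8L) .NB_COORDS[, 1] + .NB_COORDS[, 2] * np
          else .N4[, 1] + .N4[, 2] * np
  lab <- matrix(0L, nr + 2L, nc + 2L)
  nlab <- 0L
  for (i in which(P)) {
    if (lab[i] > 0L) next
    nlab <- nlab + 1L
    lab[i] <- nlab
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nbr <- j + offs
      hit <- nbr[P[nbr] & lab[nbr] == 0L]
      lab[hit] <- nlab
      queue <- c(queue, hit)
    }
  }
  list(labels = lab[2:(nr + 1L), 2:(nc + 1L)], n = nlab)
}

#' Count skeleton endpoints and branchpoints
#'
#' Endpoints are skeleton pixels with exactly one skeleton 8-neighbour.
#' Branchpoint pixels have three or more skeleton 8-neighbours; adjacent
#' branchpoint pixels are merged into a single node (8-connected cluster
#' counting), since thick junctions otherwise over-count.
#'
#' @param skeleton logical matrix (skeleton map).
#' @return list with integer counts `bp` and `ep`.
#' @export
count_nodes <- function(skeleton) {
  m <- as_binary_matrix(skeleton)
  deg <- neighbor_count8(m)
  ep <- sum(m & deg == 1L)
  bp <- label_components(m & deg >= 3L, 8L)$n
  list(bp = as.integer(bp), ep = as.integer(ep))
}

#' Decompose a skeleton into vessel branches
#'
#' Skeleton pixels partition into node pixels (>= 3 skeleton 8-neighbours),
#' and non-node pixels whose 8-connected components are simple paths or
#' simple cycles (their degree within the full skeleton is at most 2). Each
#' path component becomes one branch; at each end the branch is extended by
#' one step onto the adjacent node pixel when one exists (the lowest-cost
#' one: orthogonal before diagonal, then lowest row, then lowest column).
#' Pure cycles with no node contact become a single branch with
#' `is_loop = TRUE`.
#'
#' Each branch records its ordered pixel path, the geodesic length along the
#' path (orthogonal step 1, diagonal step `sqrt(2)`) and the Euclidean
#' distance between its two end pixels. Loops have Euclidean length 0.
#'
#' @param skeleton logical matrix.
#' @return list of `vessel_branch` objects (fields `path` — an n x 2 matrix
#'   of (row, col) —, `geodesic_length`, `euclidean_length`, `is_loop`).
#' @export
decompose_branches <- function(skeleton) {
  m <- as_binary_matrix(skeleton)
  if (!any(m)) return(list())
  nr <- nrow(m); nc <- ncol(m)
  deg <- neighbor_count8(m)
  nodepix <- m & deg >= 3L
  interior <- m & !nodepix
  comp <- label_components(interior, 8L)
  branches <- list()
  if (comp$n == 0L) return(branches)

  node_idx <- which(nodepix)
  node_rc <- cbind(row = (node_idx - 1L) %% nr + 1L,
                   col = (node_idx - 1L) %/% nr + 1L)

  # deterministic choice of the node pixel a terminal attaches to
  best_attachment <- function(r, c, exclude = NULL) {
    if (length(node_idx) == 0L) return(NULL)
    dr <- abs(node_rc[, 1] - r); dc <- abs(node_rc[, 2] - c)
    adj <- pmax(dr, dc) == 1L
    if (!is.null(exclude))
      adj <- adj & !(node_rc[, 1] == exclude[1] & node_rc[, 2] == exclude[2])
    if (!any(adj)) return(NULL)
    cost <- ifelse(dr + dc == 1L, 1, sqrt(2))
    ord <- order(cost, node_rc[, 1], node_rc[, 2])
    ord <- ord[adj[ord]]
    node_rc[ord[1], ]
  }

  step_cost <- function(p, q) if (sum(abs(p - q)) == 1L) 1 else sqrt(2)

  for (ci in seq_len(comp$n)) {
    idx <- which(comp$labels == ci)
    rc <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
    npix <- nrow(rc)
    # induced adjacency within the component
    adj_list <- lapply(seq_len(npix), function(i) {
      d1 <- abs(rc[, 1] - rc[i, 1]); d2 <- abs(rc[, 2] - rc[i, 2])
      which(pmax(d1, d2) == 1L)
    })
    ideg <- lengths(adj_list)
    is_cycle <- npix >= 3L && all(ideg == 2L)
    ends <- which(ideg <= 1L)
    start <- if (is_cycle) 1L else ends[order(rc[ends, 1], rc[ends, 2])][1]
    # ordered traversal (unique because induced degree <= 2)
    path <- integer(npix); path[1] <- start
    prev <- 0L
    for (k in seq_len(npix - 1L)) {
      nxt <- setdiff(adj_list[[path[k]]], prev)
      prev <- path[k]
      path[k + 1L] <- nxt[1]
    }
    pts <- rc[path, , drop = FALSE]
    geo <- 0
    if (npix > 1L)
      for (k in seq_len(npix - 1L)) geo <- geo + step_cost(pts[k, ], pts[k + 1L, ])
    if (is_cycle) {
      geo <- geo + step_cost(pts[npix, ], pts[1, ])
      branches[[length(branches) + 1L]] <- vessel_branch(pts, geo, 0, TRUE)
      next
    }
    # attach terminal node pixels, if any
    a1 <- best_attachment(pts[1, 1], pts[1, 2])
    a2 <- if (npix == 1L)
      best_attachment(pts[1, 1], pts[1, 2], exclude = a1)
    else best_attachment(pts[npix, 1], pts[npix, 2])
    if (!is.null(a1)) { geo <- geo + step_cost(a1, pts[1, ]); pts <- rbind(a1, pts) }
    if (!is.null(a2)) { geo <- geo + step_cost(pts[nrow(pts), ], a2); pts <- rbind(pts, a2) }
    euc <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
    branches[[length(branches) + 1L]] <- vessel_branch(pts, geo, euc, euc == 0)
  }
  branches
}

#' Build a vessel branch from an ordered pixel path
#'
#' Convenience constructor for a branch given its ordered (row, col) pixel
#' path: the geodesic length sums the step costs (orthogonal 1, diagonal
#' `sqrt(2)`), the Euclidean length is the straight-line distance between
#' the first and last pixel, and a branch whose endpoints coincide is a
#' loop.
#'
#' @param path n x 2 matrix of (row, col) pixel coordinates, n >= 2 (each
#'   consecutive pair must be 8-adjacent).
#' @return a `vessel_branch` object.
#' @export
vessel_branch_from_path <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2)
    stop_octalens("a branch path needs at least 2 points",
                  "octalens_parameter_error")
  steps <- abs(path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])
  if (any(rowSums(steps) == 0) || any(steps > 1))
    stop_octalens("consecutive path pixels must be distinct and 8-adjacent",
                  "octalens_parameter_error")
  geo <- sum(ifelse(rowSums(steps) == 1L, 1, sqrt(2)))
  euc <- sqrt(sum((path[1, ] - path[nrow(path), ])^2))
  vessel_branch(path, geo, euc, euc == 0)
}

#' @noRd
vessel_branch <- function(path, geodesic, euclidean, is_loop) {
  dimnames(path) <- list(NULL, c("row", "col"))
  structure(list(path = path,
                 geodesic_length = geodesic,
                 euclidean_length = euclidean,
                 is_loop = is_loop),
            class = "vessel_branch")
}

#' @export
print.vessel_branch <- function(x, ...) {
  cat(sprintf("<vessel_branch> %d px, geodesic %.3f, euclidean %.3f%s\n",
              nrow(x$path), x$geodesic_length, x$euclidean_length,
              if (x$is_loop) ", loop" else ""))
  invisible(x)
}
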