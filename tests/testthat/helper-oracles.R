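# Brute-force oracles, written independently of the package internals:
# direct double loops, distance matrices and union-find instead of the
# padded-matrix BFS/traversal code used by the implementation.

# perimeter: vessel pixel with a background 4-neighbour (border = background)
oracle_perimeter_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    if (i == 1 || i == nr || j == 1 || j == nc ||
        !mask[i - 1, j] || !mask[i + 1, j] ||
        !mask[i, j - 1] || !mask[i, j + 1]) cnt <- cnt + 1L
  }
  cnt
}

# union-find components over a pixel set given an adjacency predicate
.uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# endpoint / clustered-branchpoint counts from pairwise distances
oracle_count_nodes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(bp = 0L, ep = 0L))
  D <- as.matrix(stats::dist(idx, method = "maximum"))
  A <- D <= 1 & D > 0
  deg <- rowSums(A)
  ep <- sum(deg == 1)
  bpix <- which(deg >= 3)
  bp <- if (!length(bpix)) 0L else {
    comp <- .uf_components(A[bpix, bpix, drop = FALSE])
    length(unique(comp))
  }
  list(bp = as.integer(bp), ep = as.integer(ep))
}

# branch decomposition signature: same definition as the implementation
# (node pixels = degree >= 3, interior components are paths/cycles, lowest
# (cost, row, col) node attachment per terminal), different machinery.
oracle_branch_signature <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(n = 0L, loops = 0L, geo = numeric(0), euc = numeric(0)))
  n <- nrow(idx)
  D <- as.matrix(stats::dist(idx, method = "maximum"))
  A <- D <= 1 & D > 0
  deg <- rowSums(A)
  node <- deg >= 3
  geo <- euc <- numeric(0); loops <- 0L
  int_id <- which(!node)
  if (!length(int_id)) return(list(n = 0L, loops = 0L, geo = geo, euc = euc))
  Ai <- A[int_id, int_id, drop = FALSE]
  comp <- .uf_components(Ai)
  cost <- function(p, q) if (sum(abs(p - q)) == 1) 1 else sqrt(2)
  for (cc in unique(comp)) {
    mem <- int_id[comp == cc]
    k <- length(mem)
    # sum of all internal edges (valid: induced graph is a path or cycle)
    g <- 0
    if (k > 1) for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (A[mem[a], mem[b]]) g <- g + cost(idx[mem[a], ], idx[mem[b], ])
    }
    ideg <- if (k == 1) 0 else rowSums(A[mem, mem, drop = FALSE])
    if (k >= 3 && all(ideg == 2)) {        # pure cycle
      loops <- loops + 1L
      geo <- c(geo, g); euc <- c(euc, 0)
      next
    }
    ends <- if (k == 1) c(mem, mem) else {
      e <- mem[ideg <= 1]
      e[order(idx[e, 1], idx[e, 2])]
    }
    pick <- function(end, exclude = NA) {
      cand <- which(node & A[, end])
      cand <- setdiff(cand, exclude)
      if (!length(cand)) return(NA_integer_)
      cc_ <- vapply(cand, function(q) cost(idx[q, ], idx[end, ]), numeric(1))
      cand[order(cc_, idx[cand, 1], idx[cand, 2])][1]
    }
    a1 <- pick(ends[1])
    a2 <- if (k == 1) pick(ends[2], exclude = a1) else pick(ends[2])
    p_start <- if (is.na(a1)) idx[ends[1], ] else idx[a1, ]
    p_end <- if (is.na(a2)) idx[ends[2], ] else idx[a2, ]
    if (!is.na(a1)) g <- g + cost(idx[a1, ], idx[ends[1], ])
    if (!is.na(a2)) g <- g + cost(idx[a2, ], idx[ends[2], ])
    e_ <- sqrt(sum((p_start - p_end)^2))
    if (e_ == 0) loops <- loops + 1L
    geo <- c(geo, g); euc <- c(euc, e_)
  }
  list(n = length(geo), loops = loops,
       geo = sort(round(geo, 9)), euc = sort(round(euc, 9)))
}

impl_branch_signature <- function(branches) {
  geo <- vapply(branches, function(b) b$geodesic_length, numeric(1))
  euc <- vapply(branches, function(b) b$euclidean_length, numeric(1))
  list(n = length(branches),
       loops = sum(vapply(branches, function(b) b$is_loop, logical(1))),
       geo = sort(round(geo, 9)), euc = sort(round(euc, 9)))
}

# exhaustive-scan Otsu on an integer 0-255 grid: try all 256 thresholds,
# maximize between-class variance computed straight from the pixel values
oracle_otsu_integer <- function(v) {
  v <- as.numeric(v)
  best_t <- NA; best_s <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# rasterization: pixels strictly within w/2 of the segment
oracle_stroke_pixel_count <- function(p0, p1, w, size) {
  cnt <- 0L
  for (x in seq_len(size)) for (y in seq_len(size)) {
    vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
    l2 <- vx^2 + vy^2
    t <- if (l2 == 0) 0 else max(0, min(1, ((x - p0[1]) * vx + (y - p0[2]) * vy) / l2))
    d <- sqrt((x - (p0[1] + t * vx))^2 + (y - (p0[2] + t * vy))^2)
    if (d < w / 2) cnt <- cnt + 1L
  }
  cnt
}

# one-way within-subject ANOVA through stats::aov (independent route)
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(seq_len(n), k)),
                   time = factor(rep(seq_len(k), each = n)))
  s <- summary(stats::aov(y ~ time + Error(subj / time), data = df))
  tab <- s[["Error: subj:time"]][[1]]
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df1 = tab[["Df"]][1], df2 = tab[["Df"]][2])
}

# textbook Pearson r and its t-based two-sided p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}

# random small binary mask for the oracle sweeps
random_mask <- function(nr, nc, p) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# a diamond ring (L1 circle): every pixel has exactly two 8-neighbours
diamond_ring <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(i - ctr) + abs(j - ctr) == radius) m[i, j] <- TRUE
  m
}
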