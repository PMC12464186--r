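# Internal helpers shared across the image-analysis modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a matrix by (dr, dc), filling exposed cells with `fill`.
# dr > 0 moves content down (towards larger row indices).
#' @noRd
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Offsets of the 8-neighbourhood, orthogonal steps first.
.N8 <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
             dc = c(0, 0, -1, 1, -1, 1, -1, 1))
.N4 <- .N8[1:4, , drop = FALSE]

# Count foreground 8-neighbours of every pixel of a logical matrix.
#' @noRd
neighbor_count8 <- function(mask) {
  m <- mask * 1L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(.N8)))
    out <- out + shift_mat(m, .N8[i, 1], .N8[i, 2], 0L)
  out
}

# Count foreground 4-neighbours (border counts as background / zero fill).
#' @noRd
neighbor_count4 <- function(mask) {
  m <- mask * 1L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(.N4)))
    out <- out + shift_mat(m, .N4[i, 1], .N4[i, 2], 0L)
  out
}

# Replicate-boundary separable convolution along rows / columns done with a
# banded matrix product; `kernel` is centered (odd length).
#' @noRd
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (t in -r:r) {
    j <- pmin(pmax(seq_len(n) + t, 1L), n)   # replicate boundary
    w <- kernel[t + r + 1L]
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + w
  }
  M
}

# Separable convolution of image `img` with kernel ky along rows (first
# index) and kx along columns (second index).
#' @noRd
sep_convolve <- function(img, ky, kx) {
  My <- conv_band_matrix(nrow(img), ky)
  Mx <- conv_band_matrix(ncol(img), kx)
  My %*% img %*% t(Mx)
}

# Sampled Gaussian and its first/second derivatives at scale sigma,
# all using the common normalisation that makes the smoother sum to 1.
#' @noRd
gaussian_kernels <- function(sigma) {
  r <- max(2L, as.integer(ceiling(3.5 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  s <- sum(g)
  g0 <- g / s
  g1 <- (-x / sigma^2) * g / s
  g2 <- ((x^2 - sigma^2) / sigma^4) * g / s
  g2 <- g2 - sum(g2) / length(g2)   # exact zero response to constants
  list(g0 = g0, g1 = g1, g2 = g2, radius = r)
}

# Evaluate a polynomial with coefficients c0 + c1 x + ... at x.
#' @noRd
polyval_asc <- function(coeffs, x) {
  out <- rep(0, length(x))
  for (j in rev(seq_along(coeffs))) out <- out * x + coeffs[j]
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of (params, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @noRd
stop_octalens <- function(msg, class) {
  stop(structure(class = c(class, "octalens_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
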