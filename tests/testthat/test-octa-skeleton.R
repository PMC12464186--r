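# Thinning, perimeter, node counting and branch decomposition.

test_that("a solid bar thins to a single one-pixel-wide line", {
  bar <- matrix(FALSE, 10, 40)
  bar[4:6, 5:34] <- TRUE                     # 3 x 30 bar
  sk <- skeletonize_map(bar)
  expect_equal(octalens:::label_components(sk)$n, 1L)
  expect_gte(sum(sk), 26)
  expect_lte(sum(sk), 30)
  # single-pixel wide: no 2x2 all-true block
  blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -1] & sk[-1, -1]
  expect_false(any(blocks))
  expect_true(all(bar[sk]))                  # skeleton subset of the map
})

test_that("thinning is idempotent on minimal inputs", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_identical(skeletonize_map(m), m)
  expect_identical(skeletonize_map(matrix(FALSE, 4, 4)),
                   matrix(FALSE, 4, 4))
})

test_that("thinning preserves the number of components", {
  two <- matrix(FALSE, 12, 30)
  two[3:5, 2:28] <- TRUE
  two[9:11, 2:28] <- TRUE
  expect_equal(octalens:::label_components(skeletonize_map(two))$n, 2L)
  set.seed(99)
  for (rep in 1:8) {                          # random unions of rectangles
    m <- matrix(FALSE, 40, 40)
    for (k in 1:5) {
      r <- sort(sample(3:38, 2)); c <- sort(sample(3:38, 2))
      m[r[1]:r[2], c[1]:c[2]] <- TRUE
    }
    sk <- skeletonize_map(m)
    expect_equal(octalens:::label_components(sk)$n,
                 octalens:::label_components(m)$n)
    expect_true(all(m[sk]))
    blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    expect_false(any(blocks))
  }
})

test_that("perimeter follows the boundary-pixel definition", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 6:15] <- TRUE                      # 10x10 solid square
  expect_equal(sum(perimeter_map(m)), 36L)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(sum(perimeter_map(one)), 1L)
  line <- matrix(FALSE, 5, 30); line[3, 2:29] <- TRUE
  expect_identical(perimeter_map(line), line)  # every line pixel is contour
  # border counts as background
  full <- matrix(TRUE, 6, 6)
  expect_equal(sum(perimeter_map(full)), 20L)
  # every perimeter pixel is a vessel pixel with a background 4-neighbour
  set.seed(3)
  r <- random_mask(15, 15, 0.5)
  p <- perimeter_map(r)
  expect_true(all(r[p]))
  expect_equal(sum(p), oracle_perimeter_count(r))
})

test_that("small enclosed holes are filled, real gaps are not", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 5:15] <- TRUE
  m[9:10, 9:10] <- FALSE                     # 4 px hole
  expect_true(all(fill_small_holes(m, 10)[5:15, 5:15]))
  expect_identical(fill_small_holes(m, 2), m) # too large for the budget
  # a border-touching notch is not an enclosed hole
  notch <- matrix(TRUE, 8, 8); notch[1:4, 4] <- FALSE
  expect_identical(fill_small_holes(notch, 50), notch)
})

test_that("endpoint and branchpoint counts follow the degree rules", {
  line <- matrix(FALSE, 7, 30); line[4, 3:28] <- TRUE
  expect_equal(count_nodes(line), list(bp = 0L, ep = 2L))
  plus <- matrix(FALSE, 25, 25)
  plus[13, 3:23] <- TRUE; plus[3:23, 13] <- TRUE
  expect_equal(count_nodes(plus), list(bp = 1L, ep = 4L))
  ywig <- matrix(FALSE, 20, 20)
  ywig[10:18, 10] <- TRUE                     # stem
  for (k in 1:7) { ywig[10 - k, 10 - k] <- TRUE; ywig[10 - k, 10 + k] <- TRUE }
  expect_equal(count_nodes(ywig), list(bp = 1L, ep = 3L))
})

test_that("branch decomposition handles stars, paths and cycles", {
  plus <- matrix(FALSE, 25, 25)
  plus[13, 3:23] <- TRUE; plus[3:23, 13] <- TRUE
  br <- decompose_branches(plus)
  expect_length(br, 4)
  for (b in br) {
    expect_equal(b$geodesic_length, b$euclidean_length, tolerance = 1e-12)
    expect_false(b$is_loop)
  }
  ring <- diamond_ring(6)
  br <- decompose_branches(ring)
  expect_length(br, 1)
  expect_true(br[[1]]$is_loop)
  expect_equal(br[[1]]$euclidean_length, 0)
  expect_equal(br[[1]]$geodesic_length, 24 * sqrt(2), tolerance = 1e-9)
  expect_identical(impl_branch_signature(br), oracle_branch_signature(ring))
})

test_that("branch paths are ordered chains inside the skeleton", {
  tr <- generate_vascular_tree(depth = 3, density = 1, seed = 21)
  img <- render_octa_image(tr)
  sk <- skeletonize_map(binarize(img$pixels, 115))
  for (b in decompose_branches(sk)) {
    expect_gte(b$geodesic_length, b$euclidean_length - 1e-9)
    steps <- abs(diff(b$path))
    expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
    expect_identical(b$is_loop, b$euclidean_length == 0)
  }
})

test_that("decomposition agrees with the pixel-graph oracle on random masks", {
  set.seed(1234)
  for (rep in 1:300) {
    m <- random_mask(5, 5, sample(c(0.3, 0.5, 0.7), 1))
    expect_identical(impl_branch_signature(decompose_branches(m)),
                     oracle_branch_signature(m))
    expect_identical(count_nodes(m), oracle_count_nodes(m))
    expect_equal(sum(perimeter_map(m)), oracle_perimeter_count(m))
  }
})

test_that("branches built from explicit paths validate their geometry", {
  b <- vessel_branch_from_path(cbind(5, 5:15))
  expect_equal(b$geodesic_length, 10)
  expect_equal(b$euclidean_length, 10)
  expect_error(vessel_branch_from_path(cbind(1, 1)),
               class = "octalens_parameter_error")
  expect_error(vessel_branch_from_path(rbind(c(1, 1), c(3, 1))),
               class = "octalens_parameter_error")
})
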