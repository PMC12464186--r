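# The nine perfusion metrics and the quantification driver.

test_that("vessel area density is the exact pixel-count ratio", {
  expect_equal(compute_vad(matrix(TRUE, 8, 8)), 1)
  expect_equal(compute_vad(matrix(FALSE, 8, 8)), 0)
  m <- matrix(FALSE, 30, 30); m[1:10, 1:27] <- TRUE   # 270 of 900
  expect_equal(compute_vad(m), 0.3)
})

test_that("vessel diameter index relates area to skeleton length", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(compute_vdi(one, one), 1)
  bar <- matrix(FALSE, 10, 40); bar[4:6, 5:34] <- TRUE
  vdi <- compute_vdi(bar, skeletonize_map(bar))
  expect_gte(vdi, 3.0); expect_lte(vdi, 3.5)
  expect_error(compute_vdi(bar, matrix(FALSE, 10, 40)),
               class = "octalens_degenerate_error")
})

test_that("wider strokes of the same tree increase VDI and decrease VPI", {
  tr <- generate_vascular_tree(depth = 2, density = 1, seed = 13,
                               tortuosity_amplitude = 0)
  res <- lapply(c(3, 6), function(w) {
    t2 <- tr; t2$diameters <- rep(w, length(tr$diameters))
    img <- render_octa_image(t2)
    b <- binarize(img$pixels, 115)
    list(vdi = compute_vdi(b, skeletonize_map(b)),
         vpi = compute_vpi(perimeter_map(b), b))
  })
  expect_gt(res[[2]]$vdi, res[[1]]$vdi)
  expect_lt(res[[2]]$vpi, res[[1]]$vpi)
})

test_that("vessel perimeter index matches forced counts", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(compute_vpi(perimeter_map(sq), sq), 0.36)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(compute_vpi(perimeter_map(one), one), 1)
  line <- matrix(FALSE, 5, 30); line[3, 2:29] <- TRUE
  expect_equal(compute_vpi(perimeter_map(line), line), 1)
  expect_error(compute_vpi(line, matrix(FALSE, 5, 30)),
               class = "octalens_degenerate_error")
})

test_that("tortuosity is the mean geodesic over Euclidean ratio", {
  straight <- vessel_branch_from_path(cbind(4, 2:12))
  expect_equal(as.numeric(compute_bvt(list(straight))), 1)
  # L path: 10 orthogonal steps right then 10 down
  L <- vessel_branch_from_path(rbind(cbind(2, 2:12), cbind(3:12, 12)))
  expect_equal(as.numeric(compute_bvt(list(L))), 20 / (10 * sqrt(2)),
               tolerance = 1e-12)
  # loops are excluded from the mean, their count is reported
  ring <- decompose_branches(diamond_ring(5))[[1]]
  bvt <- compute_bvt(list(straight, L, ring))
  expect_equal(as.numeric(bvt), mean(c(1, 20 / (10 * sqrt(2)))),
               tolerance = 1e-12)
  expect_equal(attr(bvt, "excluded_loops"), 1L)
  expect_error(compute_bvt(list(ring)), class = "octalens_degenerate_error")
  expect_error(compute_bvt(list()), class = "octalens_degenerate_error")
})

test_that("complexity index follows the isoperimetric form", {
  bar <- matrix(FALSE, 5, 104); bar[3, 3:102] <- TRUE   # 1 x 100 bar
  expect_equal(compute_vci(perimeter_map(bar), bar), 100^2 / (4 * pi * 100),
               tolerance = 1e-12)
  # two disjoint copies double the index: (2P)^2 / (4 pi 2A) = 2 VCI
  two <- matrix(FALSE, 30, 30)
  two[5:10, 5:10] <- TRUE; two[20:25, 20:25] <- TRUE
  one <- matrix(FALSE, 30, 30); one[5:10, 5:10] <- TRUE
  expect_equal(compute_vci(perimeter_map(two), two),
               2 * compute_vci(perimeter_map(one), one), tolerance = 1e-12)
})

test_that("a large rasterized disk approaches the isoperimetric limit", {
  r <- 100; n <- 2 * r + 9; ctr <- (n + 1) / 2
  g <- expand.grid(row = 1:n, col = 1:n)
  disk <- matrix(sqrt((g$row - ctr)^2 + (g$col - ctr)^2) <= r, n, n)
  P <- perimeter_map(disk)
  vci <- compute_vci(P, disk)
  # boundary-pixel perimeter of a digital disk is shorter than 2*pi*r, so
  # the digital limit sits below 1; radius 100 lands within 0.25 of it
  expect_equal(vci, sum(P)^2 / (4 * pi * sum(disk)), tolerance = 1e-12)
  expect_lt(abs(vci - 1), 0.25)
  r2 <- 10; n2 <- 2 * r2 + 9; c2 <- (n2 + 1) / 2
  g2 <- expand.grid(row = 1:n2, col = 1:n2)
  d2 <- matrix(sqrt((g2$row - c2)^2 + (g2$col - c2)^2) <= r2, n2, n2)
  expect_gt(vci, compute_vci(perimeter_map(d2), d2))  # approaches from below
})

test_that("total and average vessel length follow the skeleton counts", {
  line <- matrix(FALSE, 7, 54); line[4, 3:52] <- TRUE   # 50 px line
  br <- decompose_branches(line)
  len <- vessel_lengths(line, br)
  expect_equal(len$tvl, 50L)
  expect_equal(len$avl, 50)
  plus <- matrix(FALSE, 25, 25)
  plus[13, 3:23] <- TRUE; plus[3:23, 13] <- TRUE
  brp <- decompose_branches(plus)
  lp <- vessel_lengths(plus, brp)
  expect_equal(lp$avl, lp$tvl / 4)
  # two disjoint equal lines: TVL doubles, AVL unchanged
  two <- matrix(FALSE, 9, 54); two[3, 3:52] <- TRUE; two[7, 3:52] <- TRUE
  l2 <- vessel_lengths(two, decompose_branches(two))
  expect_equal(l2$tvl, 100L)
  expect_equal(l2$avl, 50)
  expect_error(vessel_lengths(line, list()),
               class = "octalens_degenerate_error")
})

test_that("quantify is deterministic and honours the quality gate", {
  tr <- generate_vascular_tree(depth = 2, density = 1, seed = 3, canvas = 96)
  img_ok <- render_octa_image(tr, quality_index = 30)
  img_bad <- render_octa_image(tr, quality_index = 29)
  m1 <- quantify(img_ok)
  m2 <- quantify(img_ok)
  expect_identical(m1, m2)
  expect_error(quantify(img_bad), class = "octalens_quality_error")
  expect_error(quantify(img_bad), regexp = "quality index < 30")
  # the gate is configurable
  expect_s3_class(quantify(img_bad, quant_config(min_quality_index = 20)),
                  "perfusion_metrics")
})

test_that("metric identities hold exactly on quantified images", {
  tr <- generate_vascular_tree(depth = 3, density = 1, seed = 6, canvas = 128)
  img <- render_octa_image(tr, quality_index = 60)
  v <- frangi_enhance(img)
  b <- fill_small_holes(binarize(v, otsu_threshold(v)), 10)
  sk <- skeletonize_map(b)
  p <- perimeter_map(b)
  m <- quantify(img)
  expect_equal(m$vad * length(b), sum(b))
  expect_equal(m$vdi * m$tvl, sum(b))
  expect_equal(m$vpi * sum(b), sum(p))
  expect_equal(m$tvl, sum(sk))
  expect_true(all(b[sk]))                    # skeleton subset of binary
  expect_true(all(b[p]))                     # perimeter subset of binary
})
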