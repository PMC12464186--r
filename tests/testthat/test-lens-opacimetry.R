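# AS-OCT lens densitometry: edge detection, robust quartic fitting, mask
# construction, opacity measurement and series averaging.

test_that("lens scenes render with the configured intensities", {
  sc <- default_lens_scene(cortex_intensity = 40, nucleus_intensity = 40)
  sc$nucleus_ellipse <- NULL
  bs <- generate_lens_bscan(sc)
  tm <- octalens:::scene_lens_mask(sc, bs$height, bs$width)
  expect_equal(mean(bs$pixels[tm]), 40)      # uniform region, exact
  sc2 <- default_lens_scene(cortex_intensity = 40, nucleus_intensity = 60)
  bs2 <- generate_lens_bscan(sc2)
  tm2 <- octalens:::scene_lens_mask(sc2, bs2$height, bs2$width)
  m <- mean(bs2$pixels[tm2])
  expect_gt(m, 40); expect_lt(m, 60)         # mixture of the two levels
})

test_that("artifact columns carry no foreground after thresholding", {
  sc <- default_lens_scene(artifact_columns = c(60, 61, 150))
  bs <- generate_lens_bscan(sc)
  thr <- otsu_threshold(bs$pixels)
  expect_false(any(bs$pixels[, c(60, 61, 150)] > thr))
  edges <- detect_lens_edges(bs)
  expect_true(all(is.na(edges$anterior_y[c(60, 61, 150)])))
})

test_that("crossing surfaces raise a geometry error", {
  sc <- lens_scene_truth(anterior_coeffs = c(100, 0, 0, 0, 0),
                         posterior_coeffs = c(40, 0, 0, 0, 0))
  expect_error(generate_lens_bscan(sc), class = "octalens_geometry_error")
})

test_that("edge detection tracks the true quartic surfaces", {
  sc <- default_lens_scene()
  bs <- generate_lens_bscan(sc)
  edges <- detect_lens_edges(bs)
  s <- octalens:::scene_surfaces(sc, edges$col)
  ok <- !is.na(edges$anterior_y)
  err_a <- abs(edges$anterior_y[ok] - s$anterior[ok])
  err_p <- abs(edges$posterior_y[ok] - s$posterior[ok])
  expect_gte(mean(err_a <= 1), 0.95)
  expect_gte(mean(err_p <= 1), 0.95)
  # fully-foreground column: anterior first row, posterior last row
  m <- matrix(0, 30, 20); m[, 7] <- 200
  e <- detect_lens_edges(m, threshold = 100)
  expect_equal(e$anterior_y[7], 1L)
  expect_equal(e$posterior_y[7], 30L)
  expect_error(detect_lens_edges(matrix(0, 10, 10), threshold = 10),
               class = "octalens_segmentation_error")
})

test_that("noiseless quartic samples are recovered to machine-level error", {
  coef_true <- c(30, 0.2, -0.004, 2e-5, 1.5e-8)
  x <- 10:220
  y <- octalens:::polyval_asc(coef_true, x)
  fit <- fit_surface_polynomial(x, y)
  expect_lt(max(abs(predict(fit, x) - y)), 0.5)
  expect_equal(fit$corrected_points, 0L)
  expect_true(fit$converged)
})

test_that("gross outliers are corrected without breaking recovery", {
  set.seed(8)
  coef_true <- c(30, 0.2, -0.004, 2e-5, 1.5e-8)
  x <- 10:220
  y <- octalens:::polyval_asc(coef_true, x)
  bad <- sample(seq_along(x), round(0.1 * length(x)))
  y_c <- y; y_c[bad] <- y_c[bad] + 50
  fit <- fit_surface_polynomial(x, y_c)
  expect_lt(max(abs(predict(fit, x) - y)), 0.5)
  expect_gte(fit$corrected_points, round(0.8 * length(bad)))
})

test_that("the correction-disabled limit equals plain least squares", {
  set.seed(9)
  x <- 1:120
  y <- octalens:::polyval_asc(c(10, 0.3, -0.002, 1e-5, -2e-8), x) + rnorm(120)
  fit_inf <- fit_surface_polynomial(x, y, deviation_k = 1e9)
  beta <- stats::lm(y ~ poly(x, 4, raw = TRUE))$coefficients
  expect_equal(unname(fit_inf$coeffs), unname(beta), tolerance = 1e-6)
  expect_equal(fit_inf$corrected_points, 0L)
})

test_that("underdetermined fits are rejected", {
  expect_error(fit_surface_polynomial(1:4, c(1, 2, 3, 4)),
               class = "octalens_underdetermined_error")
})

test_that("the lens mask is exactly the strict between-surfaces region", {
  flat_a <- fit_surface_polynomial(1:100, rep(10, 100))
  flat_p <- fit_surface_polynomial(1:100, rep(50, 100))
  mask <- build_lens_mask(flat_a, flat_p, height = 60, width = 100)
  expect_equal(sum(mask), 39 * 100)
  expect_equal(range(which(rowSums(mask) > 0)), c(11, 49))
  expect_error(build_lens_mask(flat_p, flat_a, 60, 100),
               class = "octalens_geometry_error")
})

test_that("segmentation overlaps the true lens region almost perfectly", {
  sc <- default_lens_scene()
  bs <- generate_lens_bscan(sc)
  seg <- octalens:::segment_lens_scan(bs)
  tm <- octalens:::scene_lens_mask(sc, bs$height, bs$width)
  dice <- 2 * sum(seg$mask & tm) / (sum(seg$mask) + sum(tm))
  expect_gte(dice, 0.95)
})

test_that("mean opacity is the arithmetic mean under the mask", {
  img <- matrix(0, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:14, 5:14] <- TRUE
  img[5:14, 5:9] <- 30; img[5:14, 10:14] <- 50
  expect_equal(mean_opacity(img, mask), 40)
  img2 <- matrix(40, 20, 20)
  expect_equal(mean_opacity(img2, mask), 40)
  expect_error(mean_opacity(img, matrix(FALSE, 20, 20)),
               class = "octalens_degenerate_error")
})

test_that("noise-free opacity equals the analytic cortex/nucleus mixture", {
  sc <- default_lens_scene(cortex_intensity = 40, nucleus_intensity = 60)
  bs <- generate_lens_bscan(sc)
  tm <- octalens:::scene_lens_mask(sc, bs$height, bs$width)
  nm <- octalens:::scene_nucleus_mask(sc, bs$height, bs$width) & tm
  expected <- (40 * (sum(tm) - sum(nm)) + 60 * sum(nm)) / sum(tm)
  seg <- octalens:::segment_lens_scan(bs)
  expect_equal(mean_opacity(bs, seg$mask), expected, tolerance = 0.02)
})

test_that("the nuclear ROI reads the nucleus", {
  sc <- default_lens_scene(cortex_intensity = 40, nucleus_intensity = 60)
  bs <- generate_lens_bscan(sc)
  seg <- octalens:::segment_lens_scan(bs)
  # ellipse fully inside the uniform nucleus
  e <- sc$nucleus_ellipse
  inner <- list(center = e$center, semi_axes = 0.4 * e$semi_axes, rotation = 0)
  expect_equal(as.numeric(nucleus_roi(bs, seg$mask, roi = inner)), 60)
  # auto ROI: nuclear value above the whole-lens value
  nuc <- as.numeric(nucleus_roi(bs, seg$mask))
  expect_gt(nuc, mean_opacity(bs, seg$mask))
  # ellipse entirely outside the mask
  far <- list(center = c(5, 5), semi_axes = c(2, 2), rotation = 0)
  expect_error(nucleus_roi(bs, seg$mask, roi = far),
               class = "octalens_roi_error")
})

test_that("series averaging is the arithmetic mean and order-invariant", {
  sc <- default_lens_scene(speckle_sd = 0.15)
  scans <- generate_lens_series(sc, n_scans = 15, seed = 3)
  res <- lens_opacity_from_series(scans)
  expect_equal(res$lens_opacity, mean(res$per_scan_lens))
  expect_equal(res$nuclear_opacity, mean(res$per_scan_nucleus))
  res_perm <- lens_opacity_from_series(rev(scans))
  expect_equal(res_perm$lens_opacity, res$lens_opacity)
  expect_true(all(res$per_scan_lens >= 0 & res$per_scan_lens <= 255))
  # identical scans: series equals the single-scan value
  same <- lens_opacity_from_series(rep(scans[1], 15))
  expect_equal(same$lens_opacity, res$per_scan_lens[1])
  # wrong count is an error
  expect_error(lens_opacity_from_series(scans[1:7]),
               class = "octalens_parameter_error")
  # an unsegmentable scan names its index
  broken <- scans
  broken[[4]] <- asoct_scan(matrix(0, 140, 200), scan_index = 4L)
  expect_error(lens_opacity_from_series(broken), regexp = "scan 4",
               class = "octalens_segmentation_error")
})

test_that("cumulative dissipated energy is the power-time product", {
  expect_equal(compute_cde(0, 123), 0)
  expect_equal(compute_cde(5, 2), 10)
  expect_equal(compute_cde(1, 1), 1)
  expect_error(compute_cde(-1, 5), class = "octalens_parameter_error")
  expect_error(compute_cde(5, -1), class = "octalens_parameter_error")
})
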