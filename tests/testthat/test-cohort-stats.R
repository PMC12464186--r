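# Repeated-measures ANOVA, sphericity, Greenhouse-Geisser correction and
# the Pearson correlation screen.

test_that("within-subject ANOVA matches the independent aov route", {
  set.seed(11)
  for (rep in 1:5) {
    Y <- matrix(rnorm(6 * 3, mean = rep(c(0, 0.4, 0.9), each = 6)), 6, 3)
    mine <- rm_anova(Y)
    ora <- oracle_rm_anova(Y)
    expect_equal(mine$f_stat, ora$f, tolerance = 1e-10)
    expect_equal(mine$df_num_uncorrected, ora$df1)
    expect_equal(mine$df_den_uncorrected, ora$df2)
    # compare p on the uncorrected scale (aov never corrects)
    p_uncorr <- pf(mine$f_stat, mine$df_num_uncorrected,
                   mine$df_den_uncorrected, lower.tail = FALSE)
    expect_equal(p_uncorr, ora$p, tolerance = 1e-10)
  }
})

test_that("subjects constant over time give zero F", {
  Y <- matrix(rep(c(3, 7, 1, 9), 4), 4, 4)
  an <- rm_anova(Y)
  expect_equal(an$f_stat, 0)
  expect_equal(an$ss_time, 0)
})

test_that("ANOVA is invariant to global and per-subject constant offsets", {
  set.seed(12)
  Y <- matrix(rnorm(40), 10, 4)
  a <- rm_anova(Y)
  b <- rm_anova(Y + 100)
  c <- rm_anova(Y + matrix(rnorm(10), 10, 4))   # subject offsets
  expect_equal(a$f_stat, b$f_stat, tolerance = 1e-9)
  expect_equal(a$f_stat, c$f_stat, tolerance = 1e-9)
})

test_that("missing cells and single subjects are rejected", {
  Y <- matrix(rnorm(12), 4, 3); Y[2, 2] <- NA
  expect_error(rm_anova(Y), class = "octalens_missing_error")
  expect_error(rm_anova(matrix(1:4, 1, 4)),
               class = "octalens_parameter_error")
})

test_that("Mauchly's W matches the eigenvalue formula and base R", {
  set.seed(13)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  mine <- mauchly_test(Y)
  base <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(mine$w_stat, unname(base$statistic), tolerance = 1e-10)
  # direct eigenvalue oracle
  Cm <- octalens:::orthonormal_contrasts(4)
  ev <- eigen(stats::cov(Y %*% Cm), symmetric = TRUE)$values
  expect_equal(mine$w_stat, prod(ev) / mean(ev)^3, tolerance = 1e-12)
  expect_equal(mine$df, 5)
})

test_that("compound-symmetric data are spherical with W near one", {
  set.seed(14)
  n <- 60; k <- 4
  subj <- rnorm(n, sd = 2)
  Y <- matrix(subj, n, k) + matrix(rnorm(n * k), n, k)
  mt <- mauchly_test(Y)
  expect_gt(mt$w_stat, 0.8)
  expect_gt(mt$p_value, 0.05)
  # exactly compound-symmetric covariance, constructed: W == 1
  S <- matrix(0.5, k, k); diag(S) <- 1
  L <- chol(S)
  Z <- matrix(rnorm(2000 * k), 2000, k) %*% L
  Zc <- scale(Z, scale = FALSE)
  # force the sample contrast covariance to the identity eigenstructure
  Cm <- octalens:::orthonormal_contrasts(k)
  Sc <- stats::cov(Zc %*% Cm)
  E <- eigen(Sc, symmetric = TRUE)
  W <- Zc %*% Cm %*% E$vectors %*% diag(1 / sqrt(E$values))
  Yexact <- W   # contrast scores with exactly identity covariance
  ev <- eigen(stats::cov(Yexact), symmetric = TRUE)$values
  expect_equal(prod(ev) / mean(ev)^(k - 1), 1, tolerance = 1e-6)
})

test_that("k = 2 timepoints pass sphericity trivially", {
  Y <- matrix(rnorm(20), 10, 2)
  mt <- mauchly_test(Y)
  expect_true(mt$trivial)
  expect_equal(mt$w_stat, 1)
})

test_that("Greenhouse-Geisser epsilon matches base R and its limits", {
  set.seed(15)
  Y <- matrix(rnorm(10 * 4), 10, 4)
  # trace-formula oracle: eps = tr(S_c)^2 / ((k-1) tr(S_c^2))
  Cm <- octalens:::orthonormal_contrasts(4)
  Sc <- stats::cov(Y %*% Cm)
  eps_oracle <- sum(diag(Sc))^2 / (3 * sum(Sc * Sc))
  expect_equal(gg_epsilon(Y), eps_oracle, tolerance = 1e-10)
  # spherical construction: epsilon 1 within numerical tolerance
  k <- 4
  Cm <- octalens:::orthonormal_contrasts(k)
  set.seed(16)
  Z <- matrix(rnorm(500 * (k - 1)), 500, k - 1)
  Zc <- scale(Z, scale = FALSE)
  E <- eigen(stats::cov(Zc), symmetric = TRUE)
  Zw <- Zc %*% E$vectors %*% diag(1 / sqrt(E$values))   # identity covariance
  Ysph <- Zw %*% t(Cm)
  expect_equal(gg_epsilon(Ysph), 1, tolerance = 1e-6)
  # one dominant eigenvalue drives epsilon to the lower bound
  Ydom <- matrix(rnorm(40), 40, 1) %*% t(c(1, -1, 1, -1)) +
    1e-4 * matrix(rnorm(160), 40, 4)
  eps <- gg_epsilon(Ydom)
  expect_lt(eps, 1 / 3 + 0.01)
  expect_gte(eps, 1 / 3)
  # clamp contract on arbitrary input
  expect_gte(gg_epsilon(Y), 1 / 3)
  expect_lte(gg_epsilon(Y), 1)
})

test_that("corrected p-values are never smaller than uncorrected ones", {
  set.seed(17)
  for (rep in 1:10) {
    base_wave <- rnorm(4)
    Y <- matrix(rnorm(32), 8, 4) +
      matrix(rnorm(8), 8, 1) %*% t(base_wave)   # induce non-sphericity
    an <- rm_anova(Y)
    p_uncorr <- pf(an$f_stat, an$df_num_uncorrected,
                   an$df_den_uncorrected, lower.tail = FALSE)
    expect_gte(an$p_value, p_uncorr - 1e-12)
    if (an$correction_applied) expect_false(an$sphericity_ok)
    expect_gte(an$epsilon, 1 / 3); expect_lte(an$epsilon, 1)
  }
})

test_that("Pearson correlation matches the textbook formula", {
  x <- c(2, 4, 5, 7, 9, 10, 12, 13, 15, 18)
  y <- c(1, 3, 7, 6, 8, 12, 11, 14, 13, 20)
  mine <- pearson_corr(x, y)
  ora <- oracle_pearson(x, y)
  expect_equal(mine$r, ora$r, tolerance = 1e-12)
  expect_equal(mine$p_value, ora$p, tolerance = 1e-12)
  expect_equal(mine$n, 10L)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_corr(x, rep(1, 10)),
               class = "octalens_degenerate_error")
  expect_error(pearson_corr(1:2, 1:2), class = "octalens_parameter_error")
})

test_that("correlation is invariant to affine rescaling", {
  set.seed(18)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  r0 <- pearson_corr(x, y)$r
  expect_equal(pearson_corr(10 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -2 * y)$r, -r0, tolerance = 1e-12)
})

test_that("change tables are keyed by eye and exact", {
  co <- generate_cohort(cohort_sim_params(n_eyes = 12, seed = 5))
  d0 <- delta_metrics(co, "t0", "t0")
  expect_true(all(abs(as.matrix(d0[-1])) < 1e-12))
  d <- delta_metrics(co, "t0", "t3")
  expect_equal(d$vad_svp, co$vad_svp_t3 - co$vad_svp_t0)
  perm <- co[sample(nrow(co)), ]
  class(perm) <- class(co)
  dp <- delta_metrics(perm, "t0", "t3")
  expect_equal(dp$vad_svp[match(d$eye, dp$eye)], d$vad_svp)
  expect_error(delta_metrics(co, "t0", "t9"),
               class = "octalens_parameter_error")
})

test_that("the correlation screen mirrors the study table layout", {
  co <- generate_cohort(cohort_sim_params(n_eyes = 60, seed = 7,
                                          target_correlation = 0.6))
  scr <- correlation_screen(co)
  expect_setequal(unique(scr$predictor),
                  c("lens_opacity", "nuclear_opacity", "cde", "iop_change",
                    "phaco_time", "fluid"))
  expect_equal(nrow(scr), 27 * 6)           # 9 metrics x 3 plexuses x 6
  expect_true(all(scr$n == 60))
  # a deterministic linear dependence shows up as r = 1
  co$cde <- co$vad_svp_t3 - co$vad_svp_t0
  scr2 <- correlation_screen(co)
  cell <- subset(scr2, metric == "vad" & plexus == "SVP" & predictor == "cde")
  expect_equal(cell$r, 1, tolerance = 1e-12)
})

test_that("timepoint summaries carry means, F and p per series", {
  co <- generate_cohort(cohort_sim_params(n_eyes = 25, seed = 9))
  ts <- timepoint_summary(co)
  expect_equal(nrow(ts), 27)
  expect_true(all(c("t0_mean", "t3_sd", "f_stat", "p_value") %in% names(ts)))
  i <- which(ts$metric == "vad" & ts$plexus == "SVP")
  expect_equal(ts$t0_mean[i], mean(co$vad_svp_t0))
})
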