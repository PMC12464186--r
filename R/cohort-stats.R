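# Longitudinal cohort statistics: one-way within-subject (repeated
# measures) ANOVA with Mauchly sphericity assessment and Greenhouse-Geisser
# correction, Pearson correlation, per-eye change tables and the
# correlation screen of perfusion changes against functional predictors.

#' Repeated-measures ANOVA (one within-subject factor)
#'
#' Classical complete-case decomposition of a subjects x timepoints matrix:
#' \eqn{SS_{time}} with \eqn{k - 1} df, error \eqn{SS_{subj \times time}}
#' with \eqn{(n-1)(k-1)} df, and \eqn{F = MS_{time}/MS_{error}}. For
#' \eqn{k \ge 3} timepoints Mauchly's test assesses sphericity of the
#' within-subject covariance; if sphericity is rejected at `alpha` the
#' degrees of freedom are scaled by the Greenhouse-Geisser epsilon before
#' the p-value is taken from the F distribution.
#'
#' @param data numeric matrix, rows = subjects, columns = timepoints (no
#'   missing cells).
#' @param alpha significance level of the sphericity decision (0.05).
#' @return an object of class `rm_anova_result`: `f_stat`, `df_num`,
#'   `df_den` (epsilon-scaled when corrected), `p_value`, `epsilon`,
#'   `sphericity` (a `sphericity_result` or `NULL` for k = 2),
#'   `sphericity_ok`, `correction_applied`, plus the uncorrected dfs.
#' @export
rm_anova <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  if (anyNA(data))
    stop_octalens("missing cells: complete-case design required",
                  "octalens_missing_error")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2)
    stop_octalens("need >= 2 subjects and >= 2 timepoints",
                  "octalens_parameter_error")
  grand <- mean(data)
  col_m <- colMeans(data)
  row_m <- rowMeans(data)
  ss_time <- n * sum((col_m - grand)^2)
  resid <- sweep(sweep(data, 2, col_m), 1, row_m - grand)
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_time <- ss_time / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ms_time == 0) 0 else Inf
  } else ms_time / ms_err
  sph <- NULL; eps <- 1; sph_ok <- TRUE
  if (k >= 3) {
    # a singular contrast covariance (e.g. integer metrics constant across
    # timepoints, or n <= k - 1) leaves sphericity unassessable: fall back
    # to the uncorrected test
    sph <- tryCatch(mauchly_test(data), octalens_error = function(e) NULL)
    if (!is.null(sph)) {
      eps <- gg_epsilon(data)
      sph_ok <- is.na(sph$p_value) || sph$p_value > alpha
    }
  }
  correct <- !sph_ok
  adf1 <- if (correct) eps * df1 else df1
  adf2 <- if (correct) eps * df2 else df2
  p <- if (is.infinite(f)) 0 else stats::pf(f, adf1, adf2, lower.tail = FALSE)
  structure(list(f_stat = f, df_num = adf1, df_den = adf2,
                 df_num_uncorrected = df1, df_den_uncorrected = df2,
                 p_value = p, epsilon = eps,
                 sphericity = sph, sphericity_ok = sph_ok,
                 correction_applied = correct,
                 ss_time = ss_time, ss_error = ss_err,
                 n_subjects = n, n_timepoints = k),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%.3g, %.3g) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f_stat, x$p_value))
  if (!is.null(x$sphericity))
    cat(sprintf("  Mauchly W = %.4g (p = %.4g); GG epsilon = %.4g%s\n",
                x$sphericity$w_stat, x$sphericity$p_value, x$epsilon,
                if (x$correction_applied) " [correction applied]" else ""))
  invisible(x)
}

# orthonormal contrast matrix (k x (k-1)), Helmert-based
#' @noRd
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of the orthonormal within-subject contrasts
#' is proportional to the identity. `W` is the ratio of the geometric to
#' the arithmetic mean (raised to `k - 1`) of the contrast-covariance
#' eigenvalues; the chi-square approximation uses the standard correction
#' factor with `k(k-1)/2 - 1` degrees of freedom.
#'
#' @param data subjects x timepoints matrix, `k >= 3`, `n > k - 1`.
#' @return an object of class `sphericity_result`: `w_stat`, `chi2_stat`,
#'   `df`, `p_value`. For `k = 2` sphericity holds trivially: `w_stat = 1`,
#'   `p_value = NA`, `trivial = TRUE`.
#' @export
mauchly_test <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (k == 2)
    return(structure(list(w_stat = 1, chi2_stat = 0, df = 0,
                          p_value = NA_real_, trivial = TRUE),
                     class = "sphericity_result"))
  if (k < 2 || n <= k - 1)
    stop_octalens("need k >= 3 timepoints and n > k - 1 subjects",
                  "octalens_parameter_error")
  Cm <- orthonormal_contrasts(k)
  Y <- data %*% Cm
  S <- stats::cov(Y)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop_octalens("degenerate contrast covariance", "octalens_degenerate_error")
  p <- k - 1
  W <- prod(ev) / mean(ev)^p
  d <- n - 1
  f <- (2 * p^2 + p + 2) / (6 * p * d)
  chi2 <- -(1 - f) * d * log(W)
  df <- p * (p + 1) / 2 - 1
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(w_stat = W, chi2_stat = chi2, df = df, p_value = pval,
                 trivial = FALSE),
            class = "sphericity_result")
}

#' @export
print.sphericity_result <- function(x, ...) {
  if (isTRUE(x$trivial))
    cat("Sphericity holds trivially (k = 2)\n")
  else
    cat(sprintf("Mauchly W = %.4g, chi2(%d) = %.4g, p = %.4g\n",
                x$w_stat, x$df, x$chi2_stat, x$p_value))
  invisible(x)
}

#' Greenhouse-Geisser epsilon
#'
#' \eqn{\epsilon = (\sum \lambda)^2 / ((k-1) \sum \lambda^2)} over the
#' eigenvalues of the orthonormal-contrast covariance, clamped to
#' `[1/(k-1), 1]`.
#'
#' @param data subjects x timepoints matrix, `k >= 3`.
#' @return scalar epsilon.
#' @export
gg_epsilon <- function(data) {
  data <- as.matrix(data)
  k <- ncol(data)
  if (k < 3)
    stop_octalens("epsilon needs k >= 3 timepoints",
                  "octalens_parameter_error")
  Cm <- orthonormal_contrasts(k)
  S <- stats::cov(data %*% Cm)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev == 0))
    stop_octalens("degenerate contrast covariance", "octalens_degenerate_error")
  eps <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  min(1, max(1 / (k - 1), eps))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, both non-constant.
#' @return an object of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop_octalens("need at least 3 complete pairs", "octalens_parameter_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_octalens("correlation undefined for constant input",
                  "octalens_degenerate_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g (n = %d)\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Per-eye change table between two timepoints
#'
#' `change = value(to_tp) - value(from_tp)` for every metric x plexus
#' series; the IOP change is computed identically. Rows stay keyed by eye
#' id, so row order is irrelevant.
#'
#' @param cohort a `cohort_table` (see [generate_cohort()]).
#' @param from_tp,to_tp timepoint labels among `"t0".."t3"` (case
#'   insensitive).
#' @return data frame with `eye`, one `<metric>_<plexus>` column per
#'   series, and `iop`.
#' @export
delta_metrics <- function(cohort, from_tp = "t0", to_tp = "t3") {
  tps <- c("t0", "t1", "t2", "t3")
  from_tp <- tolower(from_tp); to_tp <- tolower(to_tp)
  if (!from_tp %in% tps || !to_tp %in% tps)
    stop_octalens("unknown timepoint label", "octalens_parameter_error")
  out <- data.frame(eye = cohort$eye)
  for (s in cohort_series(cohort))
    out[[s]] <- cohort[[paste0(s, "_", to_tp)]] -
      cohort[[paste0(s, "_", from_tp)]]
  out$iop <- cohort[[paste0("iop_", to_tp)]] -
    cohort[[paste0("iop_", from_tp)]]
  out
}

#' Correlation screen of metric changes against functional predictors
#'
#' Pearson correlation between the per-eye change of every metric x plexus
#' series (between the configured timepoints, default T3 - T0) and each
#' predictor: lens opacity, nuclear opacity, CDE, IOP change, phaco time
#' and fluid volume. Cells with fewer than 3 complete pairs are marked
#' unavailable. Raw p-values carry the significance flag at `alpha`; a
#' Holm-adjusted column is reported alongside for transparency but does not
#' drive the flag.
#'
#' @param cohort a `cohort_table`.
#' @param from_tp,to_tp timepoints defining the change (default T0 to T3).
#' @param predictors character vector of predictor columns; `"iop_change"`
#'   refers to the IOP change between the same timepoints.
#' @param alpha significance level for the flag.
#' @return data frame of class `correlation_screen`: `metric`, `plexus`,
#'   `predictor`, `r`, `p_value`, `n`, `significant`, `p_holm`,
#'   `available`.
#' @export
correlation_screen <- function(cohort, from_tp = "t0", to_tp = "t3",
                               predictors = c("lens_opacity",
                                              "nuclear_opacity", "cde",
                                              "iop_change", "phaco_time",
                                              "fluid"),
                               alpha = 0.05) {
  d <- delta_metrics(cohort, from_tp, to_tp)
  rows <- list()
  for (s in cohort_series(cohort)) {
    parts <- strsplit(s, "_")[[1]]
    for (p in predictors) {
      pv <- if (p == "iop_change") d$iop else cohort[[p]]
      if (is.null(pv))
        stop_octalens(sprintf("predictor '%s' not present in the cohort", p),
                      "octalens_parameter_error")
      res <- tryCatch(pearson_corr(d[[s]], pv),
                      octalens_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = parts[1], plexus = toupper(parts[2]), predictor = p,
        r = if (is.null(res)) NA_real_ else res$r,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        n = if (is.null(res)) sum(!is.na(d[[s]]) & !is.na(pv)) else res$n,
        available = !is.null(res))
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  out$p_holm <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_holm[ok] <- stats::p.adjust(out$p_value[ok], method = "holm")
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' Timepoint summary with repeated-measures ANOVA per series
#'
#' Mean and SD at every timepoint plus the within-subject ANOVA (with
#' sphericity assessment and Greenhouse-Geisser correction where needed)
#' for each metric x plexus series — the longitudinal summary table of a
#' perfusion study.
#'
#' @param cohort a `cohort_table`.
#' @param alpha sphericity decision level.
#' @return data frame with one row per series: means/SDs per timepoint,
#'   `f_stat`, `p_value`, `epsilon`, `correction_applied`.
#' @export
timepoint_summary <- function(cohort, alpha = 0.05) {
  tps <- c("t0", "t1", "t2", "t3")
  rows <- list()
  for (s in cohort_series(cohort)) {
    parts <- strsplit(s, "_")[[1]]
    mat <- as.matrix(cohort[paste0(s, "_", tps)])
    an <- rm_anova(mat, alpha = alpha)
    row <- data.frame(metric = parts[1], plexus = toupper(parts[2]))
    for (tp in tps) {
      row[[paste0(tp, "_mean")]] <- mean(mat[, paste0(s, "_", tp)])
      row[[paste0(tp, "_sd")]] <- stats::sd(mat[, paste0(s, "_", tp)])
    }
    row$f_stat <- an$f_stat
    row$p_value <- an$p_value
    row$epsilon <- an$epsilon
    row$correction_applied <- an$correction_applied
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality diagnostics per series and timepoint
#'
#' Reported as a diagnostic only; nothing downstream is gated on it.
#'
#' @param cohort a `cohort_table`.
#' @return data frame with `series`, `timepoint`, `w`, `p_value`.
#' @export
normality_diagnostics <- function(cohort) {
  tps <- c("t0", "t1", "t2", "t3")
  rows <- list()
  for (s in cohort_series(cohort)) for (tp in tps) {
    v <- cohort[[paste0(s, "_", tp)]]
    sw <- tryCatch(stats::shapiro.test(v), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      series = s, timepoint = tp,
      w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
      p_value = if (is.null(sw)) NA_real_ else sw$p.value)
  }
  do.call(rbind, rows)
}
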