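# Synthetic longitudinal cohorts: per-eye perfusion metrics at four
# timepoints (T0 preoperative, T1/T2/T3 postoperative), intraocular
# pressure, surgical parameters and lens/nuclear opacity, with a
# configurable correlation between nuclear opacity and the metric change.

#' Default cohort profile: metric trajectories per plexus
#'
#' Baseline (T0) means and SDs and the T1-T3 mean trajectory for the nine
#' perfusion metrics in the three plexuses (SVP, ICP, DCP), emulating the
#' magnitude and the jump-then-plateau time course typical of macular
#' perfusion after cataract surgery: a pronounced first-week increase
#' followed by little further change.
#'
#' @return data frame with columns `metric`, `plexus`, `t0_mean`, `t0_sd`,
#'   `t1_mean`, `t2_mean`, `t3_mean`.
#' @export
default_cohort_profile <- function() {
  tab <- rbind(
    c("vad", "SVP", 0.32, 0.04, 0.34, 0.34, 0.35),
    c("vad", "ICP", 0.22, 0.04, 0.24, 0.23, 0.24),
    c("vad", "DCP", 0.20, 0.04, 0.22, 0.22, 0.22),
    c("vdi", "SVP", 3.83, 0.18, 3.78, 3.77, 3.72),
    c("vdi", "ICP", 3.06, 0.09, 3.07, 3.07, 3.06),
    c("vdi", "DCP", 2.64, 0.05, 2.63, 2.64, 2.62),
    c("vpi", "SVP", 0.70, 0.03, 0.70, 0.70, 0.71),
    c("vpi", "ICP", 0.91, 0.01, 0.90, 0.90, 0.90),
    c("vpi", "DCP", 0.95, 0.01, 0.95, 0.95, 0.95),
    c("bvt", "SVP", 1.25, 0.03, 1.26, 1.26, 1.27),
    c("bvt", "ICP", 1.24, 0.02, 1.25, 1.25, 1.25),
    c("bvt", "DCP", 1.25, 0.02, 1.25, 1.25, 1.26),
    c("vci", "SVP", 3151, 476, 3305, 3369, 3474),
    c("vci", "ICP", 3528, 589, 3807, 3797, 3918),
    c("vci", "DCP", 3584, 640, 3968, 3930, 4047),
    c("bp", "SVP", 1142, 345, 1329, 1355, 1408),
    c("bp", "ICP", 628, 173, 734, 714, 752),
    c("bp", "DCP", 728, 220, 900, 861, 913),
    c("tvl", "SVP", 19465, 3127, 20690, 21010, 21592),
    c("tvl", "ICP", 15189, 3147, 16784, 16789, 17447),
    c("tvl", "DCP", 15278, 3305, 17505, 17367, 17989),
    c("avl", "SVP", 14.70, 1.06, 14.77, 14.79, 14.84),
    c("avl", "ICP", 11.97, 0.97, 12.51, 12.60, 12.76),
    c("avl", "DCP", 11.23, 0.89, 11.79, 11.95, 12.03),
    c("ep", "SVP", 1870, 306, 1766, 1755, 1714),
    c("ep", "ICP", 3453, 292, 3422, 3389, 3430),
    c("ep", "DCP", 4034, 382, 4003, 3931, 3976))
  out <- data.frame(metric = tab[, 1], plexus = tab[, 2],
                    t0_mean = as.numeric(tab[, 3]),
                    t0_sd = as.numeric(tab[, 4]),
                    t1_mean = as.numeric(tab[, 5]),
                    t2_mean = as.numeric(tab[, 6]),
                    t3_mean = as.numeric(tab[, 7]))
  out
}

#' Cohort simulation parameters
#'
#' @param n_eyes number of eyes (one per patient); default 46.
#' @param profile metric trajectory table, see [default_cohort_profile()].
#' @param target_correlation population Pearson correlation between nuclear
#'   opacity and the configured metric change (`delta_to` minus T0), in
#'   (-1, 1) inclusive of the exact endpoints only when `change_sd > 0`.
#' @param change_sd_frac stochastic scale of the per-eye metric change, as
#'   a fraction of the baseline SD (the bivariate-normal scale of the
#'   change; 0 makes every eye's change identical and the correlation
#'   undefined).
#' @param noise_sd_frac measurement noise added to the intermediate
#'   timepoints (T1, T2 when `delta_to = "t3"`), as a fraction of baseline
#'   SD; the target-change timepoint receives none so the population
#'   correlation is exact.
#' @param delta_to which follow-up defines the correlated change
#'   (`"t3"` by default).
#' @param opacity_mean,opacity_sd nuclear opacity distribution (PIU).
#' @param lens_opacity_mean,lens_opacity_sd whole-lens opacity (PIU).
#' @param seed integer seed.
#' @return an object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_eyes = 46L,
                              profile = default_cohort_profile(),
                              target_correlation = 0.35,
                              change_sd_frac = 0.5,
                              noise_sd_frac = 0.15,
                              delta_to = "t3",
                              opacity_mean = 36.71, opacity_sd = 13.67,
                              lens_opacity_mean = 43.92, lens_opacity_sd = 6.27,
                              seed = 1L) {
  if (n_eyes < 4)
    stop_octalens("n_eyes must be >= 4", "octalens_parameter_error")
  if (target_correlation < -1 || target_correlation > 1)
    stop_octalens("target_correlation must lie in [-1, 1]",
                  "octalens_parameter_error")
  if (change_sd_frac < 0 || noise_sd_frac < 0)
    stop_octalens("sd fractions must be >= 0", "octalens_parameter_error")
  delta_to <- match.arg(delta_to, c("t1", "t2", "t3"))
  structure(list(n_eyes = as.integer(n_eyes), profile = profile,
                 target_correlation = target_correlation,
                 change_sd_frac = change_sd_frac,
                 noise_sd_frac = noise_sd_frac,
                 delta_to = delta_to,
                 opacity_mean = opacity_mean, opacity_sd = opacity_sd,
                 lens_opacity_mean = lens_opacity_mean,
                 lens_opacity_sd = lens_opacity_sd,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Generate a longitudinal cohort table
#'
#' One row per eye. For every metric x plexus series the per-eye baseline
#' is drawn around the profile's T0 mean (between-eye SD = the profile's
#' T0 SD); the change to the configured follow-up is drawn jointly with the
#' standardized nuclear opacity from a bivariate normal so that their
#' population correlation equals `target_correlation` exactly:
#' `change = jump + change_sd * (r * z_opacity + sqrt(1 - r^2) * z_eye)`.
#' Intermediate timepoints follow the profile's jump-then-plateau shape
#' plus measurement noise. Intraocular pressure declines over follow-up
#' (means 16.08, 15.40, 14.29, 12.96 mmHg); cumulative dissipated energy,
#' phacoemulsification time and fluid volume are drawn from truncated
#' normals of realistic magnitude.
#'
#' If `change_sd_frac = 0` every eye receives the identical mean jump and
#' the opacity-change correlation is undefined by construction; the result
#' is flagged via the attribute `degenerate_change = TRUE`.
#'
#' @param params a [cohort_sim_params()].
#' @return a `cohort_table` data frame: columns `eye`,
#'   `<metric>_<plexus>_<tp>` (all lower case, e.g. `vad_svp_t0`),
#'   `iop_t0..iop_t3`, `cde`, `phaco_time`, `fluid`, `lens_opacity`,
#'   `nuclear_opacity`.
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  pr <- params$profile
  n <- params$n_eyes
  r <- params$target_correlation
  with_seed(params$seed, {
    z_op <- stats::rnorm(n)
    nuclear <- pmax(1, params$opacity_mean + params$opacity_sd * z_op)
    # whole-lens opacity co-varies with nuclear opacity (they share the
    # cataract severity) but is not the correlation target
    lens <- pmax(1, params$lens_opacity_mean + params$lens_opacity_sd *
                   (0.6 * z_op + sqrt(1 - 0.36) * stats::rnorm(n)))
    out <- data.frame(eye = sprintf("eye%03d", seq_len(n)))
    tps <- c("t0", "t1", "t2", "t3")
    to <- params$delta_to
    for (i in seq_len(nrow(pr))) {
      base <- pr$t0_mean[i] + pr$t0_sd[i] * stats::rnorm(n)
      jump <- pr[[paste0(to, "_mean")]][i] - pr$t0_mean[i]
      change_sd <- params$change_sd_frac * pr$t0_sd[i]
      noise_sd <- params$noise_sd_frac * pr$t0_sd[i]
      z_eye <- stats::rnorm(n)
      delta <- jump + change_sd * (r * z_op + sqrt(1 - r^2) * z_eye)
      shape <- function(tp) {
        d_to <- pr[[paste0(to, "_mean")]][i] - pr$t0_mean[i]
        d_tp <- pr[[paste0(tp, "_mean")]][i] - pr$t0_mean[i]
        if (d_to == 0) as.numeric(tp == to) else d_tp / d_to
      }
      key <- paste0(pr$metric[i], "_", tolower(pr$plexus[i]))
      for (tp in tps) {
        val <- if (tp == "t0") base
        else if (tp == to) base + delta
        else base + delta * shape(tp) + noise_sd * stats::rnorm(n)
        out[[paste0(key, "_", tp)]] <- val
      }
    }
    iop_means <- c(16.08, 15.40, 14.29, 12.96)
    iop_base <- stats::rnorm(n, 0, 2.6)
    for (j in seq_along(tps))
      out[[paste0("iop_", tps[j])]] <-
        pmax(5, iop_means[j] + iop_base + stats::rnorm(n, 0, 1.2))
    out$phaco_time <- pmax(0, stats::rnorm(n, 213.35, 117.81))
    out$cde <- ifelse(out$phaco_time == 0, 0,
                      pmax(0, stats::rnorm(n, 2.89, 1.80)))
    out$fluid <- pmax(10, stats::rnorm(n, 41.91, 12.92))
    out$lens_opacity <- lens
    out$nuclear_opacity <- nuclear
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "delta_to") <- to
    attr(out, "degenerate_change") <- params$change_sd_frac == 0
    out
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d eyes, %d columns\n", nrow(x), ncol(x)))
  NextMethod()
}

# metric x plexus series names present in a cohort table
#' @noRd
cohort_series <- function(cohort) {
  cn <- grep("_(svp|icp|dcp)_t0$", names(cohort), value = TRUE)
  sub("_t0$", "", cn)
}
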