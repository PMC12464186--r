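# End-to-end study orchestration: simulate a full synthetic study on disk
# (OCTA images per eye x timepoint x plexus, AS-OCT lens series per eye,
# covariates), then run the complete analysis over such a directory tree:
# quantify every angiogram behind the quality gate, measure lens opacities,
# assemble the longitudinal table and produce the summary and correlation
# tables.

#' Study configuration
#'
#' @param input_dir study root (layout of [simulate_study()]:
#'   `octa/<eye>/<tp>/<plexus>.png`, `asoct/<eye>/scan-NN.png`,
#'   `covariates.csv`).
#' @param output_dir where result CSVs and the log are written.
#' @param quant a [quant_config()].
#' @param opacimetry an [opacimetry_config()].
#' @param delta_from,delta_to timepoints defining the change used by the
#'   correlation screen.
#' @param alpha significance level.
#' @return an object of class `study_config`.
#' @export
study_config <- function(input_dir, output_dir,
                         quant = quant_config(),
                         opacimetry = opacimetry_config(),
                         delta_from = "t0", delta_to = "t3",
                         alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    stop_octalens("alpha must lie in (0, 1)", "octalens_config_error")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 quant = quant, opacimetry = opacimetry,
                 delta_from = delta_from, delta_to = delta_to,
                 alpha = alpha),
            class = "study_config")
}

#' Simulate a complete synthetic study on disk
#'
#' Generates a directory tree in the layout [run_study()] consumes: per eye
#' and timepoint one OCTA en-face image per plexus (trees whose stroke
#' widths and tortuosity increase postoperatively, more so for eyes with
#' denser nuclei), per eye a radial AS-OCT series whose nucleus intensity
#' equals the eye's nuclear opacity, and a covariates CSV (IOP per
#' timepoint, CDE, phaco time, fluid, plus the ground-truth opacities).
#' Ground-truth sidecars (`truth.json`) accompany every OCTA image.
#' Deterministic given `seed`.
#'
#' @param out_dir output directory (created; must not already contain a
#'   study).
#' @param n_eyes number of eyes.
#' @param plexuses plexus labels to render per timepoint.
#' @param octa_size en-face canvas in pixels.
#' @param n_scans lens scans per eye.
#' @param lens_size `c(height, width)` of lens scans.
#' @param noise OCTA noise parameters passed to [render_octa_image()]
#'   (`NULL` for noise-free).
#' @param cohort_params a [cohort_sim_params()] for the covariates and
#'   opacity distribution (its `n_eyes` is overridden).
#' @param seed integer seed.
#' @return the study root, invisibly; a `manifest.json` records the layout.
#' @export
simulate_study <- function(out_dir, n_eyes = 8L,
                           plexuses = c("SVP", "ICP", "DCP"),
                           octa_size = 160L, n_scans = 15L,
                           lens_size = c(140, 200),
                           noise = list(speckle_sd = 0.12, additive_sd = 4),
                           cohort_params = cohort_sim_params(),
                           seed = 1L) {
  tps <- c("t0", "t1", "t2", "t3")
  cohort_params$n_eyes <- as.integer(n_eyes)
  cohort_params$seed <- as.integer(seed)
  truth_cohort <- generate_cohort(cohort_params)
  dir.create(file.path(out_dir, "octa"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "asoct"), recursive = TRUE, showWarnings = FALSE)
  z_op <- if (n_eyes > 1 &&
              stats::sd(truth_cohort$nuclear_opacity) > 0)
    as.numeric(scale(truth_cohort$nuclear_opacity)) else rep(0, n_eyes)
  jump_shape <- c(t0 = 0, t1 = 0.85, t2 = 0.9, t3 = 1)
  img_seed <- function(...) {
    as.integer((sum(c(...) * c(7919, 104729, 1299709, 15485863)) +
                  as.numeric(seed)) %% 2147483647)
  }
  for (i in seq_len(n_eyes)) {
    eye <- truth_cohort$eye[i]
    for (j in seq_along(tps)) {
      d <- file.path(out_dir, "octa", eye, tps[j])
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_along(plexuses)) {
        # postoperative dilation and tortuosity, stronger for denser nuclei
        wid <- 2.6 + jump_shape[j] * (0.5 + 0.25 * z_op[i])
        amp <- 1.2 + jump_shape[j] * (0.25 + 0.12 * z_op[i])
        tr <- generate_vascular_tree(
          depth = 3, density = 2, tortuosity_amplitude = max(0, amp),
          base_width = max(2, wid), canvas = octa_size,
          trunk_length = octa_size * 0.19,
          seed = img_seed(i, j, k, 1))
        img <- render_octa_image(tr, noise = noise,
                                 seed = img_seed(i, j, k, 2),
                                 quality_index = 55,
                                 plexus_label = plexuses[k])
        path <- file.path(d, paste0(plexuses[k], ".png"))
        write_enface_png(img, path)
        jsonlite::write_json(
          list(bp = tr$true_counts$bp, ep = tr$true_counts$ep,
               centerline_length = tr$true_centerline_length),
          file.path(d, paste0(plexuses[k], ".truth.json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
    scene <- default_lens_scene(height = lens_size[1], width = lens_size[2],
                                cortex_intensity =
                                  0.9 * truth_cohort$lens_opacity[i],
                                nucleus_intensity =
                                  min(250, truth_cohort$nuclear_opacity[i] * 1.6),
                                speckle_sd = 0.18)
    scans <- generate_lens_series(scene, n_scans = n_scans,
                                  height = lens_size[1], width = lens_size[2],
                                  seed = img_seed(i, 0, 0, 3))
    d <- file.path(out_dir, "asoct", eye)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_along(scans))
      write_enface_png(scans[[s]], file.path(d, sprintf("scan-%02d.png", s)))
  }
  cov_cols <- c("eye", paste0("iop_", tps), "cde", "phaco_time", "fluid",
                "lens_opacity", "nuclear_opacity")
  utils::write.csv(as.data.frame(truth_cohort)[cov_cols],
                   file.path(out_dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_eyes = n_eyes, timepoints = tps, plexuses = plexuses,
         n_scans = n_scans, seed = seed),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Run the full analysis over a study directory
#'
#' Quantifies every OCTA image (skipping, with a logged reason, images that
#' fail the quality gate or are missing — the affected eye is excluded from
#' that plexus' longitudinal analysis), measures lens and nuclear opacity
#' from each eye's AS-OCT series, merges everything with the covariates
#' into a longitudinal table, and writes: `metrics.csv` (one row per image),
#' `opacity.csv` (per eye), `cohort.csv` (merged wide table),
#' `timepoint_summary.csv` (means/SD and RM-ANOVA per series),
#' `correlation_screen.csv`, and `log.txt`. Rerunning with identical inputs
#' and configuration reproduces identical outputs.
#'
#' @param config a [study_config()].
#' @return list with the output paths and the in-memory tables (class
#'   `study_result`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  tps <- c("t0", "t1", "t2", "t3")
  octa_root <- file.path(config$input_dir, "octa")
  eyes <- sort(list.dirs(octa_root, recursive = FALSE, full.names = FALSE))
  if (!length(eyes))
    stop_octalens("no eyes found under octa/", "octalens_parameter_error")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  metric_rows <- list()
  for (eye in eyes) for (tp in tps) {
    d <- file.path(octa_root, eye, tp)
    for (path in sort(list.files(d, pattern = "\\.png$", full.names = TRUE))) {
      plexus <- sub("\\.png$", "", basename(path))
      img <- read_enface_png(path)
      pm <- tryCatch(quantify(img, config$quant),
                     octalens_error = function(e) e)
      if (inherits(pm, "error")) {
        note("EXCLUDE %s %s %s: %s", eye, tp, plexus, conditionMessage(pm))
        next
      }
      row <- cbind(data.frame(eye = eye, timepoint = tp, plexus = plexus),
                   as.data.frame(pm),
                   data.frame(threshold = attr(pm, "threshold"),
                              excluded_loops = attr(pm, "excluded_loops")))
      metric_rows[[length(metric_rows) + 1L]] <- row
    }
  }
  metrics <- do.call(rbind, metric_rows)

  opac_rows <- list()
  for (eye in eyes) {
    d <- file.path(config$input_dir, "asoct", eye)
    paths <- sort(list.files(d, pattern = "\\.png$", full.names = TRUE))
    if (!length(paths)) { note("NO-LENS %s", eye); next }
    cfg <- config$opacimetry
    cfg$n_scans <- length(paths)
    res <- tryCatch(
      lens_opacity_from_series(lapply(paths, read_asoct_png), cfg),
      octalens_error = function(e) e)
    if (inherits(res, "error")) {
      note("LENS-FAIL %s: %s", eye, conditionMessage(res))
      next
    }
    opac_rows[[length(opac_rows) + 1L]] <-
      data.frame(eye = eye, lens_opacity_measured = res$lens_opacity,
                 nuclear_opacity_measured = res$nuclear_opacity)
  }
  opacity <- do.call(rbind, opac_rows)

  # wide longitudinal table from the per-image metrics
  wide <- data.frame(eye = eyes)
  mnames <- c("vad", "vdi", "vpi", "bvt", "vci", "bp", "ep", "tvl", "avl")
  if (!is.null(metrics)) for (pl in unique(metrics$plexus)) for (tp in tps) {
    sel <- metrics$plexus == pl & metrics$timepoint == tp
    for (mn in mnames) {
      col <- paste0(mn, "_", tolower(pl), "_", tp)
      wide[[col]] <- metrics[[mn]][sel][match(wide$eye, metrics$eye[sel])]
    }
  }
  cov_path <- file.path(config$input_dir, "covariates.csv")
  if (file.exists(cov_path)) {
    cov <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
    wide <- merge(wide, cov, by = "eye", sort = TRUE)
  }
  if (!is.null(opacity)) wide <- merge(wide, opacity, by = "eye", all.x = TRUE)
  class(wide) <- c("cohort_table", "data.frame")

  # per-series longitudinal summary on complete eyes only
  summ_rows <- list(); scr <- NULL
  series <- cohort_series(wide)
  for (s in series) {
    mat <- as.matrix(wide[paste0(s, "_", tps)])
    ok <- stats::complete.cases(mat)
    if (sum(!ok))
      note("RM-ANOVA %s: %d eye(s) excluded for missing images", s, sum(!ok))
    if (sum(ok) < 2) { note("RM-ANOVA %s: too few complete eyes", s); next }
    an <- rm_anova(mat[ok, , drop = FALSE], alpha = config$alpha)
    parts <- strsplit(s, "_")[[1]]
    mm <- colMeans(mat[ok, , drop = FALSE])
    names(mm) <- paste0(tps, "_mean")
    summ_rows[[length(summ_rows) + 1L]] <- data.frame(
      metric = parts[1], plexus = toupper(parts[2]), n = sum(ok),
      t(mm),
      f_stat = an$f_stat, p_value = an$p_value, epsilon = an$epsilon,
      correction_applied = an$correction_applied)
  }
  summary_tab <- if (length(summ_rows)) do.call(rbind, summ_rows) else NULL
  complete <- wide[stats::complete.cases(
    wide[unlist(lapply(series, function(s) paste0(s, "_", tps)))]), ]
  if (nrow(complete) >= 4 && all(c("lens_opacity", "nuclear_opacity",
                                   "cde") %in% names(complete)))
    scr <- correlation_screen(complete, config$delta_from, config$delta_to,
                              alpha = config$alpha)

  paths <- list(metrics = file.path(config$output_dir, "metrics.csv"),
                opacity = file.path(config$output_dir, "opacity.csv"),
                cohort = file.path(config$output_dir, "cohort.csv"),
                summary = file.path(config$output_dir, "timepoint_summary.csv"),
                screen = file.path(config$output_dir, "correlation_screen.csv"),
                log = file.path(config$output_dir, "log.txt"))
  if (!is.null(metrics))
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  if (!is.null(opacity))
    utils::write.csv(opacity, paths$opacity, row.names = FALSE)
  utils::write.csv(as.data.frame(wide), paths$cohort, row.names = FALSE)
  if (!is.null(summary_tab))
    utils::write.csv(summary_tab, paths$summary, row.names = FALSE)
  if (!is.null(scr))
    utils::write.csv(as.data.frame(scr), paths$screen, row.names = FALSE)
  writeLines(log_lines, paths$log)
  structure(list(paths = paths, metrics = metrics, opacity = opacity,
                 cohort = wide, summary = summary_tab, screen = scr,
                 log = log_lines),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d eyes, %d images quantified, %d log lines\n",
              nrow(x$cohort), if (is.null(x$metrics)) 0L else nrow(x$metrics),
              length(x$log)))
  invisible(x)
}
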