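# File interfaces: 8-bit grayscale PNG images with JSON sidecars for
# acquisition metadata, and CSV cohort tables.

#' Write an image as 8-bit grayscale PNG with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the quality index, plexus label and
#' physical scale so a later [read_enface_png()] restores the full object.
#'
#' @param image an [en_face_image()] or [asoct_scan()].
#' @param path output path ending in `.png`.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(image, path, sidecar = TRUE) {
  px <- as_pixel_matrix(image)
  png::writePNG(px / 255, target = path)
  if (sidecar) {
    meta <- if (inherits(image, "en_face_image"))
      list(type = "enface", quality_index = image$quality_index,
           plexus_label = image$plexus_label,
           mm_per_pixel = image$mm_per_pixel)
    else if (inherits(image, "asoct_scan"))
      list(type = "asoct", scan_index = image$scan_index)
    else list(type = "matrix")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Read an 8-bit grayscale PNG as an en-face image
#'
#' Multichannel PNGs are collapsed to their first channel. If a
#' `<path>.json` sidecar exists, its quality index and plexus label are
#' attached.
#'
#' @param path PNG path.
#' @return an [en_face_image()].
#' @export
read_enface_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  px <- round(a * 255)
  qi <- NULL; plexus <- "unlabeled"; mmpp <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    qi <- meta$quality_index
    plexus <- meta$plexus_label %||% "unlabeled"
    mmpp <- meta$mm_per_pixel
  }
  en_face_image(px, mm_per_pixel = mmpp, quality_index = qi,
                plexus_label = plexus)
}

#' Read an 8-bit grayscale PNG as an AS-OCT scan
#'
#' @param path PNG path.
#' @param scan_index radial position; if `NULL`, taken from the sidecar or
#'   from a trailing number in the file name.
#' @return an [asoct_scan()].
#' @export
read_asoct_png <- function(path, scan_index = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  if (is.null(scan_index)) {
    sc <- paste0(path, ".json")
    if (file.exists(sc)) scan_index <- jsonlite::read_json(sc)$scan_index
    if (is.null(scan_index)) {
      m <- regmatches(basename(path), regexpr("[0-9]+", basename(path)))
      scan_index <- if (length(m)) as.integer(m) else 1L
    }
  }
  asoct_scan(round(a * 255), scan_index = scan_index)
}

#' Write a cohort table to CSV
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with one row per eye (schema of
#'   [generate_cohort()]).
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"eye" %in% names(out))
    stop_octalens("cohort CSV must contain an 'eye' column",
                  "octalens_parameter_error")
  class(out) <- c("cohort_table", "data.frame")
  out
}
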