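# Shared I/O: frame stacks and label stacks from multipage TIFF or numbered
# PNG directories, JSON/YAML run configuration, ROI JSON, and reports with
# an embedded provenance block.

# read one image file as a numeric matrix (grayscale) in [0, 1]
.read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    abort_domain("unsupported image format: .", ext,
                 " (use PNG or TIFF): ", path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

# list a directory's numbered frames in numeric order
.numbered_files <- function(path) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    abort_domain("no PNG/TIFF frames found in directory: ", path)
  nums <- suppressWarnings(
    as.numeric(gsub("\\D", "", basename(files))))
  if (any(is.na(nums))) files[order(basename(files))]
  else files[order(nums)]
}

# read pages (list of H x W matrices in [0,1]) from a TIFF file or directory
.read_pages <- function(path) {
  if (dir.exists(path)) {
    lapply(.numbered_files(path), .read_image_gray)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(img) {
      if (length(dim(img)) == 3L) {
        if (dim(img)[3] >= 3L)
          0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
        else img[, , 1]
      } else img
    })
  }
}

#' Read a video frame stack
#'
#' Accepts a multipage TIFF or a directory of numbered PNG/TIFF frames
#' (ordered by the number embedded in the filename). RGB frames are
#' converted to ITU-R 601 luminance. The frame rate is never inferred from
#' filenames; it must be supplied.
#'
#' @param path TIFF file or frame directory.
#' @param fps frame rate in frames/second (required).
#' @return a [frame_stack()] with intensities in `[0, 1]`.
#' @export
read_frame_stack <- function(path, fps) {
  if (missing(fps) || is.null(fps))
    abort_domain("fps is required (key: fps); it is never inferred")
  pages <- .read_pages(path)
  dims <- vapply(pages, dim, c(1L, 1L))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    abort_domain("mixed frame shapes in ", path)
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  frame_stack(frames, fps)
}

#' Read a labeled section stack
#'
#' Reads integer label images (stored as 8-bit gray, label = pixel value)
#' from a multipage TIFF or a numbered image directory, and validates the
#' labels against the background/kidney/blood-cell coding.
#'
#' @param path TIFF file or image directory.
#' @param meta list with `pixel_size_um` and `section_thickness_um`, or the
#'   path of a JSON sidecar containing them.
#' @return a [section_stack()].
#' @export
read_label_stack <- function(path, meta) {
  if (missing(meta) || is.null(meta))
    abort_domain("meta with pixel_size_um and section_thickness_um ",
                 "is required")
  if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "section_thickness_um"))
    if (is.null(meta[[key]])) abort_domain("meta is missing key: ", key)
  pages <- .read_pages(path)
  labs <- lapply(pages, function(m) {
    v <- m * 255
    if (max(abs(v - round(v))) > 1e-6)
      abort_domain("non-integer pixel values in label image")
    matrix(as.integer(round(v)), nrow(m), ncol(m))
  })
  arr <- array(unlist(labs), c(dim(labs[[1]]), length(labs)))
  section_stack(arr, meta$pixel_size_um, meta$section_thickness_um)
}

#' Read ROIs from JSON
#'
#' The JSON carries 0-based, half-open rectangles:
#' `{"heart_rois": [[row0, col0, row1, col1], x3], "reference_roi": [...]}`.
#'
#' @param path JSON file.
#' @return a [roi_set()].
#' @export
read_rois_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$heart_rois) || is.null(js$reference_roi))
    abort_domain("ROI JSON needs keys heart_rois and reference_roi")
  mk <- function(v) roi(v[1], v[2], v[3], v[4])
  hr <- if (is.matrix(js$heart_rois))
    lapply(seq_len(nrow(js$heart_rois)), function(i) mk(js$heart_rois[i, ]))
  else lapply(js$heart_rois, mk)
  roi_set(hr, mk(unlist(js$reference_roi)))
}

#' Read a run configuration (JSON or YAML)
#'
#' Unit-bearing keys are spelled out in the file (e.g. `fps`,
#' `energy_mev_per_u`, `pixel_size_um`); unknown top-level blocks are
#' rejected to catch typos.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = , yml = yaml::read_yaml(path),
    abort_domain("config must be .json or .yaml, got .", ext))
  known <- c("dosimetry", "heartrate", "volumetry", "stats", "simulate",
             "output_dir", "log_level", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    abort_domain("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Write an analysis report with provenance
#'
#' JSON reports embed a provenance block (package version, seed, optional
#' config echo) and keep stable key order and full float precision, so a
#' rerun with the same inputs is byte-identical. CSV output is available
#' for tabular results.
#'
#' @param results named list (JSON) or data frame (CSV).
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @param seed optional seed to record.
#' @param config optional configuration list to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = "json",
                         seed = NULL, config = NULL) {
  if (!format %in% c("json", "csv"))
    abort_domain("unknown report format: ", format, " (use json or csv)")
  if (format == "csv") {
    if (!is.data.frame(results))
      abort_domain("csv format requires a data frame")
    utils::write.csv(results, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- list(
    provenance = list(
      package = "fishbeam",
      version = as.character(utils::packageVersion("fishbeam")),
      seed = seed, config = config),
    results = results)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write report to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}
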