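#' Analyse one grain scan
#'
#' Runs the full pipeline on one image: segmentation, size measurement,
#' whole-grain colour, optional crease detection and optional CIELAB
#' conversion. This is the in-memory core of [grain_scan_batch()].
#'
#' @param image a [raster_image()] or a file path.
#' @param config a [pipeline_config()].
#' @return object of class `grain_scan_result`: list with `results`
#'   (tibble, one row per grain), `labels`, `crease` (or `NULL`),
#'   `image`, `config`.
#' @export
grain_scan <- function(image, config = pipeline_config()) {
  if (is.character(image)) image <- read_image(image)
  stopifnot(inherits(image, "raster_image"), inherits(config, "pipeline_config"))
  if (is.na(image$dpi)) {
    if (is.null(config$dpi) || is.na(config$dpi))
      stop("image has no dpi metadata and no dpi is configured")
    image$dpi <- config$dpi
  }
  labels <- segment(image, config)
  sizes <- measure_size(labels, image$dpi)
  creases <- if (config$crease && max(labels) > 0L)
    detect_creases(image, labels, sizes, config) else NULL
  colours <- partition_colour(image, labels, creases, config$calibration)
  results <- dplyr::left_join(sizes, colours, by = "grain_id")
  if (is.null(creases)) results$crease_detected <- NA
  structure(list(results = tibble::as_tibble(results), labels = labels,
                 crease = creases, image = image, config = config),
            class = "grain_scan_result")
}

#' @export
print.grain_scan_result <- function(x, ...) {
  cat(sprintf("<grain_scan_result: %d grains>\n", max(x$labels)))
  print(x$results)
  invisible(x)
}

#' @rdname grain_scan
#' @param x,object a `grain_scan_result`.
#' @param ... unused.
#' @export
tidy.grain_scan_result <- function(x, ...) x$results

#' @rdname grain_scan
#' @export
glance.grain_scan_result <- function(x, ...) {
  tibble::tibble(
    n_grains = max(x$labels),
    mean_area_mm2 = mean(x$results$area_mm2),
    mean_majellipse_mm = mean(x$results$majellipse_mm),
    mean_minellipse_mm = mean(x$results$minellipse_mm),
    n_crease = if (all(is.na(x$results$crease_detected))) NA_integer_
    else sum(x$results$crease_detected, na.rm = TRUE))
}

#' @rdname grain_scan
#' @export
autoplot.grain_scan_result <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$area_mm2)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = expression("grain area " * (mm^2)), y = "grains",
                  title = sprintf("%d grains, mean area %.2f mm²",
                                  nrow(object$results),
                                  mean(object$results$area_mm2))) +
    ggplot2::theme_minimal()
}

#' Batch-process scan images
#'
#' Processes each input image with [grain_scan()] and writes, per image,
#' the results CSV (into a `Results` sub-directory), the 16-bit grain
#' label TIFF, the grain overlay JPEG and - when crease detection is on -
#' the crease label TIFF and crease overlay JPEG. One image's failure does
#' not abort the batch.
#'
#' @param inputs character vector of image paths.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return a run manifest tibble: `input`, `status` (`"ok"`/`"failed"`),
#'   `n_grains`, `reason`, `csv`, `elapsed_s`.
#' @export
grain_scan_batch <- function(inputs, config = pipeline_config(), out_dir = ".") {
  if (length(inputs) == 0) stop("no input images given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(inputs, function(path) {
    t0 <- proc.time()[["elapsed"]]
    stem_name <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      scan <- grain_scan(path, config)
      stem <- file.path(out_dir, stem_name)
      write_label_image(scan$labels, stem, "grainLbl")
      write_overlay(scan$image, scan$labels, stem, "grainOvr")
      if (!is.null(scan$crease)) {
        write_label_image(scan$crease$crease_labels, stem, "creaseLbl")
        write_overlay(scan$image, scan$crease$crease_labels, stem, "creaseOvr")
      }
      csv <- write_results_csv(scan$results, out_dir, stem_name)
      tibble::tibble(input = path, status = "ok",
                     n_grains = max(scan$labels), reason = NA_character_,
                     csv = csv)
    }, error = function(e) {
      tibble::tibble(input = path, status = "failed", n_grains = NA_integer_,
                     reason = conditionMessage(e), csv = NA_character_)
    })
    res$elapsed_s <- proc.time()[["elapsed"]] - t0
    message(sprintf("[seedscan] %s: %s%s (%.1fs)", stem_name, res$status,
                    ifelse(res$status == "ok",
                           sprintf(", %d grains", res$n_grains), ""),
                    res$elapsed_s))
    res
  })
  dplyr::bind_rows(rows)
}

#' Calibrate a scanner from a colour-checker scan
#'
#' Locates the card, measures the swatches, fits the RGB to CIELAB
#' transform and writes the `*RGB2Labmat.tif` / `*RGB2Laboff.tif` pair.
#'
#' @param card path to the card scan or a [raster_image()].
#' @param reference reference table (see [colorchecker_reference()]).
#' @param stem output stem for the transform files.
#' @param layout swatch grid c(rows, cols).
#' @return the fitted [colour_transform][fit_transform], invisibly; the
#'   file paths are in attribute `paths`.
#' @export
colour_calibration <- function(card, reference = colorchecker_reference(),
                               stem = "calibration", layout = c(4L, 6L)) {
  if (is.character(card)) card <- read_image(card)
  swatches <- extract_swatches(card, layout = layout, reference = reference)
  transform <- fit_transform(swatches)
  paths <- save_transform(transform, stem)
  attr(transform, "paths") <- paths
  invisible(transform)
}

#' Write / read a pipeline configuration file
#'
#' Round-trippable YAML serialisation of a [pipeline_config()] (the
#' calibration transform is referenced by its file stem).
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @param calibration_stem optional stem of a saved transform to record.
#' @return `path`, invisibly (write); a [pipeline_config()] (read).
#' @export
write_config <- function(config, path, calibration_stem = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- config[setdiff(names(config), "calibration")]
  x$calibration_stem <- calibration_stem
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  calib <- if (!is.null(x$calibration_stem)) load_transform(x$calibration_stem)
  x$calibration_stem <- NULL
  do.call(pipeline_config, c(x, list(calibration = calib)))
}
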