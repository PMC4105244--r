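#' Write a label image
#'
#' Writes the label map as a 16-bit single-channel TIFF named
#' `<stem>.<suffix>.tif`, where the suffix is `grainLbl` for grain labels or
#' `creaseLbl` for crease labels. The round trip through
#' [read_label_image()] is lossless for up to 65535 objects.
#'
#' @param labels integer label matrix (0 = background).
#' @param stem output path stem (directory + sample name, no extension).
#' @param suffix `"grainLbl"` or `"creaseLbl"`.
#' @return the written path, invisibly.
#' @export
write_label_image <- function(labels, stem, suffix = c("grainLbl", "creaseLbl")) {
  suffix <- match.arg(suffix)
  if (max(labels) > 65535L) stop("more than 65535 objects cannot be stored in 16 bits")
  path <- paste0(stem, ".", suffix, ".tif")
  m <- as_num_matrix(labels) / 65535
  ok <- tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none",
                        reduce = FALSE)
  if (!isTRUE(ok == 1L)) stop("failed to write ", path)
  invisible(path)
}

#' Read back a label image written by [write_label_image()]
#'
#' @param path path to a 16-bit label TIFF.
#' @return integer label matrix with attribute `n_objects`.
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  attr(m, "n_objects") <- length(unique(m[m > 0L]))
  m
}

#' Write a coloured label overlay
#'
#' Renders each label in a distinct colour from a fixed 12-colour
#' qualitative palette (cycled by label id), alpha-blended over the input
#' image, and writes a JPEG named `<stem>.<suffix>.jpg`. The input image is
#' not modified. Output bytes are deterministic for identical inputs.
#'
#' @param image a [raster_image()].
#' @param labels integer label matrix of matching size.
#' @param stem output path stem.
#' @param suffix `"grainOvr"` or `"creaseOvr"`.
#' @param alpha blend weight of the label colour (0..1).
#' @return the written path, invisibly.
#' @export
write_overlay <- function(image, labels, stem,
                          suffix = c("grainOvr", "creaseOvr"), alpha = 0.5) {
  suffix <- match.arg(suffix)
  stopifnot(inherits(image, "raster_image"))
  if (!all(dim(labels) == dim(image$pixels)[1:2]))
    stop("label map and image shapes differ")
  path <- paste0(stem, ".", suffix, ".jpg")
  maxval <- 2^image$bit_depth - 1
  img <- array(as.numeric(image$pixels), dim(image$pixels)) / maxval
  ids <- labels > 0L
  if (any(ids)) {
    pal <- grDevices::col2rgb(overlay_palette()) / 255
    ci <- (labels[ids] - 1L) %% ncol(pal) + 1L
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ids] <- (1 - alpha) * plane[ids] + alpha * pal[ch, ci]
      img[, , ch] <- plane
    }
  }
  jpeg::writeJPEG(img, path, quality = 0.92)
  invisible(path)
}

#' Write the per-grain results CSV
#'
#' Writes results to `<out_dir>/Results/<stem>.csv` with a fixed column
#' order and numeric values serialised to 4 decimal places. Missing
#' colour/crease measurements are left empty.
#'
#' @param table a tibble of grain records (see [grain_scan()]).
#' @param out_dir output directory; a `Results` sub-directory is created.
#' @param stem sample name for the file.
#' @return the written path, invisibly.
#' @export
write_results_csv <- function(table, out_dir, stem) {
  dir.create(file.path(out_dir, "Results"), recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "Results", paste0(stem, ".csv"))
  cols <- results_columns()
  out <- tibble::as_tibble(table)
  for (cn in setdiff(cols, names(out))) out[[cn]] <- NA_real_
  out <- out[cols]
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) ifelse(is.na(x), "", sprintf("%.4f", x))
    else if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
    else as.character(x)
  }
  chr <- dplyr::mutate(out, dplyr::across(dplyr::everything(), fmt))
  readr::write_csv(chr, path, na = "")
  invisible(path)
}

results_columns <- function() {
  c("grain_id", "area_mm2", "perimeter_mm", "majellipse_mm", "minellipse_mm",
    "mean_R", "mean_G", "mean_B", "L", "a", "b", "crease_detected",
    "L_noncrease", "a_noncrease", "b_noncrease",
    "L_crease", "a_crease", "b_crease")
}
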