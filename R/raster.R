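#' Raster image container
#'
#' A `raster_image` is an H x W x 3 integer array of channel values in the
#' native bit depth of the scan (0..255 or 0..65535), with the scanner
#' resolution in dots per inch attached. All pipeline stages consume and
#' produce this unit; values are never rescaled on read.
#'
#' @param pixels H x W x 3 (or H x W, promoted to 3 identical channels)
#'   array of non-negative integers.
#' @param dpi scanner resolution in dots per inch, or `NA` if unknown.
#' @param bit_depth 8 or 16.
#' @param source_path origin of the pixels, for provenance.
#' @return object of class `raster_image`.
#' @export
raster_image <- function(pixels, dpi = NA_real_, bit_depth = 8L,
                         source_path = NA_character_) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) stop("zero-area image")
  bit_depth <- as.integer(bit_depth)
  stopifnot(bit_depth %in% c(8L, 16L))
  maxval <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxval)
    stop("channel values outside declared bit depth")
  if (!is.na(dpi) && dpi <= 0) stop("dpi must be positive")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, dpi = as.numeric(dpi),
                 bit_depth = bit_depth, source_path = source_path),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %d x %d, %d-bit, dpi=%s>\n",
              d[1], d[2], x$bit_depth,
              ifelse(is.na(x$dpi), "?", format(x$dpi))))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Read a scan image
#'
#' Reads TIFF, PNG or JPEG into a [raster_image()], keeping native channel
#' values (no rescaling; a 16-bit TIFF keeps values up to 65535). Greyscale
#' files are promoted to three identical channels, an alpha channel is
#' dropped. The resolution is taken from file metadata where present
#' (TIFF/PNG); an explicit `dpi` argument always wins. A missing dpi is
#' allowed at read time but the measurement stages will refuse it.
#'
#' @param path file path.
#' @param dpi optional resolution override in dots per inch.
#' @return a [raster_image()].
#' @export
read_image <- function(path, dpi = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  meta_dpi <- NA_real_
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    res <- attr(px, "x.resolution")
    unit <- attr(px, "resolution.unit")
    if (!is.null(res) && is.numeric(res) && res > 0) {
      meta_dpi <- if (!is.null(unit) && identical(unit, "cm")) res * 2.54 else res
    }
    bits <- attr(px, "bits.per.sample")
    bit_depth <- if (!is.null(bits) && bits == 16) 16L else 8L
    # as.is yields native integers for greyscale but [0,1] reals for RGB
    pixels <- if (is.integer(px)) px else round(px * (2^bit_depth - 1))
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0)
      meta_dpi <- info$dpi[1]
    bit_depth <- if (!is.null(info$bit.depth) && info$bit.depth == 16) 16L else 8L
    pixels <- round(px * (2^bit_depth - 1))
  } else if (ext %in% c("jpg", "jpeg")) {
    px <- jpeg::readJPEG(path)
    bit_depth <- 8L
    pixels <- round(px * 255)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(pixels)) == 2L) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (dim(pixels)[3] > 3L) pixels <- pixels[, , 1:3, drop = FALSE]
  if (dim(pixels)[3] < 3L) {
    pixels <- array(rep(pixels[, , 1L], 3L), c(dim(pixels)[1:2], 3L))
  }
  use_dpi <- if (!is.null(dpi)) as.numeric(dpi) else meta_dpi
  raster_image(pixels, dpi = use_dpi, bit_depth = bit_depth, source_path = path)
}

#' Derive the segmentation grey image
#'
#' The grey image used for segmentation is the mean of the red and green
#' channels; blue is discarded because red and green give the strongest
#' grain/background contrast for cereal seed on a dark backing.
#'
#' @param image a [raster_image()].
#' @return numeric matrix of grey values on the native channel scale.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  (as_num_matrix(image$pixels[, , 1L]) + as_num_matrix(image$pixels[, , 2L])) / 2
}
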