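#' Pipeline configuration
#'
#' Bundles the user-facing parameters of the grain segmentation and
#' measurement pipeline. The two size parameters describe the smallest
#' grain the user expects; they drive the attribute-filter criteria
#' (crease filling at 0.3 x min width; debris removal at 0.7 x min width
#' and 0.7 x min length) and the area filter (0.5 x min width x min
#' length) after conversion to pixels at `dpi`.
#'
#' @param min_grain_width_mm smallest expected grain width (mm).
#' @param min_grain_length_mm smallest expected grain length (mm); must be
#'   at least the width.
#' @param dpi scanner resolution (dots per inch).
#' @param gaussian_sigma_px pre-smoothing Gaussian sigma in pixels.
#' @param elongation_threshold axis-ratio threshold of the scratch-removal
#'   thinning; structures more elongated than this are removed. Raise it
#'   for very elongated species.
#' @param dt_sigma_px Gaussian sigma (pixels) applied to the distance
#'   transform before watershed splitting of touching grains.
#' @param crease enable crease detection and crease/non-crease colour.
#' @param crease_tau detection threshold: minimum contrast (grey levels)
#'   between grain mean and crease-path mean for a crease to be declared.
#' @param crease_k along-axis mean-filter window (odd, pixels).
#' @param calibration optional [colour_transform] for CIELAB output.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_grain_width_mm = 2,
                            min_grain_length_mm = 4,
                            dpi = 300,
                            gaussian_sigma_px = 1,
                            elongation_threshold = 5,
                            dt_sigma_px = 2,
                            crease = FALSE,
                            crease_tau = 15,
                            crease_k = 9,
                            calibration = NULL) {
  stopifnot(min_grain_width_mm > 0,
            min_grain_length_mm >= min_grain_width_mm,
            dpi > 0, gaussian_sigma_px >= 0, elongation_threshold > 1,
            dt_sigma_px >= 0, crease_tau > 0, crease_k >= 3, crease_k %% 2 == 1)
  if (!is.null(calibration) && !inherits(calibration, "colour_transform"))
    stop("calibration must be a colour_transform")
  structure(list(min_grain_width_mm = min_grain_width_mm,
                 min_grain_length_mm = min_grain_length_mm,
                 dpi = dpi,
                 gaussian_sigma_px = gaussian_sigma_px,
                 elongation_threshold = elongation_threshold,
                 dt_sigma_px = dt_sigma_px,
                 crease = isTRUE(crease),
                 crease_tau = crease_tau,
                 crease_k = as.integer(crease_k),
                 calibration = calibration),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config: min grain %g x %g mm @ %g dpi, ",
                     "sigma=%g px, elongation<=%g, crease=%s>\n"),
              x$min_grain_width_mm, x$min_grain_length_mm, x$dpi,
              x$gaussian_sigma_px, x$elongation_threshold,
              if (x$crease) "on" else "off"))
  invisible(x)
}

config_px <- function(config) {
  list(min_width = mm_to_px(config$min_grain_width_mm, config$dpi),
       min_length = mm_to_px(config$min_grain_length_mm, config$dpi))
}

#' Preprocess the grey image before thresholding
#'
#' Simplifies the grey image with the fixed operator chain: Gaussian
#' smoothing (noise), attribute closing with width criterion 0.3 x min
#' grain width (fills the dark grain crease), elongation thinning (removes
#' bright scratches), attribute opening with width criterion 0.7 x min
#' grain width (thin debris) and attribute opening with length criterion
#' 0.7 x min grain length (thick debris). All attribute operators are
#' contour-preserving.
#'
#' @param gray numeric grey matrix from [to_grayscale()].
#' @param config a [pipeline_config()].
#' @return simplified grey matrix.
#' @export
preprocess <- function(gray, config) {
  stopifnot(inherits(config, "pipeline_config"))
  px <- config_px(config)
  m <- as_num_matrix(gray)
  if (config$gaussian_sigma_px > 0) {
    ksize <- 2 * ceiling(3 * config$gaussian_sigma_px) + 1
    if (ksize > min(dim(m))) stop("smoothing kernel larger than image")
    m <- as.matrix(EBImage::gblur(m, sigma = config$gaussian_sigma_px))
  }
  m <- attribute_closing(m, min_px = max(1, round(0.3 * px$min_width)),
                         attribute = "width")
  m <- elongation_thinning(m, max_ratio = config$elongation_threshold)
  m <- attribute_opening(m, min_px = max(1, round(0.7 * px$min_width)),
                         attribute = "width")
  m <- attribute_opening(m, min_px = max(1, round(0.7 * px$min_length)),
                         attribute = "length")
  m
}

#' Automated global threshold from the grey/gradient bivariate histogram
#'
#' Selects a single global grey threshold for separating bright grains from
#' the dark background. Edge pixels carry mixed grain/background values and
#' bias plain histogram methods, so the grey histogram is restricted to the
#' low-gradient stratum of the bivariate (grey level, gradient magnitude)
#' histogram - pixels whose gradient magnitude does not exceed the image
#' median - and the threshold maximises the between-class variance of that
#' stratum's grey histogram. Ties are resolved to the midpoint of the tying
#' levels, deterministically.
#'
#' @param gray numeric grey matrix (typically preprocessed).
#' @return scalar threshold; foreground is `gray > threshold`.
#' @export
global_threshold <- function(gray) {
  m <- as_num_matrix(gray)
  if (max(m) == min(m)) stop("no contrast: image is constant")
  gx <- matrix(0, nrow(m), ncol(m)); gy <- gx
  gx[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
  gy[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
  grad <- sqrt(gx^2 + gy^2)
  stratum <- m[grad <= stats::median(grad)]
  # 256-bin histogram over the stratum's grey range
  lo <- floor(min(stratum)); hi <- ceiling(max(stratum))
  if (hi == lo) hi <- lo + 1
  nb <- min(256L, max(2L, as.integer(hi - lo + 1)))
  edges <- seq(lo, hi, length.out = nb + 1L)
  h <- as.numeric(graphics::hist(stratum, breaks = edges, plot = FALSE)$counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  # between-class variance for every split after bin k
  wcum <- cumsum(h); total <- wcum[nb]
  mcum <- cumsum(h * mids); mtot <- mcum[nb]
  k <- seq_len(nb - 1L)
  w0 <- wcum[k]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nb - 1L)
  mu0 <- mcum[k][valid] / w0[valid]
  mu1 <- (mtot - mcum[k][valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  best <- which(bcv >= max(bcv) - 1e-9 * abs(max(bcv)))
  kstar <- best[ceiling(length(best) / 2)]
  edges[kstar + 1L]
}

#' Split touching grains
#'
#' Partitions the thresholded foreground by finding the troughs between
#' regional maxima of the Gaussian-smoothed Euclidean distance transform:
#' watershed flooding of the inverted smoothed distance map, restricted to
#' the mask. The union of the parts equals the input mask exactly; any
#' pixels the flood leaves unassigned are attached to the nearest part.
#'
#' @param mask logical foreground matrix.
#' @param config a [pipeline_config()]; `dt_sigma_px` controls the
#'   distance-map smoothing.
#' @return integer label matrix with attribute `n_objects`.
#' @export
split_touching <- function(mask, config) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- as.matrix(mask)
  if (!is.logical(m)) m <- m != 0
  if (!any(m)) {
    out <- matrix(0L, nrow(m), ncol(m)); attr(out, "n_objects") <- 0L
    return(out)
  }
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(m), nrow(m))))
  if (config$dt_sigma_px > 0)
    d <- as.matrix(EBImage::gblur(d, sigma = config$dt_sigma_px))
  d[!m] <- 0
  d[m & d <= 0] <- .Machine$double.eps
  ws <- as.matrix(EBImage::watershed(EBImage::as.Image(d), tolerance = 1, ext = 1))
  storage.mode(ws) <- "integer"
  ws[!m] <- 0L
  ws <- .fill_orphans(ws, m)
  relabel_consecutive(ws)
}

#' Remove small regions
#'
#' Removes labelled regions whose pixel area is below
#' 0.5 x min grain width x min grain length (in pixels), then relabels the
#' survivors consecutively from 1. This clears fragments created by the
#' splitting step.
#'
#' @param labels integer label matrix.
#' @param config a [pipeline_config()].
#' @return filtered, consecutively relabelled label matrix.
#' @export
filter_small <- function(labels, config) {
  stopifnot(inherits(config, "pipeline_config"))
  px <- config_px(config)
  thresh <- 0.5 * px$min_width * px$min_length
  lab <- labels
  storage.mode(lab) <- "integer"
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas > 0L & areas < thresh)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_consecutive(lab)
}

#' Segment a scan into individual grains
#'
#' Full segmentation chain: grey derivation (mean of red and green),
#' preprocessing ([preprocess()]), global thresholding
#' ([global_threshold()]), splitting of touching grains
#' ([split_touching()]) and small-region filtering ([filter_small()]).
#' Deterministic: identical image and configuration give a bit-identical
#' label map.
#'
#' @param image a [raster_image()].
#' @param config a [pipeline_config()].
#' @return integer label matrix with attribute `n_objects`.
#' @export
segment <- function(image, config) {
  stopifnot(inherits(image, "raster_image"), inherits(config, "pipeline_config"))
  gray <- to_grayscale(image)
  pre <- preprocess(gray, config)
  if (max(pre) - min(pre) < 10) {
    # a featureless scan is near-flat after preprocessing; grains on a dark
    # backing carry ~100 grey levels of contrast, so a dynamic range under
    # 10 levels means there is nothing to segment
    out <- matrix(0L, nrow(pre), ncol(pre))
    attr(out, "n_objects") <- 0L
    return(out)
  }
  t <- global_threshold(pre)
  mask <- pre > t
  labels <- split_touching(mask, config)
  filter_small(labels, config)
}
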