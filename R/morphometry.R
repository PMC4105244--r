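#' Per-grain size measurements in millimetres
#'
#' Computes, for every label, the pixel area, a Crofton 4-direction
#' perimeter estimate, and the major/minor axes of the best-fit ellipse
#' (the ellipse with the same normalised second central moments as the
#' pixel set - the standard length and width surrogates, robust to
#' boundary noise), all converted from pixels to millimetres via
#' 25.4 / dpi. Area is exactly `pixel_count * (25.4/dpi)^2`.
#'
#' A 1/12 per-pixel variance term enters the moment ellipse so that
#' degenerate 1-px-wide objects receive a finite minor axis of about one
#' pixel.
#'
#' @param labels integer label matrix (1..n, 0 background).
#' @param dpi scanner resolution in dots per inch.
#' @return tibble with one row per grain: `grain_id`, `area_mm2`,
#'   `perimeter_mm`, `majellipse_mm`, `minellipse_mm`, `centroid_row`,
#'   `centroid_col` (pixels), `orientation_rad` in (-pi/2, pi/2].
#' @export
#' @examples
#' lab <- matrix(0L, 60, 60); lab[20:40, 15:45] <- 1L
#' measure_size(lab, dpi = 300)
measure_size <- function(labels, dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1 || is.na(dpi) || dpi <= 0)
    stop("dpi must be a positive number")
  lab <- labels
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0L)
    return(tibble::tibble(grain_id = integer(), area_mm2 = numeric(),
                          perimeter_mm = numeric(), majellipse_mm = numeric(),
                          minellipse_mm = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(), orientation_rad = numeric()))
  scale <- 25.4 / dpi
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab) + 1L
  c <- (idx - 1L) %/% nrow(lab) + 1L
  cnt <- tabulate(l, nbins = n)
  sr <- rowsum_vec(r, l, n); sc <- rowsum_vec(c, l, n)
  srr <- rowsum_vec(as.numeric(r)^2, l, n)
  scc <- rowsum_vec(as.numeric(c)^2, l, n)
  src <- rowsum_vec(as.numeric(r) * c, l, n)
  mr <- sr / cnt; mc <- sc / cnt
  vrr <- srr / cnt - mr^2 + 1 / 12
  vcc <- scc / cnt - mc^2 + 1 / 12
  vrc <- src / cnt - mr * mc
  tr <- vrr + vcc
  disc <- pmax(tr^2 / 4 - (vrr * vcc - vrc^2), 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- pmax(tr / 2 - sqrt(disc), 1e-12)
  # orientation of the major axis, measured from the column (x) axis;
  # row axis points down, so negate to get the conventional sign
  theta <- 0.5 * atan2(2 * vrc, vcc - vrr)
  theta <- ifelse(theta <= -pi / 2, theta + pi, theta)
  tibble::tibble(
    grain_id = seq_len(n),
    area_mm2 = cnt * scale^2,
    perimeter_mm = crofton_perimeter(lab, n) * scale,
    majellipse_mm = 4 * sqrt(l1) * scale,
    minellipse_mm = 4 * sqrt(l2) * scale,
    centroid_row = mr,
    centroid_col = mc,
    orientation_rad = theta)
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(as.numeric(x), g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Crofton 4-direction perimeter estimate per label, in pixels.
# Counts label/other transitions along rows, columns and both diagonals
# (image border counts as background) and applies the Cauchy-Crofton
# weights: P = pi/2 * mean over directions of (crossings x line spacing).
crofton_perimeter <- function(lab, n) {
  H <- nrow(lab); W <- ncol(lab)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- lab
  count_dir <- function(dr, dc) {
    a <- pad[1:(H + 1L) + (dr < 0), 1:(W + 1L) + (dc < 0), drop = FALSE]
    b <- pad[1:(H + 1L) + (dr > 0), 1:(W + 1L) + (dc > 0), drop = FALSE]
    diff <- a != b
    tab <- numeric(n)
    for (m in list(a[diff], b[diff])) {
      mm <- m[m > 0L]
      if (length(mm)) {
        t <- tabulate(mm, nbins = n)
        tab <- tab + t
      }
    }
    tab
  }
  ch <- count_dir(0L, 1L)    # along rows
  cv <- count_dir(1L, 0L)    # along columns
  d1 <- count_dir(1L, 1L)
  d2 <- count_dir(1L, -1L)
  (pi / 2) * (ch * 1 + cv * 1 + d1 / sqrt(2) + d2 / sqrt(2)) / 4
}

#' Per-grain mean channel values
#'
#' Arithmetic mean of each colour channel over each grain's pixels, or over
#' caller-supplied sub-region masks (used by the crease partitioning).
#' Empty regions yield `NA` means.
#'
#' @param labels integer label matrix.
#' @param image a [raster_image()] of matching size.
#' @param region_masks optional logical matrix restricting the measured
#'   pixels (e.g. the non-crease region); same shape as `labels`.
#' @return tibble: `grain_id`, `mean_R`, `mean_G`, `mean_B`, `n_px`.
#' @export
mean_colour <- function(labels, image, region_masks = NULL) {
  stopifnot(inherits(image, "raster_image"))
  if (!all(dim(labels) == dim(image$pixels)[1:2]))
    stop("label map and image shapes differ")
  lab <- labels
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0L)
    return(tibble::tibble(grain_id = integer(), mean_R = numeric(),
                          mean_G = numeric(), mean_B = numeric(),
                          n_px = integer()))
  sel <- lab > 0L
  if (!is.null(region_masks)) {
    if (!all(dim(region_masks) == dim(lab))) stop("region mask shape differs")
    sel <- sel & region_masks
  }
  idx <- which(sel)
  l <- lab[idx]
  cnt <- if (length(l)) tabulate(l, nbins = n) else integer(n)
  ch_mean <- function(k) {
    plane <- image$pixels[, , k]
    s <- if (length(l)) rowsum_vec(as.numeric(plane[idx]), l, n) else numeric(n)
    ifelse(cnt > 0L, s / cnt, NA_real_)
  }
  tibble::tibble(grain_id = seq_len(n),
                 mean_R = ch_mean(1L), mean_G = ch_mean(2L),
                 mean_B = ch_mean(3L), n_px = as.integer(cnt))
}
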