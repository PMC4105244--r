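#' Published CIELAB reference values for the 24-patch ColorChecker
#'
#' The widely published CIELAB (D50, 2 degree observer) coordinates of the
#' classic 24-swatch ColorChecker card, in row-major card order (dark skin
#' first, black last). A user-supplied reference CSV with columns
#' `swatch_id`, `L`, `a`, `b` may be substituted anywhere a reference is
#' accepted; reported Lab values are in the illuminant of the reference
#' table used.
#'
#' @param path optional CSV to use instead of the packaged table.
#' @return tibble: `swatch_id`, `name` (if present), `L`, `a`, `b`.
#' @export
colorchecker_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "colorchecker_lab_d50.csv",
                        package = "seedscan", mustWork = TRUE)
  ref <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("swatch_id", "L", "a", "b")
  if (!all(need %in% names(ref)))
    stop("reference CSV must have columns swatch_id, L, a, b")
  ref
}

#' Locate and measure the swatches of a scanned colour-checker card
#'
#' Finds the swatch cells as locally uniform (low-gradient) regions of the
#' card scan, keeps the `rows x cols` candidates of mutually consistent
#' area, estimates the card orientation from the swatch centroids (robust
#' to rotations of a few degrees), orders the swatches row-major in the
#' card frame and averages RGB over the central 50% of each cell,
#' border-safe. Each swatch is matched positionally to a row of the
#' reference table.
#'
#' @param card_image a [raster_image()] of the card.
#' @param layout c(rows, cols) of the swatch grid.
#' @param reference reference table as from [colorchecker_reference()].
#' @return a `swatch_set` tibble: `swatch_id`, `mean_R`, `mean_G`,
#'   `mean_B`, `L`, `a`, `b`, `n_px`.
#' @export
extract_swatches <- function(card_image, layout = c(4L, 6L),
                             reference = colorchecker_reference()) {
  stopifnot(inherits(card_image, "raster_image"))
  nr <- layout[1]; nc <- layout[2]
  nsw <- nr * nc
  if (nrow(reference) != nsw)
    stop("reference has ", nrow(reference), " rows but layout expects ", nsw)
  g <- (as_num_matrix(card_image$pixels[, , 1]) +
          as_num_matrix(card_image$pixels[, , 2]) +
          as_num_matrix(card_image$pixels[, , 3])) / 3
  H <- nrow(g); W <- ncol(g)
  gx <- matrix(0, H, W); gy <- gx
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  grad <- sqrt(gx^2 + gy^2)
  flat <- grad <= max(3 * (2^card_image$bit_depth - 1) / 255,
                      2 * stats::median(grad))
  lab <- label_components(flat)
  n <- attr(lab, "n_objects")
  if (n < nsw) stop("card not found: too few uniform regions")
  areas <- tabulate(lab[lab > 0L], nbins = n)
  # swatches have mutually consistent area; background/card-body blobs are
  # far larger, noise specks far smaller
  ord <- order(areas, decreasing = TRUE)
  med <- stats::median(areas[ord][seq_len(min(n, nsw * 2))])
  cand <- which(areas >= 0.4 * med & areas <= 2.5 * med)
  # drop regions touching the image border (background)
  border_ids <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  cand <- setdiff(cand, border_ids)
  if (length(cand) < nsw) stop("card grid fit failure: found ",
                               length(cand), " swatch candidates")
  cand <- cand[order(areas[cand], decreasing = TRUE)][seq_len(nsw)]
  idx <- which(lab %in% cand)
  l <- lab[idx]
  r <- (idx - 1L) %% H + 1L; c <- (idx - 1L) %/% H + 1L
  cent <- dplyr::tibble(id = l, r = r, c = c) |>
    dplyr::summarise(cr = mean(.data$r), cc = mean(.data$c), .by = "id")
  # orientation from the dominant centroid direction: for a wider-than-tall
  # grid the first principal axis runs along the rows
  pc <- stats::prcomp(cbind(cent$cc, cent$cr))
  ang <- atan2(pc$rotation[2, 1], pc$rotation[1, 1])
  if (ang > pi / 2) ang <- ang - pi
  if (ang < -pi / 2) ang <- ang + pi
  u <- cent$cc * cos(ang) + cent$cr * sin(ang)    # along card rows
  v <- -cent$cc * sin(ang) + cent$cr * cos(ang)   # down card columns
  rowi <- cut_rank(v, nr); coli <- cut_rank(u, nc)
  if (anyDuplicated(paste(rowi, coli)))
    stop("card grid fit failure: ambiguous swatch arrangement")
  order_idx <- order(rowi, coli)
  ids <- cent$id[order_idx]
  # central 50% of each swatch cell, border-safe
  mean_central <- function(sid) {
    pix <- which(lab == sid)
    pr <- (pix - 1L) %% H + 1L; pc2 <- (pix - 1L) %/% H + 1L
    uu <- pc2 * cos(ang) + pr * sin(ang)
    vv <- -pc2 * sin(ang) + pr * cos(ang)
    keep <- uu >= stats::quantile(uu, 0.25) & uu <= stats::quantile(uu, 0.75) &
      vv >= stats::quantile(vv, 0.25) & vv <= stats::quantile(vv, 0.75)
    pix <- pix[keep]
    vapply(1:3, function(ch) mean(card_image$pixels[, , ch][pix]), numeric(1))
  }
  m <- t(vapply(ids, mean_central, numeric(3)))
  out <- tibble::tibble(swatch_id = reference$swatch_id,
                        mean_R = m[, 1], mean_G = m[, 2], mean_B = m[, 3],
                        L = reference$L, a = reference$a, b = reference$b,
                        n_px = as.integer(areas[ids]))
  class(out) <- c("swatch_set", class(out))
  out
}

cut_rank <- function(x, k) {
  # partition a coordinate into k grid indices by rank
  as.integer(ceiling(rank(x, ties.method = "first") / (length(x) / k)))
}

#' Fit the RGB to CIELAB calibration transform
#'
#' Joint least-squares regression of the three Lab channels on the swatch
#' mean RGB values: `Lab = M %*% rgb + offset`. The training residual is
#' summarised as the root of the mean squared Euclidean Lab distance
#' (Delta E) over the swatches.
#'
#' @param swatches a swatch set from [extract_swatches()] (or any tibble
#'   with columns `mean_R`, `mean_G`, `mean_B`, `L`, `a`, `b`).
#' @return object of class `colour_transform`: `matrix` (3x3), `offset`
#'   (length 3), `residual_rms`, `per_swatch` (tibble with per-swatch
#'   Delta E).
#' @export
fit_transform <- function(swatches) {
  sw <- tibble::as_tibble(swatches)
  need <- c("mean_R", "mean_G", "mean_B", "L", "a", "b")
  stopifnot(all(need %in% names(sw)))
  if (nrow(sw) < 4) stop("at least 4 swatches are required")
  X <- as.matrix(sw[, c("mean_R", "mean_G", "mean_B")])
  Y <- as.matrix(sw[, c("L", "a", "b")])
  if (qr(cbind(1, X))$rank < 4)
    stop("degenerate swatch colours: regression design is rank deficient")
  fit <- stats::lm.fit(cbind(1, X), Y)
  M <- t(fit$coefficients[2:4, ])
  o <- as.numeric(fit$coefficients[1, ])
  pred <- X %*% t(M) + rep(o, each = nrow(X))
  de <- sqrt(rowSums((Y - pred)^2))
  per <- tibble::tibble(swatch_id = if ("swatch_id" %in% names(sw))
    sw$swatch_id else seq_len(nrow(sw)), delta_e = de)
  structure(list(matrix = unname(M), offset = o,
                 residual_rms = sqrt(mean(de^2)), per_swatch = per),
            class = "colour_transform")
}

#' @export
print.colour_transform <- function(x, ...) {
  cat(sprintf("<colour_transform: RGB -> CIELAB, training Delta E rms %.4g>\n",
              x$residual_rms))
  print(round(x$matrix, 5))
  cat("offset:", round(x$offset, 4), "\n")
  invisible(x)
}

#' @rdname fit_transform
#' @param x a `colour_transform`.
#' @param ... unused.
#' @export
tidy.colour_transform <- function(x, ...) {
  tibble::tibble(
    term = c(t(outer(c("L", "a", "b"), c("R", "G", "B"), paste, sep = "~")),
             paste0("offset_", c("L", "a", "b"))),
    estimate = c(t(x$matrix), x$offset))
}

#' @rdname fit_transform
#' @export
glance.colour_transform <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms,
                 n_swatches = nrow(x$per_swatch),
                 max_delta_e = max(x$per_swatch$delta_e))
}

#' @rdname fit_transform
#' @param object a `colour_transform`.
#' @export
autoplot.colour_transform <- function(object, ...) {
  ggplot2::ggplot(object$per_swatch,
                  ggplot2::aes(x = factor(.data$swatch_id), y = .data$delta_e)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$residual_rms, linetype = 2) +
    ggplot2::labs(x = "swatch", y = expression(Delta * E),
                  title = "Calibration residuals per swatch") +
    ggplot2::theme_minimal()
}

#' Apply a calibration transform to mean RGB values
#'
#' Maps per-grain (or per-swatch) mean RGB to CIELAB with the fitted
#' affine transform. The transform is applied to region means rather than
#' per pixel; under an affine model the two are identical.
#'
#' @param transform a [colour_transform][fit_transform].
#' @param mean_rgb n x 3 matrix or a tibble with columns `mean_R`,
#'   `mean_G`, `mean_B`.
#' @return n x 3 matrix with columns L, a, b.
#' @export
apply_transform <- function(transform, mean_rgb) {
  stopifnot(inherits(transform, "colour_transform"))
  X <- if (is.matrix(mean_rgb)) mean_rgb
  else as.matrix(tibble::as_tibble(mean_rgb)[, c("mean_R", "mean_G", "mean_B")])
  out <- X %*% t(transform$matrix) + rep(transform$offset, each = nrow(X))
  colnames(out) <- c("L", "a", "b")
  out
}

#' Save / load a calibration transform as float TIFFs
#'
#' The 3x3 matrix and the 3x1 offset are written as two 64-bit float TIFF
#' images named `<stem>RGB2Labmat.tif` and `<stem>RGB2Laboff.tif`; the
#' round trip through [load_transform()] is exact.
#'
#' @param transform a [colour_transform][fit_transform].
#' @param stem path stem for the two files.
#' @return character vector of the two paths, invisibly.
#' @export
save_transform <- function(transform, stem) {
  stopifnot(inherits(transform, "colour_transform"))
  mat_path <- paste0(stem, "RGB2Labmat.tif")
  off_path <- paste0(stem, "RGB2Laboff.tif")
  write_float_tiff(transform$matrix, mat_path)
  write_float_tiff(matrix(transform$offset, ncol = 1), off_path)
  invisible(c(mat_path, off_path))
}

#' @rdname save_transform
#' @export
load_transform <- function(stem) {
  mat_path <- paste0(stem, "RGB2Labmat.tif")
  off_path <- paste0(stem, "RGB2Laboff.tif")
  M <- read_float_tiff(mat_path)
  o <- as.numeric(read_float_tiff(off_path))
  if (!all(dim(M) == c(3, 3)) || length(o) != 3)
    stop("unexpected calibration image shapes")
  structure(list(matrix = M, offset = o, residual_rms = NA_real_,
                 per_swatch = NULL),
            class = "colour_transform")
}
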