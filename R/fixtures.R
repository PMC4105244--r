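#' Synthetic grain-field specification
#'
#' Describes a synthetic flatbed scan: elliptical grains with Gaussian
#' length/width variation, uniform random orientation, optional dark
#' longitudinal crease, a controllable fraction of touching pairs, a dark
#' background and additive Gaussian pixel noise. The seed fully determines
#' the rendered scene; rendering is anti-aliased by 4x supersampling per
#' grain.
#'
#' Defaults emulate bulk wheat scans at 300 dpi: grain length 6.7 mm and
#' width 3.4 mm on average (giving a mean grain area close to 18 mm2),
#' wheat-coloured bodies on a dark backing with around 100 grey levels of
#' grain/background contrast.
#'
#' @param n_grains number of grains to place.
#' @param length_mm,length_sd_mm grain length distribution (mm).
#' @param width_mm,width_sd_mm grain width distribution (mm).
#' @param body_rgb mean grain colour (8-bit RGB).
#' @param body_sd per-grain colour variation (grey levels).
#' @param crease_fraction fraction of grains rendered with a crease.
#' @param crease_depth crease darkening (grey levels subtracted).
#' @param crease_width_mm crease stripe width (mm).
#' @param touching_fraction fraction of grains placed as touching pairs.
#' @param background background level (8-bit).
#' @param noise_sd additive Gaussian noise sd (grey levels).
#' @param dpi render resolution.
#' @param seed integer seed; same spec + seed = identical scene.
#' @return object of class `grain_field_spec`.
#' @export
grain_field_spec <- function(n_grains = 50,
                             length_mm = 6.7, length_sd_mm = 0.35,
                             width_mm = 3.4, width_sd_mm = 0.18,
                             body_rgb = c(168, 128, 92), body_sd = 8,
                             crease_fraction = 0, crease_depth = 50,
                             crease_width_mm = 0.45,
                             touching_fraction = 0,
                             background = 16, noise_sd = 2,
                             dpi = 300, seed = 1L) {
  stopifnot(n_grains >= 0, length_mm > 0, width_mm > 0, length_mm >= width_mm,
            crease_fraction >= 0, crease_fraction <= 1,
            touching_fraction >= 0, touching_fraction <= 1,
            dpi > 0, noise_sd >= 0, length(body_rgb) == 3)
  structure(as.list(environment()), class = "grain_field_spec")
}

#' Wheat-like scene preset
#'
#' @param n_grains grains per scene.
#' @param ... overrides passed to [grain_field_spec()].
#' @return a [grain_field_spec()].
#' @export
wheat_spec <- function(n_grains = 50, ...) {
  grain_field_spec(n_grains = n_grains, ...)
}

#' Brachypodium-like scene preset (strongly elongated grains)
#'
#' Mean grain length 8.71 mm and width 1.47 mm; note the axis ratio of
#' about 6 requires raising `elongation_threshold` in [pipeline_config()].
#'
#' @param n_grains grains per scene.
#' @param ... overrides passed to [grain_field_spec()].
#' @return a [grain_field_spec()].
#' @export
brachypodium_spec <- function(n_grains = 18, ...) {
  grain_field_spec(n_grains = n_grains, length_mm = 8.71, length_sd_mm = 0.3,
                   width_mm = 1.47, width_sd_mm = 0.08, ...)
}

#' Render a synthetic grain field with ground truth
#'
#' Places the grains on a jittered grid (touching pairs share a cell),
#' rasterises each ellipse at 4x supersampling for anti-aliased edges,
#' composites over the background, and adds pixel noise. Ground truth
#' labels mark pixels with at least half ellipse coverage; the truth table
#' records each grain's true dimensions (mm), colour, orientation and
#' crease parameters.
#'
#' @param spec a [grain_field_spec()].
#' @return list with elements `image` (a [raster_image()]), `labels`
#'   (integer truth label matrix), `truth` (tibble of per-grain parameters)
#'   and `crease_masks` (logical matrix marking true crease pixels).
#' @export
render_grain_field <- function(spec) {
  stopifnot(inherits(spec, "grain_field_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(spec$seed)

  ppm <- spec$dpi / 25.4                       # pixels per mm
  len_px_max <- (spec$length_mm + 4 * spec$length_sd_mm) * ppm
  cell <- ceiling(len_px_max + 12)
  n <- spec$n_grains
  n_pairs <- floor(n * spec$touching_fraction / 2)
  n_cells <- n - n_pairs                       # pairs share a cell
  ncol_cells <- max(1L, ceiling(sqrt(n_cells)))
  nrow_cells <- max(1L, ceiling(n_cells / ncol_cells))
  H <- nrow_cells * cell; W <- ncol_cells * cell

  img <- array(spec$background, c(H, W, 3))
  labels <- matrix(0L, H, W)
  cover_best <- matrix(0, H, W)
  crease_masks <- matrix(FALSE, H, W)

  pair_host <- if (n_pairs > 0) sort(sample(n_cells, n_pairs)) else integer()

  truth <- vector("list", n)
  gi <- 0L
  draw_geom <- function() {
    L <- max(spec$width_mm, stats::rnorm(1, spec$length_mm, spec$length_sd_mm))
    Wd <- min(L, max(0.4, stats::rnorm(1, spec$width_mm, spec$width_sd_mm)))
    list(L = L, Wd = Wd, a = L * ppm / 2, b = Wd * ppm / 2,
         th = stats::runif(1, -pi / 2, pi / 2),
         col = pmin(255, pmax(0, spec$body_rgb + stats::rnorm(3, 0, spec$body_sd))),
         has_crease = stats::runif(1) < spec$crease_fraction)
  }
  place <- function(g, cr, cc) {
    gi <<- gi + 1L
    stamp_grain(gi, cr, cc, g$a, g$b, g$th, g$col, g$has_crease)
    truth[[gi]] <<- tibble::tibble(
      grain_id = gi, length_mm = g$L, width_mm = g$Wd,
      area_mm2 = pi * (g$L / 2) * (g$Wd / 2), orientation_rad = g$th,
      centroid_row = cr, centroid_col = cc,
      body_R = g$col[1], body_G = g$col[2], body_B = g$col[3],
      has_crease = g$has_crease)
    invisible()
  }

  stamp_grain <- function(id, cr, cc, a, b, th, col, has_crease) {
    ss <- 4L
    r0 <- max(1L, floor(cr - a - 2)); r1 <- min(H, ceiling(cr + a + 2))
    c0 <- max(1L, floor(cc - a - 2)); c1 <- min(W, ceiling(cc + a + 2))
    nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
    # supersampled subpixel centres
    sub <- (seq_len(ss) - 0.5) / ss - 0.5
    rows <- rep(r0:r1, each = ss) + rep(sub, nr)
    colsv <- rep(c0:c1, each = ss) + rep(sub, nc)
    dr <- outer(rows - cr, rep(1, length(colsv)))
    dc <- outer(rep(1, length(rows)), colsv - cc)
    u <- dc * cos(th) + dr * sin(th)           # along major axis
    v <- -dc * sin(th) + dr * cos(th)          # along minor axis
    inside <- (u / a)^2 + (v / b)^2 <= 1
    in_crease <- if (has_crease) {
      wpx <- spec$crease_width_mm * ppm / 2
      inside & abs(v) <= wpx & abs(u) <= 0.85 * a
    } else inside & FALSE
    # box-average the supersamples back to pixels
    pool <- function(mat) {
      m <- matrix(as.numeric(mat), nrow = ss * nr)
      m <- rowsum(m, rep(seq_len(nr), each = ss))
      t(rowsum(t(m), rep(seq_len(nc), each = ss))) / (ss * ss)
    }
    cov <- pool(inside)
    covc <- pool(in_crease)
    if (max(cov) <= 0) return(invisible())
    rows_i <- r0:r1; cols_i <- c0:c1
    for (ch in 1:3) {
      plane <- img[rows_i, cols_i, ch]
      val <- col[ch] - if (has_crease) spec$crease_depth * pmin(1, covc / pmax(cov, 1e-9)) else 0
      img[rows_i, cols_i, ch] <<- plane * (1 - cov) + val * cov
    }
    lab_block <- labels[rows_i, cols_i]
    best_block <- cover_best[rows_i, cols_i]
    take <- cov >= 0.5 & cov > best_block
    lab_block[take] <- id
    best_block[take] <- cov[take]
    labels[rows_i, cols_i] <<- lab_block
    cover_best[rows_i, cols_i] <<- best_block
    if (has_crease) {
      cm <- crease_masks[rows_i, cols_i]
      cm[covc >= 0.5 & take] <- TRUE
      crease_masks[rows_i, cols_i] <<- cm
    }
    invisible()
  }

  for (cell_id in seq_len(n_cells)) {
    if (gi >= n) break
    ctr_r <- ((cell_id - 1L) %/% ncol_cells) * cell + cell / 2
    ctr_c <- ((cell_id - 1L) %% ncol_cells) * cell + cell / 2
    if (cell_id %in% pair_host && gi < n - 1L) {
      # touching pair: side by side along their minor axes, overlapping ~2 px
      g1 <- draw_geom(); g2 <- draw_geom()
      g2$th <- g1$th + stats::runif(1, -0.15, 0.15)
      phi <- g1$th + pi / 2
      d <- g1$b + g2$b - 2
      place(g1, ctr_r - d / 2 * sin(phi), ctr_c - d / 2 * cos(phi))
      place(g2, ctr_r + d / 2 * sin(phi), ctr_c + d / 2 * cos(phi))
    } else {
      place(draw_geom(), ctr_r + stats::runif(1, -3, 3),
            ctr_c + stats::runif(1, -3, 3))
    }
  }

  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- array(round(pmin(pmax(img, 0), 255)), dim(img))

  list(image = raster_image(img, dpi = spec$dpi, bit_depth = 8L,
                            source_path = "synthetic"),
       labels = structure(labels, n_objects = gi),
       truth = dplyr::bind_rows(truth),
       crease_masks = crease_masks)
}

#' Render a synthetic colour-checker card
#'
#' Renders a rows x cols swatch card whose swatch RGB values are the exact
#' inverse-affine image of the supplied CIELAB reference values under a
#' known ground-truth RGB -> Lab transform, so that calibration can be
#' validated to machine precision. The card sits on a mid-grey scan
#' background with a dark card body separating the swatches; optional
#' rotation, Gaussian blur and pixel noise emulate scan imperfections.
#'
#' @param reference_lab n x 3 matrix (or tibble with columns L, a, b) of
#'   reference CIELAB values; defaults to [colorchecker_reference()].
#' @param transform ground-truth transform: list with `matrix` (3x3) and
#'   `offset` (length 3) mapping RGB to Lab; default
#'   [synthetic_card_transform()].
#' @param swatch_px swatch cell size (pixels).
#' @param gap_px dark gap between swatches (pixels).
#' @param rotation_deg card rotation (degrees, counter-clockwise).
#' @param blur_sigma Gaussian blur sigma applied to the rendered card.
#' @param noise_sd additive Gaussian noise sd (grey levels, 8-bit scale).
#' @param layout c(rows, cols) of the swatch grid.
#' @param seed integer seed for the noise.
#' @param bit_depth 8 or 16. A 16-bit render keeps quantisation error two
#'   orders of magnitude below realistic sensor noise, isolating the noise
#'   response of the calibration from rounding effects.
#' @return list: `image` (a [raster_image()]), `true_transform`,
#'   `true_rgb` (n x 3 swatch RGB values in layout order).
#' @export
render_colour_card <- function(reference_lab = colorchecker_reference(),
                               transform = synthetic_card_transform(),
                               swatch_px = 60, gap_px = 14,
                               rotation_deg = 0, blur_sigma = 0,
                               noise_sd = 0, layout = c(4L, 6L),
                               seed = 1L, bit_depth = 8L) {
  bit_depth <- as.integer(bit_depth)
  stopifnot(bit_depth %in% c(8L, 16L))
  lab <- as.matrix(tibble::as_tibble(reference_lab)[, c("L", "a", "b")])
  nr <- layout[1]; nc <- layout[2]
  stopifnot(nrow(lab) == nr * nc)
  rgb <- t(solve(transform$matrix, t(lab) - transform$offset))
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("reference colours fall outside the renderable RGB gamut under this transform")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)

  margin <- 3L * gap_px
  card_h <- nr * swatch_px + (nr + 1) * gap_px
  card_w <- nc * swatch_px + (nc + 1) * gap_px
  diag_px <- ceiling(sqrt(card_h^2 + card_w^2))
  H <- diag_px + 2L * margin; W <- diag_px + 2L * margin
  img <- array(96, c(H, W, 3))                 # scanner-bed grey
  th <- rotation_deg * pi / 180
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  # rotate scene coords back into the card frame
  u <- (cols - ctr[2]) * cos(th) + (rows - ctr[1]) * sin(th) + card_w / 2
  v <- -(cols - ctr[2]) * sin(th) + (rows - ctr[1]) * cos(th) + card_h / 2
  on_card <- u >= 0 & u < card_w & v >= 0 & v < card_h
  for (ch in 1:3) img[, , ch][on_card] <- 8    # dark card body
  ci <- floor((u - gap_px) / (swatch_px + gap_px))
  ri <- floor((v - gap_px) / (swatch_px + gap_px))
  du <- u - gap_px - ci * (swatch_px + gap_px)
  dv <- v - gap_px - ri * (swatch_px + gap_px)
  in_swatch <- on_card & ci >= 0 & ci < nc & ri >= 0 & ri < nr &
    du >= 0 & du < swatch_px & dv >= 0 & dv < swatch_px
  sw <- ri * nc + ci + 1                       # row-major swatch index
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[in_swatch] <- rgb[sw[in_swatch], ch]
    img[, , ch] <- plane
  }
  if (blur_sigma > 0)
    for (ch in 1:3) img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch], blur_sigma))
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  scale <- if (bit_depth == 16L) 257 else 1
  img <- array(round(pmin(pmax(img, 0), 255) * scale), dim(img))
  list(image = raster_image(img, dpi = 300, bit_depth = bit_depth,
                            source_path = "synthetic-card"),
       scale = scale,
       true_transform = transform,
       true_rgb = rgb,
       # exact swatch set, before rasterisation/quantisation: the affine
       # image of the reference is recoverable from it to machine precision
       swatches = structure(
         tibble::tibble(swatch_id = seq_len(nrow(lab)),
                        mean_R = rgb[, 1], mean_G = rgb[, 2], mean_B = rgb[, 3],
                        L = lab[, 1], a = lab[, 2], b = lab[, 3]),
         class = c("swatch_set", class(tibble::tibble()))))
}

#' Ground-truth affine map used by the synthetic card renderer
#'
#' A fixed, invertible RGB -> Lab affine map chosen so that every swatch of
#' the standard 24-patch reference maps to an in-gamut RGB value. It is a
#' rendering device for validation, not a model of any real scanner.
#'
#' @return list with `matrix` (3x3) and `offset` (length 3).
#' @export
synthetic_card_transform <- function() {
  m <- rbind(c(0.09555, 0.27369, 0.01646),
             c(0.39084, -0.50191, 0.09364),
             c(0.15773, 0.33591, -0.50742))
  list(matrix = m, offset = c(5.097, 5.742, 2.202))
}
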