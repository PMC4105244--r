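test_that("an exact affine map is recovered to machine precision", {
  card <- render_colour_card()
  tr <- fit_transform(card$swatches)
  expect_lt(max(abs(tr$matrix - card$true_transform$matrix)), 1e-6)
  expect_lt(max(abs(tr$offset - card$true_transform$offset)), 1e-6)
  expect_lt(tr$residual_rms, 1e-6)

  # self-consistency: applying the fit back to the training swatches
  # reproduces the reference with the stored residual
  pred <- apply_transform(tr, card$swatches)
  de <- sqrt(rowSums((pred - as.matrix(card$swatches[, c("L", "a", "b")]))^2))
  expect_equal(sqrt(mean(de^2)), tr$residual_rms)
})

test_that("swatch extraction measures the rendered card accurately", {
  card <- render_colour_card()
  sw <- extract_swatches(card$image)
  expect_equal(nrow(sw), 24L)
  expect_lt(max(abs(as.matrix(sw[, c("mean_R", "mean_G", "mean_B")]) -
                      card$true_rgb)), 0.5)

  # blurred card still within 1 grey level
  cardb <- render_colour_card(blur_sigma = 2)
  swb <- extract_swatches(cardb$image)
  expect_lt(max(abs(as.matrix(swb[, c("mean_R", "mean_G", "mean_B")]) -
                      card$true_rgb)), 1)

  # rotated card: swatch-to-reference assignment still correct
  cardr <- render_colour_card(rotation_deg = 5, blur_sigma = 1, noise_sd = 0.5,
                              seed = 2)
  swr <- extract_swatches(cardr$image)
  expect_lt(max(abs(as.matrix(swr[, c("mean_R", "mean_G", "mean_B")]) -
                      cardr$true_rgb)), 1.5)
})

test_that("degenerate swatch sets are rejected", {
  sw <- render_colour_card()$swatches
  expect_error(fit_transform(sw[1:3, ]), "at least 4")
  coplanar <- sw[1:6, ]
  coplanar$mean_R <- 10; coplanar$mean_G <- 20; coplanar$mean_B <- 30
  expect_error(fit_transform(coplanar), "rank deficient")
})

test_that("noisy swatches give small residual and near-true matrix", {
  set.seed(51)
  sw <- render_colour_card()$swatches
  noisy <- sw
  noisy$mean_R <- noisy$mean_R + rnorm(24)
  noisy$mean_G <- noisy$mean_G + rnorm(24)
  noisy$mean_B <- noisy$mean_B + rnorm(24)
  tr <- fit_transform(noisy)
  true <- render_colour_card()$true_transform
  expect_lt(tr$residual_rms, 2)
  expect_lt(max(abs(tr$matrix - true$matrix)), 0.05)
})

test_that("fitted transform is invariant to swatch order", {
  sw <- render_colour_card()$swatches
  set.seed(52)
  perm <- sample(nrow(sw))
  tr1 <- fit_transform(sw)
  tr2 <- fit_transform(sw[perm, ])
  expect_equal(tr1$matrix, tr2$matrix)
  expect_equal(tr1$offset, tr2$offset)
})

test_that("transform save/load round trip is exact with the standard names", {
  d <- withr::local_tempdir()
  set.seed(53)
  tr <- structure(list(matrix = matrix(rnorm(9), 3), offset = rnorm(3),
                       residual_rms = 0.1, per_swatch = NULL),
                  class = "colour_transform")
  paths <- save_transform(tr, file.path(d, "cam1"))
  expect_identical(basename(paths),
                   c("cam1RGB2Labmat.tif", "cam1RGB2Laboff.tif"))
  back <- load_transform(file.path(d, "cam1"))
  expect_identical(back$matrix, tr$matrix)
  expect_identical(back$offset, tr$offset)

  # identity transform file shapes
  id <- structure(list(matrix = diag(3), offset = c(0, 0, 0),
                       residual_rms = 0, per_swatch = NULL),
                  class = "colour_transform")
  save_transform(id, file.path(d, "id"))
  expect_equal(dim(read_float_tiff(file.path(d, "idRGB2Labmat.tif"))), c(3L, 3L))
  expect_equal(dim(read_float_tiff(file.path(d, "idRGB2Laboff.tif"))), c(3L, 1L))
})

test_that("float TIFF writer agrees with the tiff-package reader on float32 data", {
  # cross-check the private float TIFF layout against an independent
  # reader: values representable in float32 survive both paths
  d <- withr::local_tempdir()
  m <- matrix(c(0.5, 0.25, -2, 1024, 3, 0.125), 2, 3)
  p <- file.path(d, "x.tif")
  seedscan:::write_float_tiff(m, p)
  expect_equal(seedscan:::read_float_tiff(p), m)
})

test_that("applying transforms matches the affine model", {
  # identity: Lab equals RGB numerically
  id <- structure(list(matrix = diag(3), offset = c(0, 0, 0),
                       residual_rms = 0, per_swatch = NULL),
                  class = "colour_transform")
  x <- matrix(c(10, 20, 30, 200, 100, 50), 2, 3, byrow = TRUE)
  expect_equal(unname(apply_transform(id, x)), x)

  # affine closure: a transform fitted on exact swatches maps a held-out
  # colour from the same affine map exactly
  card <- render_colour_card()
  tr <- fit_transform(card$swatches[1:20, ])
  held <- card$swatches[21:24, ]
  got <- apply_transform(tr, held)
  expect_equal(unname(got), unname(as.matrix(held[, c("L", "a", "b")])),
               tolerance = 1e-9)

  # realistic fitted transform maps mid-grey into the L* in [0, 100] band
  full <- fit_transform(card$swatches)
  grey <- apply_transform(full, matrix(c(128, 128, 128), 1))
  expect_gte(grey[1, "L"], 0); expect_lte(grey[1, "L"], 100)
})

test_that("tidy/glance/autoplot methods expose the fit", {
  tr <- fit_transform(render_colour_card()$swatches)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12L)
  gl <- glance(tr)
  expect_named(gl, c("residual_rms", "n_swatches", "max_delta_e"))
  expect_s3_class(autoplot(tr), "ggplot")
})
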