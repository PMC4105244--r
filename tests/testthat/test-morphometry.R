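test_that("area conversion is exact: pixel count times (25.4/dpi)^2", {
  lab <- matrix(0L, 60, 60); lab[11:60, 11:60] <- 1L   # 2500 px
  out <- measure_size(lab, dpi = 300)
  expect_identical(out$area_mm2, 2500 * (25.4 / 300)^2)
  expect_equal(out$area_mm2, 2500 * 645.16 / 90000, tolerance = 1e-12)
  expect_error(measure_size(lab, dpi = 0), "positive")
})

test_that("moment ellipse recovers rendered ellipse axes within 2%", {
  lab <- matrix(0L, 120, 160)
  lab[ellipse_mask(120, 160, 60, 80, a = 40, b = 19)] <- 1L
  out <- measure_size(lab, dpi = 300)
  expect_equal(out$majellipse_mm, 80 * 25.4 / 300, tolerance = 0.02)
  expect_equal(out$minellipse_mm, 38 * 25.4 / 300, tolerance = 0.02)
  expect_true(out$majellipse_mm >= out$minellipse_mm)
})

test_that("disc measurements: axis ratio within 1%, perimeter within 3% of 2*pi*r", {
  r <- 30
  lab <- matrix(0L, 100, 100)
  lab[ellipse_mask(100, 100, 50, 50, r, r)] <- 1L
  out <- measure_size(lab, dpi = 300)
  expect_equal(out$majellipse_mm / out$minellipse_mm, 1, tolerance = 0.01)
  expect_equal(out$perimeter_mm, 2 * pi * r * 25.4 / 300, tolerance = 0.03)
})

test_that("measurements are rotation invariant within 2%", {
  base <- NULL
  for (th in c(0, 0.3, 0.8, 1.2, pi / 2)) {
    lab <- matrix(0L, 160, 160)
    lab[ellipse_mask(160, 160, 80, 80, 45, 22, theta = th)] <- 1L
    out <- measure_size(lab, dpi = 300)
    if (is.null(base)) base <- out
    expect_equal(out$majellipse_mm, base$majellipse_mm, tolerance = 0.02)
    expect_equal(out$minellipse_mm, base$minellipse_mm, tolerance = 0.02)
  }
})

test_that("mm measurements are invariant under dpi doubling within 1.5%", {
  sp300 <- wheat_spec(n_grains = 6, dpi = 300, noise_sd = 0, seed = 41)
  sp600 <- wheat_spec(n_grains = 6, dpi = 600, noise_sd = 0, seed = 41)
  s300 <- render_grain_field(sp300); s600 <- render_grain_field(sp600)
  m300 <- measure_size(s300$labels, 300); m600 <- measure_size(s600$labels, 600)
  expect_equal(m600$area_mm2, m300$area_mm2, tolerance = 0.015)
  expect_equal(m600$majellipse_mm, m300$majellipse_mm, tolerance = 0.015)
  expect_equal(m600$minellipse_mm, m300$minellipse_mm, tolerance = 0.015)
})

test_that("degenerate 1-px-wide objects get a finite ~1 px minor axis", {
  lab <- matrix(0L, 30, 230); lab[15, 11:210] <- 1L
  out <- measure_size(lab, dpi = 300)
  expect_gt(out$minellipse_mm, 0)
  expect_equal(out$minellipse_mm, 25.4 / 300 * 4 * sqrt(1 / 12), tolerance = 1e-6)
})

test_that("mean colour equals the masked mean per channel", {
  px <- array(0L, c(20, 20, 3))
  lab <- matrix(0L, 20, 20)
  lab[5:10, 5:10] <- 1L
  for (ch in 1:3) px[, , ch][lab == 1L] <- c(120L, 80L, 40L)[ch]
  img <- raster_image(px, dpi = 300)
  out <- mean_colour(lab, img)
  expect_equal(unlist(out[1, c("mean_R", "mean_G", "mean_B")]),
               c(mean_R = 120, mean_G = 80, mean_B = 40))

  # half/half arithmetic
  px2 <- array(0L, c(10, 10, 3))
  lab2 <- matrix(0L, 10, 10); lab2[1:10, 1:2] <- 1L
  px2[, 2, ] <- rep(c(200L, 100L, 50L), each = 10)
  out2 <- mean_colour(lab2, raster_image(px2, dpi = 300))
  expect_equal(unname(unlist(out2[1, c("mean_R", "mean_G", "mean_B")])),
               c(100, 50, 25))

  # random texture vs brute-force masked mean, plus sub-region masks
  set.seed(42)
  px3 <- array(sample(0:255, 30 * 30 * 3, TRUE), c(30, 30, 3))
  lab3 <- matrix(0L, 30, 30)
  lab3[bf_components(matrix(runif(900) < 0.3, 30, 30)) > 0] <- 1L
  lab3[25:30, 25:30] <- 2L
  img3 <- raster_image(px3, dpi = 300)
  region <- matrix(rep(c(TRUE, FALSE), length.out = 900), 30, 30)
  out3 <- mean_colour(lab3, img3, region_masks = region)
  for (i in 1:2) {
    sel <- lab3 == i & region
    expect_equal(out3$mean_R[i], mean(px3[, , 1][sel]))
    expect_equal(out3$mean_B[i], mean(px3[, , 3][sel]))
  }

  # empty region flagged with NA colour
  out4 <- mean_colour(lab3, img3, region_masks = matrix(FALSE, 30, 30))
  expect_true(all(is.na(out4$mean_R)))
  expect_equal(out4$n_px, c(0L, 0L))
})
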