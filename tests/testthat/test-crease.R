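test_that("directional mean filter preserves axis-parallel structure", {
  # flat grain unchanged
  g <- matrix(100, 40, 80)
  mask <- ellipse_mask(40, 80, 20, 40, 35, 15)
  out <- directional_mean_filter(g, mask, 0, k = 9)
  expect_equal(out, g)

  # a dark stripe parallel to the axis is preserved
  gs <- g; gs[20, ] <- 40
  outs <- directional_mean_filter(gs, mask, 0, k = 9)
  expect_equal(outs[20, mask[20, ]], rep(40, sum(mask[20, ])))
  expect_equal(outs[10, mask[10, ]], rep(100, sum(mask[10, ])))

  # a 1-px blip perpendicular to the axis is attenuated by ~1/k
  gb <- g; gb[, 40] <- 100 - 55
  outb <- directional_mean_filter(gb, mask, 0, k = 11)
  centre <- outb[20, 40]
  expect_equal(100 - centre, 55 / 11, tolerance = 0.25)
})

test_that("the crease path tracks straight and sinuous creases", {
  H <- 60; W <- 120
  mask <- ellipse_mask(H, W, 30, 60, 52, 22)
  g <- matrix(15, H, W); g[mask] <- 150

  # straight dark stripe along the middle
  gs <- g; gs[29:31, 15:105][mask[29:31, 15:105]] <- 90
  filt <- directional_mean_filter(gs, mask, 0, k = 9)
  cr <- find_crease_path(filt, mask, 0, tau = 15)
  expect_true(cr$crease_detected)
  rows <- (cr$path_idx - 1) %% H + 1
  cols <- (cr$path_idx - 1) %/% H + 1
  in_stripe <- rows >= 28 & rows <= 32
  expect_gte(mean(in_stripe[cols >= 15 & cols <= 105]), 0.95)

  # crease-free grain with noise stays undetected
  set.seed(61)
  gn <- g; gn[mask] <- gn[mask] + rnorm(sum(mask), 0, 3)
  filtn <- directional_mean_filter(gn, mask, 0, k = 9)
  crn <- find_crease_path(filtn, mask, 0, tau = 15)
  expect_false(crn$crease_detected)

  # sinuous crease with <= 1 px/column drift is tracked
  gw <- g
  drift <- round(4 * sin(seq(0, 2 * pi, length.out = W)))
  for (cc in 15:105) {
    rr <- 30 + drift[cc]
    if (mask[rr, cc]) gw[(rr - 1):(rr + 1), cc] <- 90
  }
  filtw <- directional_mean_filter(gw, mask, 0, k = 5)
  crw <- find_crease_path(filtw, mask, 0, tau = 15)
  expect_true(crw$crease_detected)
  roww <- (crw$path_idx - 1) %% H + 1
  colw <- (crw$path_idx - 1) %/% H + 1
  sel <- colw >= 20 & colw <= 100
  expect_gte(mean(abs(roww[sel] - (30 + drift[colw[sel]])) <= 2), 0.9)

  # grains narrower than 3 px: no crease, no error
  tiny <- matrix(FALSE, 10, 10); tiny[5, 3:8] <- TRUE
  expect_false(find_crease_path(g[1:10, 1:10], tiny, 0)$crease_detected)
})

test_that("colour partition is disjoint and satisfies the weighted-mean identity", {
  spec <- wheat_spec(n_grains = 10, crease_fraction = 0.6, crease_depth = 60,
                     noise_sd = 2, seed = 62)
  scene <- render_grain_field(spec)
  cfg <- wheat_config(crease = TRUE)
  lab <- segment(scene$image, cfg)
  sizes <- measure_size(lab, 300)
  cr <- detect_creases(scene$image, lab, sizes, cfg)

  # crease pixels lie inside their grain
  expect_true(all(lab[cr$crease_mask] > 0L))
  expect_true(all((cr$crease_labels == 0L) | (cr$crease_labels == lab)))

  pc <- partition_colour(scene$image, lab, cr)
  det <- which(pc$crease_detected)
  expect_gt(length(det), 0)
  for (i in det) {
    # exact weighted-mean identity per channel
    for (ch in c("R", "G", "B")) {
      whole <- pc[[paste0("mean_", ch)]][i]
      ncm <- pc[[paste0("noncrease_", ch)]][i]
      ccm <- pc[[paste0("crease_", ch)]][i]
      nw <- pc$n_px[i]; ncn <- pc$n_px_noncrease[i]; ccn <- pc$n_px_crease[i]
      expect_equal(ncn + ccn, nw)
      expect_equal(whole, (ncn * ncm + ccn * ccm) / nw, tolerance = 1e-12)
    }
  }
})

test_that("synthetic crease/body mixtures give the expected means", {
  # grain body (150,100,60), crease stripe (60,40,25): GS mean is the
  # area-weighted mixture and the non-crease mean is the body colour
  H <- 50; W <- 90
  px <- array(10L, c(H, W, 3))
  lab <- matrix(0L, H, W)
  body <- ellipse_mask(H, W, 25, 45, 40, 18)
  lab[body] <- 1L
  stripe <- body & row(lab) %in% 24:26
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[body] <- c(150L, 100L, 60L)[ch]
    plane[stripe] <- c(60L, 40L, 25L)[ch]
    px[, , ch] <- plane
  }
  img <- raster_image(px, dpi = 300)
  creases <- list(results = tibble::tibble(grain_id = 1L, crease_detected = TRUE,
                                           crease_contrast = 60),
                  crease_labels = matrix(as.integer(stripe), H, W),
                  crease_mask = stripe)
  pc <- partition_colour(img, lab, creases)
  f <- sum(stripe) / sum(body)
  expect_equal(pc$mean_R, (1 - f) * 150 + f * 60)
  expect_equal(pc$noncrease_G, 100)
  expect_equal(pc$crease_B, 25)
})

test_that("grains without a detected crease report whole-seed colour only", {
  spec <- wheat_spec(n_grains = 6, crease_fraction = 0, noise_sd = 2, seed = 63)
  scene <- render_grain_field(spec)
  cfg <- wheat_config(crease = TRUE)
  res <- grain_scan(scene$image, cfg)
  expect_true(all(!res$results$crease_detected))
  expect_true(all(is.na(res$results$L_noncrease)))
  expect_true(all(is.finite(res$results$mean_R)))
})
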