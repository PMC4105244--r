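# Crease detection: each grain is resampled into an axis-aligned frame
# (major axis horizontal, nearest-neighbour so colour values are never
# interpolated), mean-filtered along the axis to suppress texture
# unrelated to the crease, and the darkest left-to-right path across the
# grain is traced by dynamic programming. A crease is declared when the
# path is sufficiently darker than the grain as a whole.

# internal: axis-aligned nearest-neighbour resampling frame for one grain.
# Inverse mapping: each cell of the rotated bounding box samples its
# nearest source pixel, so the frame has no holes. Returns a matrix of
# source linear indices (0 = outside grain).
axis_frame <- function(grain_idx, H, W, orientation_rad, centroid) {
  r <- (grain_idx - 1L) %% H + 1L
  c <- (grain_idx - 1L) %/% H + 1L
  th <- orientation_rad
  u <- (c - centroid[2]) * cos(th) + (r - centroid[1]) * sin(th)
  v <- -(c - centroid[2]) * sin(th) + (r - centroid[1]) * cos(th)
  u0 <- floor(min(u)); u1 <- ceiling(max(u))
  v0 <- floor(min(v)); v1 <- ceiling(max(v))
  nu <- u1 - u0 + 1L; nv <- v1 - v0 + 1L
  uu <- matrix(u0:u1, nv, nu, byrow = TRUE)
  vv <- matrix(v0:v1, nv, nu)
  rr <- round(centroid[1] + uu * sin(th) + vv * cos(th))
  cc <- round(centroid[2] + uu * cos(th) - vv * sin(th))
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  src <- matrix(0L, nv, nu)
  j <- (cc[ok] - 1L) * H + rr[ok]
  inmask <- logical(H * W); inmask[grain_idx] <- TRUE
  j[!inmask[j]] <- 0L
  src[ok] <- j
  src
}

#' Mean filter along the grain's long axis
#'
#' Replaces each grain pixel by the mean over a k-pixel window oriented
#' along the grain's major axis, the window clipped to the grain mask.
#' Pixels outside the grain are untouched. Suppresses intensity variation
#' unrelated to the longitudinal crease before path tracing.
#'
#' @param gray numeric grey matrix.
#' @param grain_mask logical matrix marking the grain's pixels.
#' @param orientation_rad major-axis orientation from [measure_size()].
#' @param k odd window length (pixels).
#' @return grey matrix with the grain's pixels filtered.
#' @export
directional_mean_filter <- function(gray, grain_mask, orientation_rad, k = 9L) {
  stopifnot(k >= 3, k %% 2 == 1)
  m <- as_num_matrix(gray)
  idx <- which(grain_mask)
  if (!length(idx)) return(m)
  H <- nrow(m)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  cent <- c(mean(r), mean(c))
  th <- orientation_rad
  half <- (k - 1L) / 2L
  offs <- -half:half
  # sample along the axis direction with nearest-neighbour steps
  acc <- numeric(length(idx)); cnt <- numeric(length(idx))
  mask <- matrix(FALSE, nrow(m), ncol(m)); mask[idx] <- TRUE
  for (o in offs) {
    rr <- round(r + o * sin(th)); cc <- round(c + o * cos(th))
    ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
    j <- (cc - 1L) * H + rr
    ok[ok] <- mask[j[ok]]
    acc[ok] <- acc[ok] + m[j[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- m
  out[idx] <- acc / pmax(cnt, 1)
  out
}

#' Trace the crease path of one grain
#'
#' Resamples the grain into an axis-aligned frame (nearest neighbour),
#' finds the minimum-cost left-to-right path (cost = filtered intensity,
#' lateral steps of at most one row per column) and declares a crease when
#' the grain mean exceeds the path mean by more than `tau` grey levels.
#' The crease mask extends the path laterally over the contiguous dark
#' valley (pixels below grain mean - tau/2 connected to the path).
#'
#' @param filtered grey matrix, typically from [directional_mean_filter()].
#' @param grain_mask logical matrix marking the grain.
#' @param orientation_rad major-axis orientation.
#' @param tau detection contrast threshold (grey levels).
#' @return list: `crease_detected`, `contrast`, `crease_idx` (linear pixel
#'   indices of the crease region, empty when undetected), `path_idx`
#'   (indices of the traced path).
#' @export
find_crease_path <- function(filtered, grain_mask, orientation_rad, tau = 15) {
  m <- as_num_matrix(filtered)
  H <- nrow(m)
  idx <- which(grain_mask)
  none <- list(crease_detected = FALSE, contrast = NA_real_,
               crease_idx = integer(), path_idx = integer())
  if (!length(idx)) return(none)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  if (diff(range(r)) < 2L || diff(range(c)) < 2L) return(none)
  cent <- c(mean(r), mean(c))
  src <- axis_frame(idx, H, ncol(m), orientation_rad, cent)
  if (nrow(src) < 3L || ncol(src) < 3L) return(none)
  # the path is confined to the grain interior: boundary pixels are
  # darkened by the grain/background transition and would attract the path
  gm <- matrix(0, nrow(m), ncol(m)); gm[idx] <- 1
  interior <- as.matrix(EBImage::distmap(gm)) > 2
  if (!any(interior)) return(none)
  cost <- matrix(NA_real_, nrow(src), ncol(src))
  inside <- src > 0L
  inside[inside] <- interior[src[inside]]
  cost[inside] <- m[src[inside]]
  path_rows <- .min_cost_path(cost)
  cols <- which(path_rows > 0L)
  if (length(cols) < 3L) return(none)
  path_src <- src[cbind(path_rows[cols], cols)]
  path_src <- unique(path_src[path_src > 0L])
  if (!length(path_src)) return(none)
  grain_mean <- mean(m[idx])
  contrast <- grain_mean - mean(m[path_src])
  if (!(contrast > tau))
    return(list(crease_detected = FALSE, contrast = contrast,
                crease_idx = integer(), path_idx = path_src))
  # dark valley support: below grain_mean - tau/2, 8-connected to the path
  dark <- matrix(FALSE, nrow(m), ncol(m))
  dark[idx] <- m[idx] < grain_mean - tau / 2
  dark[path_src] <- TRUE
  dl <- label_components(dark)
  keep <- unique(dl[path_src])
  crease_idx <- which(dl %in% keep[keep > 0L] & grain_mask)
  list(crease_detected = TRUE, contrast = contrast,
       crease_idx = crease_idx, path_idx = path_src)
}

#' Detect creases for every grain of a label map
#'
#' Runs [directional_mean_filter()] and [find_crease_path()] per grain on
#' the segmentation grey image and assembles a crease label map (crease
#' pixels carry their grain's id).
#'
#' @param image a [raster_image()].
#' @param labels grain label matrix.
#' @param sizes size table from [measure_size()] (supplies orientations).
#' @param config a [pipeline_config()]; uses `crease_tau` and `crease_k`.
#' @return list: `results` (tibble grain_id, crease_detected, contrast),
#'   `crease_labels` (integer matrix), `crease_mask` (logical matrix).
#' @export
detect_creases <- function(image, labels, sizes, config) {
  stopifnot(inherits(image, "raster_image"), inherits(config, "pipeline_config"))
  gray <- to_grayscale(image)
  H <- nrow(gray)
  crease_labels <- matrix(0L, nrow(gray), ncol(gray))
  n <- max(labels)
  res <- vector("list", n)
  idx_all <- which(labels > 0L)
  by_grain <- split(idx_all, labels[idx_all])
  for (i in seq_len(n)) {
    gidx <- by_grain[[as.character(i)]]
    if (is.null(gidx)) next
    # work in the grain's padded bounding box
    r <- (gidx - 1L) %% H + 1L
    c <- (gidx - 1L) %/% H + 1L
    r0 <- max(1L, min(r) - 2L); r1 <- min(nrow(gray), max(r) + 2L)
    c0 <- max(1L, min(c) - 2L); c1 <- min(ncol(gray), max(c) + 2L)
    hh <- r1 - r0 + 1L
    sub <- gray[r0:r1, c0:c1, drop = FALSE]
    mask <- matrix(FALSE, hh, c1 - c0 + 1L)
    lidx <- (r - r0) + (c - c0) * hh + 1L
    mask[lidx] <- TRUE
    th <- sizes$orientation_rad[match(i, sizes$grain_id)]
    filt <- directional_mean_filter(sub, mask, th, k = config$crease_k)
    cr <- find_crease_path(filt, mask, th, tau = config$crease_tau)
    if (cr$crease_detected) {
      rr <- (cr$crease_idx - 1L) %% hh + r0
      cc <- (cr$crease_idx - 1L) %/% hh + c0
      crease_labels[cbind(rr, cc)] <- i
    }
    res[[i]] <- tibble::tibble(grain_id = i,
                               crease_detected = cr$crease_detected,
                               crease_contrast = cr$contrast)
  }
  list(results = dplyr::bind_rows(res),
       crease_labels = structure(crease_labels,
                                 n_objects = length(unique(crease_labels[crease_labels > 0L]))),
       crease_mask = crease_labels > 0L)
}

#' Whole-grain, crease and non-crease colour measurements
#'
#' Reports whole-seed mean colour for every grain (the GS mode); for
#' grains with a detected crease additionally the non-crease region mean
#' (the GSwc region) and the crease region mean. Grains without a detected
#' crease form the GSncd stratum. CIELAB columns are appended when a
#' calibration transform is supplied.
#'
#' @param image a [raster_image()].
#' @param labels grain label matrix.
#' @param creases result of [detect_creases()], or `NULL` when crease
#'   detection is off.
#' @param transform optional [colour_transform][fit_transform].
#' @return tibble with columns `grain_id`, `mean_R/G/B`, optional
#'   `L/a/b`, `crease_detected` and crease/non-crease Lab columns.
#' @export
partition_colour <- function(image, labels, creases = NULL, transform = NULL) {
  whole <- mean_colour(labels, image)
  out <- dplyr::select(whole, "grain_id", "mean_R", "mean_G", "mean_B")
  if (!is.null(transform)) {
    lab <- apply_transform(transform, whole)
    out$L <- lab[, "L"]; out$a <- lab[, "a"]; out$b <- lab[, "b"]
  }
  if (is.null(creases)) return(out)
  out <- dplyr::left_join(out,
                          dplyr::select(creases$results, "grain_id", "crease_detected"),
                          by = "grain_id")
  nc_col <- mean_colour(labels, image, region_masks = !creases$crease_mask)
  cc_col <- mean_colour(labels, image, region_masks = creases$crease_mask)
  det <- out$crease_detected
  add <- function(prefix, src) {
    vals <- if (!is.null(transform)) {
      v <- apply_transform(transform, src)
      list(L = v[, "L"], a = v[, "a"], b = v[, "b"])
    } else {
      list(L = NA_real_, a = NA_real_, b = NA_real_)
    }
    for (ch in c("L", "a", "b")) {
      col <- paste0(ch, "_", prefix)
      out[[col]] <<- ifelse(det, vals[[ch]], NA_real_)
    }
  }
  add("noncrease", nc_col)
  add("crease", cc_col)
  # raw-RGB region means kept for the weighted-mean identity and tests
  out$noncrease_R <- ifelse(det, nc_col$mean_R, NA_real_)
  out$noncrease_G <- ifelse(det, nc_col$mean_G, NA_real_)
  out$noncrease_B <- ifelse(det, nc_col$mean_B, NA_real_)
  out$crease_R <- ifelse(det, cc_col$mean_R, NA_real_)
  out$crease_G <- ifelse(det, cc_col$mean_G, NA_real_)
  out$crease_B <- ifelse(det, cc_col$mean_B, NA_real_)
  out$n_px <- whole$n_px
  out$n_px_crease <- cc_col$n_px
  out$n_px_noncrease <- nc_col$n_px
  out
}
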