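# Brute-force oracles, independent of the package's implementation paths.

# 8-connected components via igraph on the pixel adjacency graph.
bf_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, H, W))
  r <- (idx - 1) %% H; c <- (idx - 1) %/% H
  edges <- c()
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    rr <- r + d[1]; cc <- c + d[2]
    ok <- rr >= 0 & rr < H & cc >= 0 & cc < W
    ok[ok] <- mask[rr[ok] + cc[ok] * H + 1]
    if (any(ok)) {
      key <- rr[ok] + cc[ok] * H + 1
      edges <- c(edges, rbind(match(idx[ok], idx), match(key, idx)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, H, W); out[idx] <- comp
  out
}

# moment-ellipse attribute of a pixel set (same formula as the filters,
# computed by an entirely separate route)
bf_attribute <- function(pix, H, type) {
  r <- (pix - 1) %% H + 1; c <- (pix - 1) %/% H + 1
  mr <- mean(r); mc <- mean(c)
  vrr <- mean((r - mr)^2) + 1 / 12
  vcc <- mean((c - mc)^2) + 1 / 12
  vrc <- mean((r - mr) * (c - mc))
  tr <- vrr + vcc
  disc <- max(tr^2 / 4 - (vrr * vcc - vrc^2), 0)
  l1 <- tr / 2 + sqrt(disc); l2 <- max(tr / 2 - sqrt(disc), 0)
  switch(type,
         width = 4 * sqrt(l2),
         length = 4 * sqrt(l1),
         elongation = if (l2 <= 1e-12) Inf else sqrt(l1 / l2))
}

# brute-force grey-level attribute filter by explicit threshold
# decomposition and component-tree traversal (direct rule)
bf_attribute_filter <- function(img, type, thresh) {
  levs <- sort(unique(as.vector(img)))
  H <- nrow(img)
  nodes <- list()
  for (t in levs) {
    lab <- bf_components(img >= t)
    for (i in seq_len(max(lab)))
      nodes[[length(nodes) + 1]] <- list(level = t, pix = which(lab == i))
  }
  nlev <- vapply(nodes, `[[`, numeric(1), "level")
  val <- numeric(length(nodes))
  for (i in order(nlev)) {
    pix <- nodes[[i]]$pix
    a <- bf_attribute(pix, H, type)
    pass <- if (type == "elongation") a <= thresh else a >= thresh
    cands <- which(nlev < nlev[i] &
                     vapply(nodes, function(nd) all(pix %in% nd$pix), logical(1)))
    if (!length(cands)) { val[i] <- nlev[i]; next }       # root survives
    par <- cands[which.max(nlev[cands])]
    val[i] <- if (pass) nlev[i] else val[par]
  }
  out <- matrix(min(levs), nrow(img), ncol(img))
  for (i in order(nlev)) out[nodes[[i]]$pix] <- val[i]
  out
}

# greedy centroid matching of detected grains to ground truth
match_to_truth <- function(sizes, truth) {
  vapply(seq_len(nrow(sizes)), function(i) {
    which.min((truth$centroid_row - sizes$centroid_row[i])^2 +
                (truth$centroid_col - sizes$centroid_col[i])^2)
  }, integer(1))
}

# count-based recall/precision of a segmentation against truth: a truth
# grain is recovered if exactly one detected centroid falls nearest to it
# within half a grain length
segmentation_scores <- function(sizes, truth, tol_px = 20) {
  m <- match_to_truth(sizes, truth)
  d <- sqrt((truth$centroid_row[m] - sizes$centroid_row)^2 +
              (truth$centroid_col[m] - sizes$centroid_col)^2)
  hit <- d <= tol_px
  tp <- length(unique(m[hit]))
  list(recall = tp / nrow(truth), precision = tp / nrow(sizes))
}

# render a plain ellipse mask (no package code) for morphometry oracles
ellipse_mask <- function(H, W, cr, cc, a, b, theta = 0) {
  r <- matrix(seq_len(H), H, W); c <- matrix(seq_len(W), H, W, byrow = TRUE)
  u <- (c - cc) * cos(theta) + (r - cr) * sin(theta)
  v <- -(c - cc) * sin(theta) + (r - cr) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

wheat_config <- function(...) {
  pipeline_config(min_grain_width_mm = 2.5, min_grain_length_mm = 5,
                  dpi = 300, ...)
}
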