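#' Convert millimetres to pixels at a given scanner resolution
#'
#' Uses 25.4 mm per inch, rounds to the nearest integer and never returns
#' less than 1 px.
#'
#' @param mm length in millimetres.
#' @param dpi scanner resolution in dots per inch.
#' @return integer pixel count.
#' @export
#' @examples
#' mm_to_px(3.4, 300)
mm_to_px <- function(mm, dpi) {
  stopifnot(is.numeric(mm), is.numeric(dpi), dpi > 0)
  pmax(1L, as.integer(round(mm * dpi / 25.4)))
}

#' Convert pixels to millimetres at a given scanner resolution
#'
#' @param px length in pixels.
#' @param dpi scanner resolution in dots per inch.
#' @return length in millimetres.
#' @export
px_to_mm <- function(px, dpi) {
  stopifnot(is.numeric(dpi), dpi > 0)
  px * 25.4 / dpi
}

# Fixed qualitative 12-colour palette for label overlays, cycled by label id.
overlay_palette <- function() {
  c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFFF33",
    "#A65628", "#F781BF", "#00CED1", "#ADFF2F", "#FF00FF", "#1E90FF")
}

# internal: coerce a matrix-like to a plain numeric matrix
as_num_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    out <- matrix(0L, nrow(labels), ncol(labels))
    attr(out, "n_objects") <- 0L
    return(out)
  }
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  out <- matrix(lut[labels + 1L], nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  attr(out, "n_objects") <- length(ids)
  out
}
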