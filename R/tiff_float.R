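# Minimal 64-bit-float TIFF support for the calibration matrix/offset
# artifacts. General-purpose TIFF readers in this toolchain only handle
# integer or 32-bit float samples, while the calibration files must hold
# real-valued matrices exactly; these two functions write and read a
# single-strip, uncompressed, little-endian, one-sample-per-pixel TIFF
# with 64-bit IEEE float samples (SampleFormat = 3).

write_float_tiff <- function(m, path) {
  m <- as_num_matrix(m)
  H <- nrow(m); W <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  n_entries <- 9L
  data_offset <- 8L + 2L + n_entries * 12L + 4L  # header + IFD + next-IFD ptr
  writeChar("II", con, eos = NULL)
  w2(42L)
  w4(8L)                                         # IFD at byte 8
  w2(n_entries)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  entry(256L, 3L, 1L, W)                         # ImageWidth
  entry(257L, 3L, 1L, H)                         # ImageLength
  entry(258L, 3L, 1L, 64L)                       # BitsPerSample
  entry(259L, 3L, 1L, 1L)                        # Compression: none
  entry(262L, 3L, 1L, 1L)                        # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)               # StripOffsets
  entry(278L, 3L, 1L, H)                         # RowsPerStrip
  entry(279L, 4L, 1L, H * W * 8L)                # StripByteCounts
  entry(339L, 3L, 1L, 3L)                        # SampleFormat: IEEE float
  w4(0L)                                         # no next IFD
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  invisible(path)
}

read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  r2 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1L, 256L))
  r4 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || r2(2) != 42)
    stop("not a little-endian TIFF: ", path)
  ifd <- r4(4)
  n <- r2(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tags[[as.character(r2(e))]] <- r4(e + 8)
  }
  need <- c("256", "257", "258", "259", "273", "279", "339")
  if (!all(need %in% names(tags)) || tags[["258"]] != 64 ||
      tags[["259"]] != 1 || tags[["339"]] != 3)
    stop("not a 64-bit float TIFF written by this package: ", path)
  W <- tags[["256"]]; H <- tags[["257"]]
  off <- tags[["273"]]
  vals <- readBin(raw[(off + 1):(off + H * W * 8)], "numeric",
                  n = H * W, size = 8, endian = "little")
  matrix(vals, nrow = H, byrow = TRUE)
}
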