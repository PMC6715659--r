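# Minimal TIFF I/O.
#
# The installed R stack has no TIFF package, so the package carries its own
# codec for the two flavours the pipeline needs: single-plane grayscale,
# uncompressed, little-endian, either 16-bit unsigned (raw camera frames)
# or 32-bit float (corrected frames).  Baseline readers (ImageJ, tifffile,
# skimage) open both.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

#' Write a grayscale image as an uncompressed little-endian TIFF
#'
#' @param im numeric matrix (rows = image rows).  For `bits = 16` values
#'   must lie in `[0, 65535]` and are written as unsigned integers; for
#'   `bits = 32` values are written as IEEE single-precision floats.
#' @param path output file path.
#' @param bits 16 (unsigned integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(im, path, bits = 16L) {
  stopifnot(is.matrix(im), bits %in% c(16L, 32L))
  nr <- nrow(im); nc <- ncol(im)
  if (bits == 16L) {
    v <- as.vector(t(im))
    if (any(v < 0 | v > 65535)) stop("16-bit TIFF values must be in [0, 65535]")
    v <- as.integer(round(v))
    v[v > 32767L] <- v[v > 32767L] - 65536L  # two's-complement wrap for writeBin
  } else {
    v <- as.double(as.vector(t(im)))
  }
  sample_format <- if (bits == 16L) 1L else 3L
  bytes_per_px <- bits / 8L
  entries <- list(  # tag, type, count, value -- must stay sorted by tag
    c(256L, .tiff_types[["LONG"]], 1L, nc),
    c(257L, .tiff_types[["LONG"]], 1L, nr),
    c(258L, .tiff_types[["SHORT"]], 1L, bits),
    c(259L, .tiff_types[["SHORT"]], 1L, 1L),   # no compression
    c(262L, .tiff_types[["SHORT"]], 1L, 1L),   # BlackIsZero
    c(273L, .tiff_types[["LONG"]], 1L, NA),    # strip offset, patched below
    c(277L, .tiff_types[["SHORT"]], 1L, 1L),
    c(278L, .tiff_types[["LONG"]], 1L, nr),
    c(279L, .tiff_types[["LONG"]], 1L, nr * nc * bytes_per_px),
    c(339L, .tiff_types[["SHORT"]], 1L, sample_format))
  data_offset <- 8L + 2L + length(entries) * 12L + 4L
  entries[[6]][4] <- data_offset

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")     # first IFD offset
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(as.integer(e[1]), con, size = 2, endian = "little")
    writeBin(as.integer(e[2]), con, size = 2, endian = "little")
    writeBin(as.integer(e[3]), con, size = 4, endian = "little")
    if (e[2] == .tiff_types[["SHORT"]]) {
      writeBin(as.integer(e[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(e[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")     # no further IFD
  writeBin(v, con, size = bytes_per_px, endian = "little")
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff()] (or any baseline
#' uncompressed single-plane grayscale little-endian TIFF)
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L) {
    stop("not a little-endian TIFF: ", path)
  }
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (k in seq_len(n_entries)) {
    off <- ifd + 2 + (k - 1) * 12
    tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
    if (count == 1) {
      val <- if (type == .tiff_types[["SHORT"]]) u16(off + 8) else u32(off + 8)
    } else {
      # value array stored at offset
      voff <- u32(off + 8)
      sz <- if (type == .tiff_types[["SHORT"]]) 2 else 4
      val <- vapply(seq_len(count) - 1, function(i) {
        if (sz == 2) u16(voff + 2 * i) else u32(voff + 4 * i)
      }, numeric(1))
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  if (need(259, 1) != 1) stop("compressed TIFF not supported: ", path)
  nc <- need(256); nr <- need(257)
  bits <- need(258); fmt <- need(339, 1)
  offs <- need(273); counts <- need(279, nr * nc * bits / 8)
  payload <- unlist(lapply(seq_along(offs), function(i) raw[offs[i] + seq_len(counts[i])]),
                    use.names = FALSE)
  n_px <- nr * nc
  if (bits == 16 && fmt == 1) {
    v <- readBin(payload, "integer", n = n_px, size = 2, signed = FALSE,
                 endian = "little")
  } else if (bits == 32 && fmt == 3) {
    v <- readBin(payload, "double", n = n_px, size = 4, endian = "little")
  } else {
    stop("unsupported TIFF sample layout (bits = ", bits, ", format = ", fmt, ")")
  }
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}
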