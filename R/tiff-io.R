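## Minimal baseline-TIFF I/O: single-channel grayscale, uncompressed,
## little-endian, 8- or 16-bit unsigned. Kept deliberately small: the
## environment ships no R TIFF package and the pipeline only ever exchanges
## plain grayscale channel images (filename pattern <fixture>_<channel>.tif).

u16_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}
u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

#' Write a grayscale image as 16-bit uncompressed TIFF
#'
#' Values are rounded and clamped to `[0, 65535]`. The file is a baseline
#' little-endian TIFF with a single strip, readable by ImageJ, tifffile, etc.
#'
#' @param mat numeric matrix of non-negative intensities (rows = image rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(mat, path) {
  stopifnot(is.matrix(mat))
  if (any(!is.finite(mat)) || any(mat < 0)) stop("intensities must be finite and >= 0")
  h <- nrow(mat); w <- ncol(mat)
  v <- pmin(pmax(round(mat), 0), 65535)
  pix <- u16_raw(as.vector(t(v)))          # TIFF is row-major
  data_off <- 8L
  ifd_off <- data_off + length(pix)
  tag <- function(id, type, count, value) {
    val <- if (type == 3L) c(u16_raw(value), as.raw(c(0L, 0L))) else u32_raw(value)
    c(u16_raw(id), u16_raw(type), u32_raw(count), val)
  }
  tags <- c(
    tag(256L, 3L, 1L, w),                  # ImageWidth
    tag(257L, 3L, 1L, h),                  # ImageLength
    tag(258L, 3L, 1L, 16L),                # BitsPerSample
    tag(259L, 3L, 1L, 1L),                 # Compression = none
    tag(262L, 3L, 1L, 1L),                 # Photometric = BlackIsZero
    tag(273L, 4L, 1L, data_off),           # StripOffsets
    tag(277L, 3L, 1L, 1L),                 # SamplesPerPixel
    tag(278L, 3L, 1L, h),                  # RowsPerStrip
    tag(279L, 4L, 1L, length(pix))         # StripByteCounts
  )
  out <- c(
    as.raw(c(0x49, 0x49, 0x2a, 0x00)), u32_raw(ifd_off),
    pix,
    u16_raw(9L), tags, u32_raw(0L)
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Read a grayscale uncompressed TIFF
#'
#' Reads the first image of an uncompressed single-sample baseline TIFF
#' (8- or 16-bit unsigned, either byte order, any strip layout).
#'
#' @param path TIFF file path.
#' @return numeric matrix of intensities.
#' @export
read_gray_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  endian <- if (raw[1] == as.raw(0x49)) "little" else "big"
  rd <- function(off, size, n = 1L) {
    readBin(raw[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, signed = FALSE, endian = endian)
  }
  rd32 <- function(off, n = 1L) {  # unsigned 32-bit via double arithmetic
    b <- as.integer(raw[(off + 1L):(off + 4L * n)])
    dim(b) <- c(4L, n)
    if (endian == "big") b <- b[4:1, , drop = FALSE]
    as.numeric(b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ])
  }
  if (rd(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd32(4L)
  ntag <- rd(ifd, 2L)
  tags <- list()
  for (t in seq_len(ntag)) {
    off <- ifd + 2L + (t - 1L) * 12L
    id <- rd(off, 2L); type <- rd(off + 2L, 2L); count <- rd32(off + 4L)
    size <- c(1L, 1L, 2L, 4L)[type]  # BYTE/ASCII/SHORT/LONG
    if (is.na(size)) next
    voff <- if (size * count <= 4L) off + 8L else rd32(off + 8L)
    vals <- if (size == 4L) rd32(voff, count) else rd(voff, size, count)
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", id, " missing in ", path)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 8L)[1]
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  if (need(259L, 1L) != 1L) stop("compressed TIFF not supported: ", path)
  offs <- need(273L); counts <- need(279L, h * w * bits / 8)
  bytes <- unlist(lapply(seq_along(offs), function(s) {
    raw[(offs[s] + 1L):(offs[s] + counts[s])]
  }))
  px <- readBin(bytes, "integer", n = h * w, size = bits / 8L,
                signed = FALSE, endian = endian)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
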