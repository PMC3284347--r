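# Minimal baseline TIFF codec: single-image, grayscale, uncompressed,
# little-endian, uint16 or float32.  Written in-package because no TIFF
# reader is available in the deployment environment; covers exactly the
# subset of TIFF 6.0 that TXM beamline exports use (one strip per row block,
# PhotometricInterpretation BlackIsZero, SamplesPerPixel 1).

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

#' Write a grayscale image as an uncompressed TIFF
#'
#' Writes a single-page, little-endian, uncompressed grayscale TIFF.
#' `uint16` images are rounded and clipped to `[0, 65535]`; `float32` images
#' are stored as IEEE single precision.
#'
#' @param img Numeric matrix (rows x cols).
#' @param path Output file path.
#' @param type `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(img, path, type = c("float32", "uint16")) {
  type <- match.arg(type)
  img <- as.matrix(img)
  h <- nrow(img); w <- ncol(img)
  bps <- if (type == "uint16") 16L else 32L
  fmt <- if (type == "uint16") 1L else 3L     # SampleFormat: 1 uint, 3 IEEE float
  nbytes <- h * w * (bps / 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(8 + nbytes), con, size = 4, endian = "little")  # IFD offset
  vals <- as.vector(t(img))                    # TIFF is row-major
  if (type == "uint16") {
    vals <- pmin(pmax(round(vals), 0), 65535)
    # writeBin has no unsigned 16-bit mode; fold into signed range
    vals <- ifelse(vals > 32767, vals - 65536, vals)
    writeBin(as.integer(vals), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == .tiff_types[["SHORT"]]) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tags <- list(
    list(256L, .tiff_types[["LONG"]],  1L, w),        # ImageWidth
    list(257L, .tiff_types[["LONG"]],  1L, h),        # ImageLength
    list(258L, .tiff_types[["SHORT"]], 1L, bps),      # BitsPerSample
    list(259L, .tiff_types[["SHORT"]], 1L, 1L),       # Compression: none
    list(262L, .tiff_types[["SHORT"]], 1L, 1L),       # BlackIsZero
    list(273L, .tiff_types[["LONG"]],  1L, 8L),       # StripOffsets
    list(277L, .tiff_types[["SHORT"]], 1L, 1L),       # SamplesPerPixel
    list(278L, .tiff_types[["LONG"]],  1L, h),        # RowsPerStrip
    list(279L, .tiff_types[["LONG"]],  1L, nbytes),   # StripByteCounts
    list(339L, .tiff_types[["SHORT"]], 1L, fmt)       # SampleFormat
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) entry(tg[[1]], tg[[2]], tg[[3]], tg[[4]])
  writeBin(0L, con, size = 4, endian = "little")      # no next IFD
  invisible(path)
}

#' Read a grayscale TIFF written by this toolkit (or any baseline
#' uncompressed grayscale TIFF)
#'
#' @param path TIFF file path.
#' @return Numeric matrix (rows x cols).
#' @seealso [write_tiff()]
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  le <- rawToChar(raw[1:2]) == "II"
  if (!le && rawToChar(raw[1:2]) != "MM") stop("not a TIFF file: ", path)
  end <- if (le) "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = end)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = end)
  if (u16(2) != 42L) stop("bad TIFF magic in ", path)
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (k in seq_len(n_entries)) {
    off <- ifd + 2 + (k - 1) * 12
    tag <- u16(off); typ <- u16(off + 2); cnt <- u32(off + 4)
    sz <- c(1L, 1L, 2L, 4L, 8L)[typ]
    val_off <- if (cnt * sz <= 4) off + 8 else u32(off + 8)
    rd <- function(i) if (typ == 3L) u16(val_off + (i - 1) * 2) else u32(val_off + (i - 1) * 4)
    tags[[as.character(tag)]] <- vapply(seq_len(cnt), rd, numeric(1))
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  w <- need(256); h <- need(257); bps <- need(258, 16)
  if (need(259, 1) != 1) stop("compressed TIFF not supported: ", path)
  if (need(277, 1) != 1) stop("multi-sample TIFF not supported: ", path)
  fmt <- need(339, 1)
  offs <- need(273); counts <- need(279, h * w * bps / 8)
  buf <- unlist(lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + counts[i])]), use.names = FALSE)
  n <- h * w
  vals <- if (fmt == 3 && bps == 32) {
    readBin(buf, "numeric", n = n, size = 4, endian = end)
  } else if (fmt %in% c(1, 4) && bps == 16) {
    readBin(buf, "integer", n = n, size = 2, signed = FALSE, endian = end)
  } else if (fmt %in% c(1, 4) && bps == 8) {
    as.integer(buf[seq_len(n)])
  } else stop("unsupported TIFF pixel format (bits=", bps, ", fmt=", fmt, ")")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
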