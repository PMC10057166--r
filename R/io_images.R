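# Minimal baseline TIFF I/O (little-endian, uncompressed, single-plane
# grayscale; uint8 / uint16 / float32) plus PNG support via the png package.
# No TIFF library is assumed; the writer emits the smallest standard-
# conforming layout (one strip, sorted IFD) and the reader handles the
# uncompressed grayscale subset typically produced by scientific cameras and
# by numpy/tifffile.

tiff_tag <- function(id, type, count, value_raw, data_env) {
  # type codes: 3 = SHORT (2 bytes), 4 = LONG (4 bytes)
  size <- c(`3` = 2L, `4` = 4L)[[as.character(type)]]
  total <- size * count
  if (total <= 4L) {
    val <- c(value_raw, raw(4L - length(value_raw)))
  } else {
    stop("out-of-line tag values not needed by this writer")
  }
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    val)
}

u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write a matrix as a grayscale TIFF
#'
#' Baseline little-endian uncompressed single-strip TIFF. Integer matrices go
#' out as uint8/uint16 per `bit_depth`; `bit_depth = "float32"` writes an
#' IEEE float sample format (used for Fv/Fm maps).
#'
#' @param x Numeric matrix (rows x cols). For integer depths values must lie
#'   in `[0, 2^bit_depth - 1]`.
#' @param path Output file path.
#' @param bit_depth 8, 16, or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(x, path, bit_depth = 16L) {
  stopifnot(is.matrix(x))
  h <- nrow(x); w <- ncol(x)
  float <- identical(bit_depth, "float32")
  if (!float) {
    bit_depth <- as.integer(bit_depth)
    stopifnot(bit_depth %in% c(8L, 16L))
    if (any(x < 0) || any(x > 2^bit_depth - 1)) {
      stop("pixel values outside [0, 2^bit_depth - 1]")
    }
  }
  bits <- if (float) 32L else bit_depth
  sample_format <- if (float) 3L else 1L
  bytes_pp <- bits / 8L
  n_tags <- 10L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  ifd <- c(
    tiff_tag(256, 4, 1, u32raw(w)),            # ImageWidth
    tiff_tag(257, 4, 1, u32raw(h)),            # ImageLength
    tiff_tag(258, 3, 1, u16raw(bits)),         # BitsPerSample
    tiff_tag(259, 3, 1, u16raw(1L)),           # Compression = none
    tiff_tag(262, 3, 1, u16raw(1L)),           # Photometric = BlackIsZero
    tiff_tag(273, 4, 1, u32raw(data_offset)),  # StripOffsets
    tiff_tag(277, 3, 1, u16raw(1L)),           # SamplesPerPixel
    tiff_tag(278, 4, 1, u32raw(h)),            # RowsPerStrip
    tiff_tag(279, 4, 1, u32raw(h * w * bytes_pp)),  # StripByteCounts
    tiff_tag(339, 3, 1, u16raw(sample_format)) # SampleFormat
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42L), con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  writeBin(ifd, con)
  writeBin(0L, con, size = 4, endian = "little")   # next IFD
  v <- as.vector(t(x))                              # TIFF is row-major
  if (float) {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else if (bit_depth == 8L) {
    writeBin(as.raw(v), con)
  } else {
    vi <- as.integer(v)
    vi[vi > 32767L] <- vi[vi > 32767L] - 65536L     # two's complement uint16
    writeBin(vi, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_uint <- function(raw_vec, offset, size, endian_little) {
  b <- as.integer(raw_vec[offset + seq_len(size)])
  if (!endian_little) b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a grayscale TIFF
#'
#' Supports the uncompressed single-plane grayscale baseline subset
#' (uint8/uint16/float32, either endianness, one or more strips).
#'
#' @param path TIFF file path.
#' @return List: `pixels` (numeric/integer matrix), `bit_depth`
#'   (8, 16 or `"float32"`).
#' @export
read_gray_tiff <- function(path) {
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 8L) stop("not a TIFF: file too short")
  order_tag <- rawToChar(buf[1:2])
  le <- order_tag == "II"
  if (!le && order_tag != "MM") stop("not a TIFF: bad byte-order mark")
  if (read_uint(buf, 2, 2, le) != 42) stop("not a TIFF: bad magic")
  ifd_off <- read_uint(buf, 4, 4, le)
  n <- read_uint(buf, ifd_off, 2, le)
  tags <- list()
  type_size <- c(`1` = 1, `3` = 2, `4` = 4)
  for (i in seq_len(n)) {
    base <- ifd_off + 2 + (i - 1) * 12
    id <- read_uint(buf, base, 2, le)
    type <- read_uint(buf, base + 2, 2, le)
    count <- read_uint(buf, base + 4, 4, le)
    sz <- type_size[as.character(type)]
    if (is.na(sz)) { tags[[as.character(id)]] <- NA; next }
    total <- sz * count
    voff <- if (total <= 4) base + 8 else read_uint(buf, base + 8, 4, le)
    vals <- vapply(seq_len(count), function(j) {
      read_uint(buf, voff + (j - 1) * sz, sz, le)
    }, numeric(1))
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", id)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 1)[1]
  if (need(259, 1)[1] != 1) stop("unsupported TIFF: compressed data")
  if (need(277, 1)[1] != 1) stop("unsupported TIFF: multi-sample pixels")
  photometric <- need(262, 1)[1]
  if (!photometric %in% c(0, 1)) stop("unsupported TIFF: not grayscale")
  sample_format <- need(339, 1)[1]
  offsets <- need(273)
  counts <- need(279, h * w * bits / 8)
  payload <- unlist(lapply(seq_along(offsets), function(i) {
    buf[offsets[i] + seq_len(counts[i])]
  }))
  npx <- h * w
  if (sample_format == 3 && bits == 32) {
    v <- readBin(payload, "numeric", n = npx, size = 4,
                 endian = if (le) "little" else "big")
    depth <- "float32"
  } else if (sample_format %in% c(1, 4) || is.na(sample_format)) {
    if (bits == 8) {
      v <- as.integer(payload[seq_len(npx)])
    } else if (bits == 16) {
      v <- readBin(payload, "integer", n = npx, size = 2, signed = FALSE,
                   endian = if (le) "little" else "big")
    } else stop("unsupported TIFF bit depth: ", bits)
    depth <- as.integer(bits)
  } else stop("unsupported TIFF sample format: ", sample_format)
  px <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
  list(pixels = px, bit_depth = depth)
}

#' Read a grayscale image file (TIFF or PNG) as a raw_image
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param channel `"Fo"` or `"Fm"`.
#' @param bit_depth Expected bit depth for PNG rescaling (PNG stores
#'   normalized values); ignored for TIFF, which is self-describing.
#' @return A [raw_image()].
#' @export
read_image <- function(path, channel = c("Fm", "Fo"), bit_depth = 16L) {
  channel <- match.arg(channel)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    t <- read_gray_tiff(path)
    if (identical(t$bit_depth, "float32")) {
      stop("expected an integer-valued fluorescence frame, got float TIFF")
    }
    raw_image(t$pixels, t$bit_depth, channel)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    maxval <- 2^bit_depth - 1
    raw_image(matrix(as.integer(round(a * maxval)), nrow(a), ncol(a)),
              bit_depth, channel)
  } else {
    stop("unsupported image format: .", ext)
  }
}

#' Write an image pair to disk
#'
#' Emits `<plant>_<day>_Fo.tif` and `<plant>_<day>_Fm.tif` in `dir`.
#'
#' @param pair An [image_pair()].
#' @param dir Output directory (created if needed).
#' @return Named character vector `c(fo = ..., fm = ...)`, invisibly.
#' @export
write_image_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "image_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- paste0(pair$plant_id, "_", pair$day)
  fo_path <- file.path(dir, paste0(stem, "_Fo.tif"))
  fm_path <- file.path(dir, paste0(stem, "_Fm.tif"))
  write_gray_tiff(pair$fo$pixels, fo_path, pair$fo$bit_depth)
  write_gray_tiff(pair$fm$pixels, fm_path, pair$fm$bit_depth)
  invisible(c(fo = fo_path, fm = fm_path))
}

#' Write an Fv/Fm map to disk
#'
#' The ratio field goes out as a 32-bit float TIFF (invalid pixels as NaN)
#' and, optionally, a pseudocolor PNG rendering.
#'
#' @param map An `fvfm_map`.
#' @param path Output TIFF path.
#' @param png_path Optional PNG path for the rendering.
#' @param colormap_name Colormap for the rendering (see
#'   [render_pseudocolor()]).
#' @return `path`, invisibly.
#' @export
write_fvfm_map <- function(map, path, png_path = NULL,
                           colormap_name = "jet") {
  stopifnot(inherits(map, "fvfm_map"))
  vals <- map$values
  vals[map$valid == 0L] <- NaN
  write_gray_tiff(vals, path, "float32")
  if (!is.null(png_path)) {
    png::writePNG(render_pseudocolor(map, colormap_name), png_path)
  }
  invisible(path)
}
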