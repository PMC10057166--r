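# Core image-analysis workflow: threshold segmentation of the plant, per-pixel
# Fv/Fm = (Fm - Fo)/Fm with a validity mask, histogram-peak (mode)
# summarization, the 0.79 healthy/stressed rule, and fixed-scale pseudocolor
# rendering.

#' Construct a raw fluorescence frame
#'
#' @param pixels Integer matrix of intensities (rows x cols).
#' @param bit_depth 8 or 16.
#' @param channel `"Fo"` (minimum fluorescence, dark-adapted, reaction centers
#'   open) or `"Fm"` (maximum fluorescence under saturating excitation).
#' @return A `raw_image` object.
#' @export
raw_image <- function(pixels, bit_depth = 16L, channel = c("Fm", "Fo")) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxval)) {
    stop("intensities outside [0, ", maxval, "]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 channel = channel),
            class = "raw_image")
}

#' Pair one plant's Fo and Fm frames with identity metadata
#'
#' @param fo,fm [raw_image()] objects with identical shape and bit depth.
#' @param plant_id,group,day Identity metadata carried through the pipeline.
#' @return An `image_pair` object.
#' @export
image_pair <- function(fo, fm, plant_id = NA_character_,
                       group = NA_character_, day = NA_integer_) {
  stopifnot(inherits(fo, "raw_image"), inherits(fm, "raw_image"))
  if (!identical(dim(fo$pixels), dim(fm$pixels))) {
    stop("Fo and Fm shapes differ")
  }
  if (fo$bit_depth != fm$bit_depth) stop("Fo and Fm bit depths differ")
  structure(list(fo = fo, fm = fm, plant_id = as.character(plant_id),
                 group = as.character(group), day = as.integer(day)),
            class = "image_pair")
}

#' Otsu's threshold for a grayscale image
#'
#' Exhaustive search over all intensity levels for the split maximizing the
#' between-class variance of the two-class partition `{<= t, > t}`. Ties go
#' to the lowest threshold.
#'
#' @param pixels Integer matrix.
#' @param bit_depth 8 or 16.
#' @return Scalar threshold `t`; foreground is `pixels > t`.
#' @export
otsu_threshold <- function(pixels, bit_depth = 16L) {
  maxval <- 2^bit_depth - 1
  if (length(unique(as.vector(pixels))) < 2L) {
    stop("degenerate image: all pixels equal, Otsu threshold undefined")
  }
  counts <- tabulate(as.vector(pixels) + 1L, nbins = maxval + 1L)
  p <- counts / sum(counts)
  levels <- 0:maxval
  w0 <- cumsum(p)                      # P(class <= t)
  mu_t <- cumsum(p * levels)           # partial mean
  mu <- mu_t[length(mu_t)]
  # between-class variance for thresholds t = 0 .. maxval-1
  w0 <- w0[-length(w0)]
  mu_t <- mu_t[-length(mu_t)]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, maxval)
  sigma_b[valid] <- (mu * w0[valid] - mu_t[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  which.max(sigma_b) - 1L
}

#' Segment the plant from the background
#'
#' Foreground = pixels strictly above a threshold, either computed by Otsu's
#' method (default) or supplied as a fixed value.
#'
#' @param image A [raw_image()] (conventionally the brighter Fm frame).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Intensity threshold; required for `method = "fixed"`.
#' @return A `binary_mask` object: `pixels` (0/1 integer matrix),
#'   `threshold` (the value actually used), `method`.
#' @export
segment_plant <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(image, "raw_image"))
  maxval <- 2^image$bit_depth - 1
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    if (threshold < 0 || threshold > maxval) {
      stop("threshold outside intensity range [0, ", maxval, "]")
    }
  } else {
    threshold <- otsu_threshold(image$pixels, image$bit_depth)
  }
  mask <- matrix(0L, nrow(image$pixels), ncol(image$pixels))
  mask[image$pixels > threshold] <- 1L
  structure(list(pixels = mask, threshold = threshold, method = method),
            class = "binary_mask")
}

mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) return(mask$pixels)
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  m <- mask
  storage.mode(m) <- "integer"
  m
}

#' Per-pixel Fv/Fm map
#'
#' Applies `Fv/Fm = (Fm - Fo) / Fm` at every foreground pixel with
#' `Fm > eps`; everything else is marked invalid. Sensor noise can push Fo
#' above Fm (negative Fv): such pixels are clipped to 0 (and values above 1
#' to 1) and counted in `clipped_fraction` rather than invalidated, so area
#' statistics are preserved while quality is flagged.
#'
#' @param pair An [image_pair()].
#' @param mask A `binary_mask` (or plain 0/1 matrix) of the same shape.
#' @param eps Intensity floor for the divide-safety check (default 1).
#' @return An `fvfm_map`: `values` (reals in `[0, 1]` where valid, `NA`
#'   elsewhere), `valid` (0/1 integer matrix), `clipped_fraction`,
#'   `provenance` (plant_id, group, day), `eps`.
#' @export
compute_fvfm_map <- function(pair, mask, eps = 1) {
  stopifnot(inherits(pair, "image_pair"))
  m <- mask_matrix(mask)
  fm <- pair$fm$pixels
  fo <- pair$fo$pixels
  if (!identical(dim(m), dim(fm))) stop("mask shape differs from image shape")
  valid <- m == 1L & fm > eps
  raw <- (fm - fo) / fm
  clipped <- sum((raw < 0 | raw > 1) & valid)
  vals <- matrix(NA_real_, nrow(fm), ncol(fm))
  vals[valid] <- pmin(pmax(raw[valid], 0), 1)
  structure(
    list(
      values = vals,
      valid = matrix(as.integer(valid), nrow(fm), ncol(fm)),
      clipped_fraction = if (any(valid)) clipped / sum(valid) else 0,
      provenance = list(plant_id = pair$plant_id, group = pair$group,
                        day = pair$day),
      eps = eps
    ),
    class = "fvfm_map"
  )
}

#' Summarize an Fv/Fm map by its histogram peak
#'
#' Histograms the valid pixels over `[0, 1]` with the given bin width; the
#' plant-level scalar is the center of the highest-count bin (the mode of the
#' pixel distribution). Ties break to the lowest bin and are reported. The
#' pixel mean is reported alongside, since group-level statistics may use
#' either scalar. Health is classified by comparing the mode against the
#' threshold for unstressed leaves (mode >= threshold is healthy).
#'
#' @param map An [compute_fvfm_map()] result.
#' @param bin_width Histogram bin width in Fv/Fm units, in (0, 0.1]; must
#'   divide 1 evenly (default 0.01).
#' @param health_threshold Fv/Fm value at or above which the plant is labeled
#'   healthy (default 0.79).
#' @return An `fvfm_summary`: `mode`, `mean`, `n_valid`, `histogram` (list
#'   with `breaks`, `counts`, `mids`), `health`, `mode_tie`,
#'   `clipped_fraction`, `provenance`.
#' @export
summarize_fvfm <- function(map, bin_width = 0.01, health_threshold = 0.79) {
  stopifnot(inherits(map, "fvfm_map"))
  if (!(bin_width > 0 && bin_width <= 0.1)) {
    stop("bin_width must be in (0, 0.1]")
  }
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-8) {
    stop("bin_width must divide [0, 1] into a whole number of bins")
  }
  v <- map$values[map$valid == 1L]
  if (length(v) == 0L) stop("empty plant: no valid pixels to summarize")
  idx <- pmin(pmax(floor(v / bin_width) + 1L, 1L), nb)  # value 1.0 -> top bin
  counts <- tabulate(idx, nbins = nb)
  mode_bin <- which.max(counts)  # first maximal bin = lowest (tie rule)
  mode <- (mode_bin - 0.5) * bin_width
  breaks <- seq(0, 1, length.out = nb + 1L)
  structure(
    list(
      mode = mode,
      mean = mean(v),
      n_valid = length(v),
      histogram = list(breaks = breaks, counts = counts,
                       mids = (breaks[-1] + breaks[-(nb + 1L)]) / 2),
      health = if (mode >= health_threshold) "healthy" else "stressed",
      health_threshold = health_threshold,
      mode_tie = sum(counts == counts[mode_bin]) > 1L,
      clipped_fraction = map$clipped_fraction,
      provenance = map$provenance
    ),
    class = "fvfm_summary"
  )
}

# 256-entry color lookup tables on [0, 1]; "jet" runs blue (low) -> red
# (high) matching conventional Fv/Fm false-color panels.
pseudocolor_lut <- function(colormap_name) {
  n <- 256L
  switch(colormap_name,
    jet = {
      ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF",
                                     "#00FF00", "#FFFF00", "#FF0000",
                                     "#7F0000"))
      ramp(seq(0, 1, length.out = n)) / 255
    },
    viridis = t(grDevices::col2rgb(viridisLite::viridis(n))) / 255,
    magma = t(grDevices::col2rgb(viridisLite::magma(n))) / 255,
    inferno = t(grDevices::col2rgb(viridisLite::inferno(n))) / 255,
    plasma = t(grDevices::col2rgb(viridisLite::plasma(n))) / 255,
    turbo = t(grDevices::col2rgb(viridisLite::turbo(n))) / 255,
    stop("unknown colormap: '", colormap_name, "'")
  )
}

#' Render an Fv/Fm map in pseudocolor
#'
#' Valid pixels are mapped through a fixed `[0, 1]` color scale (never
#' per-image min-max), so renderings are directly comparable across days and
#' treatment groups. Invalid/background pixels get a reserved color distinct
#' from every in-scale color.
#'
#' @param map An `fvfm_map`.
#' @param colormap_name One of `"jet"` (default; blue = low, red = high),
#'   `"viridis"`, `"magma"`, `"inferno"`, `"plasma"`, `"turbo"`.
#' @param background RGB triple in `[0, 1]` for invalid pixels (default
#'   black).
#' @return Numeric array `rows x cols x 3` with values in `[0, 1]`.
#' @export
render_pseudocolor <- function(map, colormap_name = "jet",
                               background = c(0, 0, 0)) {
  stopifnot(inherits(map, "fvfm_map"), length(background) == 3L,
            all(background >= 0 & background <= 1))
  lut <- pseudocolor_lut(colormap_name)
  if (any(apply(lut, 1, function(rgb) all(abs(rgb - background) < 1e-9)))) {
    stop("background color collides with an in-scale color")
  }
  d <- dim(map$values)
  img <- array(0, c(d, 3L))
  vidx <- map$valid == 1L
  li <- pmin(pmax(floor(map$values[vidx] * 255) + 1L, 1L), 256L)
  for (ch in 1:3) {
    plane <- matrix(background[ch], d[1], d[2])
    plane[vidx] <- lut[li, ch]
    img[, , ch] <- plane
  }
  img
}

#' @export
print.fvfm_summary <- function(x, ...) {
  cat(sprintf(
    "Fv/Fm summary [%s %s day %s]: mode %.3f, mean %.3f, %d px, %s\n",
    x$provenance$plant_id, x$provenance$group, x$provenance$day,
    x$mode, x$mean, x$n_valid, x$health))
  invisible(x)
}
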