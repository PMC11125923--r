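#' Multiband reflectance stack
#'
#' A light container for co-registered single-plot reflectance rasters.
#' Bands are plain numeric matrices with values in \[0, 1\]; `valid` marks
#' the pixels that belong to the plot (non-nodata, inside the plot mask).
#'
#' @param bands named list of numeric matrices; names drawn from
#'   `c("blue", "green", "red", "rededge", "nir")`. All matrices must share
#'   one shape.
#' @param valid logical matrix of the same shape, `TRUE` where pixels are
#'   usable. Defaults to all pixels valid.
#' @return a `band_stack` object.
#' @export
band_stack <- function(bands, valid = NULL) {
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands))) {
    abort("`bands` must be a non-empty named list of matrices.")
  }
  known <- c("blue", "green", "red", "rededge", "nir")
  bad <- setdiff(names(bands), known)
  if (length(bad)) {
    abort(paste0("unknown band name(s): ", paste(bad, collapse = ", ")))
  }
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1L) abort("all bands must share one shape.")
  dm <- dims[[1]]
  if (is.null(valid)) valid <- matrix(TRUE, dm[1], dm[2])
  if (!identical(dim(valid), dm)) abort("`valid` must match the band shape.")
  for (nm in names(bands)) {
    v <- bands[[nm]][valid]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      abort(paste0("band '", nm, "' has reflectance outside [0, 1] on valid pixels."))
    }
  }
  structure(list(bands = bands, valid = valid), class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  dm <- dim(x$valid)
  cat("<band_stack> ", dm[1], "x", dm[2], " pixels, bands: ",
      paste(names(x$bands), collapse = ", "),
      " (", sum(x$valid), " valid)\n", sep = "")
  invisible(x)
}

#' Quantize a reflectance band to an 8-bit gray image
#'
#' Linear quantization `g = round(255 * r)` with round-half-up, clipped to
#' \[0, 255\]. Invalid pixels keep an `NA` gray value.
#'
#' @param band numeric matrix of reflectance in \[0, 1\], or a [band_stack()]
#'   (in which case `which` selects the band, default `"red"`: the red band
#'   carries the strongest canopy/soil contrast because vegetation absorbs
#'   red light).
#' @param valid optional logical matrix; ignored when `band` is a stack.
#' @param which band name used when `band` is a `band_stack`.
#' @return a `gray_image`: list with integer matrix `pixels` and `valid`.
#' @export
to_grayscale <- function(band, valid = NULL, which = "red") {
  if (inherits(band, "band_stack")) {
    if (!which %in% names(band$bands)) {
      abort(paste0("band '", which, "' not present in stack."))
    }
    valid <- band$valid
    band <- band$bands[[which]]
  }
  if (!is.matrix(band) || length(band) == 0L) abort("`band` must be a non-empty matrix.")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(band), ncol(band))
  v <- band[valid]
  if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
    abort("reflectance outside [0, 1] on valid pixels.")
  }
  g <- matrix(NA_integer_, nrow(band), ncol(band))
  g[valid] <- pmin(255L, pmax(0L, as.integer(round_half_up(255 * v))))
  structure(list(pixels = g, valid = valid), class = "gray_image")
}

#' Gray-level frequency histogram
#'
#' @param img a `gray_image` from [to_grayscale()].
#' @return integer vector of length 256; element `g + 1` counts the valid
#'   pixels with gray value `g`. Counts always sum to the number of valid
#'   pixels.
#' @export
gray_histogram <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  vals <- img$pixels[img$valid]
  tabulate(vals + 1L, nbins = 256L)
}

#' Otsu's threshold from a gray histogram
#'
#' Returns the gray level `t` maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split into levels `<= t` and `> t`.
#' Ties are broken toward the smallest optimal `t` so results are
#' deterministic. Computed with cumulative moments in one pass.
#'
#' @param hist integer vector of 256 gray-level counts, e.g. from
#'   [gray_histogram()].
#' @return integer threshold in \[0, 255\].
#' @export
otsu_threshold <- function(hist) {
  if (length(hist) != 256L || any(hist < 0)) {
    abort("`hist` must be 256 non-negative counts.")
  }
  n <- sum(hist)
  if (sum(hist > 0) < 2L) {
    abort("histogram has fewer than two distinct gray levels; no threshold exists.")
  }
  levels <- 0:255
  c0 <- cumsum(hist)          # pixels with level <= t
  m0 <- cumsum(hist * levels) # first moment up to t
  w0 <- c0 / n
  w1 <- 1 - w0
  mu0 <- ifelse(c0 > 0, m0 / c0, 0)
  mu1 <- ifelse(n - c0 > 0, (m0[256] - m0) / (n - c0), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  as.integer(which.max(bcv)) - 1L # first maximum = smallest optimal t
}

#' Segment soil background from a gray image
#'
#' Splits valid pixels at a threshold. With `polarity = "canopy_below"`
#' (default) the dark class is canopy — vegetation absorbs red, so canopy
#' pixels are dark in the red band. The segmented display image follows the
#' usual convention of zeroing the background class and retaining original
#' gray values on the canopy class.
#'
#' @param img a `gray_image`.
#' @param threshold integer cut point in \[0, 256\]: canopy is `gray < threshold`
#'   under `"canopy_below"` and `gray >= threshold` under `"canopy_above"`.
#'   Note [otsu_threshold()] returns the top level of the dark class, so the
#'   cut point separating the two Otsu classes is `otsu + 1`;
#'   [extract_coverage()] applies that shift for you.
#' @param polarity `"canopy_below"` (canopy = gray < threshold) or
#'   `"canopy_above"` (canopy = gray >= threshold).
#' @return a `canopy_mask`: logical matrix `mask` (TRUE = canopy, NA outside
#'   validity), `threshold_used`, `polarity`, `valid`, and `segmented`, the
#'   gray image with soil zeroed out.
#' @export
remove_soil <- function(img, threshold, polarity = c("canopy_below", "canopy_above")) {
  stopifnot(inherits(img, "gray_image"))
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 256) abort("`threshold` must lie in [0, 256].")
  g <- img$pixels
  canopy <- if (polarity == "canopy_below") g < threshold else g >= threshold
  canopy[!img$valid] <- NA
  seg <- g
  seg[!img$valid | !canopy %in% TRUE] <- 0L
  structure(
    list(mask = canopy, threshold_used = as.integer(threshold),
         polarity = polarity, valid = img$valid, segmented = seg),
    class = "canopy_mask"
  )
}

#' Canopy coverage from a canopy mask
#'
#' Coverage is the percentage of valid pixels classified as canopy.
#'
#' @param mask a `canopy_mask` from [remove_soil()], or a plain logical
#'   matrix (all pixels treated as valid, NAs excluded).
#' @return canopy coverage in percent, in \[0, 100\].
#' @export
canopy_coverage <- function(mask) {
  if (inherits(mask, "canopy_mask")) {
    m <- mask$mask[mask$valid]
  } else if (is.logical(mask)) {
    m <- mask[!is.na(mask)]
  } else {
    abort("`mask` must be a canopy_mask or a logical matrix.")
  }
  if (length(m) == 0L) abort("no valid pixels; coverage undefined.")
  100 * sum(m) / length(m)
}

#' Extract canopy coverage from a band stack
#'
#' Convenience wrapper running the whole red-band segmentation chain:
#' grayscale quantization, gray histogram, Otsu threshold, soil removal,
#' pixel-ratio coverage.
#'
#' @param stack a [band_stack()].
#' @param band band used for segmentation (default `"red"`).
#' @param polarity see [remove_soil()].
#' @return one-row tibble with `coverage` (%), `threshold`, `polarity`,
#'   `n_canopy`, `n_valid`, plus the `canopy_mask` in the `mask` list-column.
#' @export
extract_coverage <- function(stack, band = "red",
                             polarity = c("canopy_below", "canopy_above")) {
  polarity <- match.arg(polarity)
  img <- to_grayscale(stack, which = band)
  t <- otsu_threshold(gray_histogram(img))
  # the Otsu classes are {g <= t} and {g > t}; the cut point is t + 1
  msk <- remove_soil(img, t + 1L, polarity)
  tibble::tibble(
    coverage = canopy_coverage(msk),
    threshold = t,
    polarity = polarity,
    n_canopy = sum(msk$mask[msk$valid]),
    n_valid = sum(msk$valid),
    mask = list(msk)
  )
}
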