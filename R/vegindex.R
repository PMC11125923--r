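#' Vegetation index catalogue
#'
#' The ten indices supported by [compute_vi()], with the bands each one
#' needs. Formulas (reflectances, unitless):
#' \describe{
#'   \item{NDVI}{(NIR - Red) / (NIR + Red)}
#'   \item{NDRE}{(NIR - RedEdge) / (NIR + RedEdge)}
#'   \item{WDRVI}{(0.1 NIR - Red) / (0.1 NIR + Red)}
#'   \item{MSR}{(NIR/Red - 1) / (NIR/Red + 1)}
#'   \item{GNDVI}{(NIR - Green) / (NIR + Green)}
#'   \item{RVI}{NIR / Red}
#'   \item{LCI}{(NIR - RedEdge) / (NIR + Red)}
#'   \item{OSAVI}{(NIR - Red) / (NIR + Red + 0.16)}
#'   \item{SAVI}{1.5 (NIR - Red) / (NIR + Red + 0.5)}
#'   \item{EVI}{2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1)}
#' }
#' @return character vector of index names.
#' @export
vi_names <- function() {
  c("NDVI", "NDRE", "WDRVI", "MSR", "GNDVI", "RVI", "LCI", "OSAVI", "SAVI", "EVI")
}

# each entry: required bands and the pixelwise formula
.vi_defs <- list(
  NDVI  = list(bands = c("nir", "red"),
               f = function(b) (b$nir - b$red) / (b$nir + b$red)),
  NDRE  = list(bands = c("nir", "rededge"),
               f = function(b) (b$nir - b$rededge) / (b$nir + b$rededge)),
  WDRVI = list(bands = c("nir", "red"),
               f = function(b) (0.1 * b$nir - b$red) / (0.1 * b$nir + b$red)),
  MSR   = list(bands = c("nir", "red"),
               f = function(b) (b$nir / b$red - 1) / (b$nir / b$red + 1)),
  GNDVI = list(bands = c("nir", "green"),
               f = function(b) (b$nir - b$green) / (b$nir + b$green)),
  RVI   = list(bands = c("nir", "red"),
               f = function(b) b$nir / b$red),
  LCI   = list(bands = c("nir", "rededge", "red"),
               f = function(b) (b$nir - b$rededge) / (b$nir + b$red)),
  OSAVI = list(bands = c("nir", "red"),
               f = function(b) (b$nir - b$red) / (b$nir + b$red + 0.16)),
  SAVI  = list(bands = c("nir", "red"),
               f = function(b) 1.5 * (b$nir - b$red) / (b$nir + b$red + 0.5)),
  EVI   = list(bands = c("nir", "red", "blue"),
               f = function(b) 2.5 * (b$nir - b$red) /
                 (b$nir + 6 * b$red - 7.5 * b$blue + 1))
)

#' Compute a vegetation index raster
#'
#' Applies the index formula per pixel. Pixels where the formula is
#' undefined (zero or non-finite denominator) are marked invalid rather
#' than substituted with a fallback value.
#'
#' @param stack a [band_stack()].
#' @param name one of [vi_names()].
#' @return a `vi_map`: list with `name`, numeric matrix `values` (NA where
#'   invalid) and logical `valid` (input validity AND finite result).
#' @export
compute_vi <- function(stack, name) {
  stopifnot(inherits(stack, "band_stack"))
  if (!name %in% names(.vi_defs)) {
    abort(paste0("unknown vegetation index '", name, "'; see vi_names()."))
  }
  def <- .vi_defs[[name]]
  missing <- setdiff(def$bands, names(stack$bands))
  if (length(missing)) {
    abort(paste0("index ", name, " needs missing band(s): ",
                 paste(missing, collapse = ", ")))
  }
  vals <- suppressWarnings(def$f(stack$bands))
  valid <- stack$valid & is.finite(vals)
  vals[!valid] <- NA_real_
  structure(list(name = name, values = vals, valid = valid), class = "vi_map")
}

#' Mean vegetation index over a mask
#'
#' Arithmetic mean of valid index values under a pixel mask, e.g. the
#' canopy mask, so soil and shadow pixels do not dilute the plot signal.
#'
#' @param vi a `vi_map` from [compute_vi()].
#' @param mask a `canopy_mask`, a logical matrix, or NULL for all valid
#'   pixels.
#' @param shadow_quantile optional fraction in \[0, 1): drop the darkest
#'   `shadow_quantile` share of masked pixels (ranked by index value)
#'   before averaging, a simple stand-in for crop-shadow removal.
#'   Default 0 (off).
#' @return scalar mean.
#' @export
plot_mean <- function(vi, mask = NULL, shadow_quantile = 0) {
  stopifnot(inherits(vi, "vi_map"))
  sel <- vi$valid
  if (inherits(mask, "canopy_mask")) {
    sel <- sel & mask$valid & (mask$mask %in% TRUE)
  } else if (is.logical(mask)) {
    sel <- sel & (mask %in% TRUE)
  } else if (!is.null(mask)) {
    abort("`mask` must be a canopy_mask, logical matrix, or NULL.")
  }
  v <- vi$values[sel]
  if (length(v) == 0L) abort("no valid pixels under the mask; mean undefined.")
  if (shadow_quantile > 0) {
    stopifnot(shadow_quantile < 1)
    v <- v[v >= stats::quantile(v, shadow_quantile)]
  }
  mean(v)
}

#' Plot-level means for several vegetation indices
#'
#' @param stack a [band_stack()].
#' @param mask mask passed to [plot_mean()] (default: all valid pixels).
#' @param names indices to compute (default all ten).
#' @return one-row tibble, one column per index.
#' @export
vi_table <- function(stack, mask = NULL, names = vi_names()) {
  vals <- purrr::map_dbl(names, function(nm) plot_mean(compute_vi(stack, nm), mask))
  tibble::as_tibble(as.list(setNames(vals, names)))
}
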