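#' Write and read a band stack on disk
#'
#' Bands are stored as single-band 8-bit PNGs (reflectance mapped linearly
#' to \[0, 1\]) plus a JSON sidecar recording band names and the
#' validity mask, so a stack round-trips without a geospatial dependency.
#'
#' @param stack a [band_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `write_band_stack` returns the sidecar path invisibly;
#'   `read_band_stack` returns a [band_stack()].
#' @export
write_band_stack <- function(stack, dir, prefix = "scene") {
  stopifnot(inherits(stack, "band_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (bn in names(stack$bands)) {
    f <- file.path(dir, paste0(prefix, "_", bn, ".png"))
    png::writePNG(stack$bands[[bn]], f, dpi = NULL)
    files[[bn]] <- basename(f)
  }
  meta <- list(prefix = prefix, bands = files,
               dim = dim(stack$valid),
               valid = as.integer(stack$valid))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  invisible(meta_path)
}

#' @rdname write_band_stack
#' @param meta_path path to the JSON sidecar written by [write_band_stack()].
#' @export
read_band_stack <- function(meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dir <- dirname(meta_path)
  dm <- as.integer(meta$dim)
  bands <- lapply(meta$bands, function(f) {
    m <- png::readPNG(file.path(dir, f))
    matrix(as.numeric(m), dm[1], dm[2])
  })
  valid <- matrix(as.integer(meta$valid) == 1L, dm[1], dm[2])
  band_stack(bands, valid)
}

#' Write a canopy mask as a PNG
#'
#' Canopy pixels are white, soil black, invalid pixels mid-gray.
#'
#' @param mask a `canopy_mask`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "canopy_mask"))
  img <- matrix(0.5, nrow(mask$mask), ncol(mask$mask))
  img[mask$valid & mask$mask %in% TRUE] <- 1
  img[mask$valid & mask$mask %in% FALSE] <- 0
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img, path)
  invisible(path)
}
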