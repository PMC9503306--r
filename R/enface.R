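#' En-face slab image
#'
#' A single-channel en-face OCTA slab raster together with its physical
#' scan geometry. Pixels are stored as an integer-valued matrix in native
#' device units (row-major, origin at the top-left, matching the image file
#' layout); `bit_depth` fixes the representable range `[0, 2^bit_depth - 1]`.
#'
#' @param pixels Numeric matrix of nonnegative integer intensities.
#' @param bit_depth Either 8 or 16.
#' @param geometry A [scan_geometry()] whose grid matches `dim(pixels)`.
#' @param channel One of `"flow"`, `"structure"`, `"compensated"`.
#'
#' @return An object of class `enface_image` with fields `pixels`,
#'   `bit_depth`, `geometry`, `channel`.
#' @export
enface_image <- function(pixels, bit_depth, geometry,
                         channel = c("flow", "structure", "compensated")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  stopifnot(inherits(geometry, "scan_geometry"))
  if (nrow(pixels) != geometry$grid_rows || ncol(pixels) != geometry$grid_cols)
    stop(sprintf(
      "image is %d x %d px but geometry declares %d x %d (rows x cols)",
      nrow(pixels), ncol(pixels), geometry$grid_rows, geometry$grid_cols))
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > maxval))
    stop(sprintf("pixel intensities must lie in [0, %d]", maxval))
  if (any(pixels != round(pixels)))
    stop("pixel intensities must be integer-valued")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         geometry = geometry, channel = channel),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("enface_image [%s]: %d x %d px, %d-bit, range [%g, %g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  print(x$geometry)
  invisible(x)
}

max_intensity <- function(image) 2^image$bit_depth - 1

#' Binary flow/deficit mask
#'
#' Per-pixel classification of an en-face slab into flow (`FALSE`) and
#' deficit (`TRUE`) aligned to the source image grid.
#'
#' @param pixels Logical matrix; `TRUE` marks a flow-deficit pixel.
#' @param geometry A [scan_geometry()] matching `dim(pixels)`.
#' @param radius_px Window radius (pixels) used to produce the mask, or
#'   `NA` for masks not produced by thresholding (e.g. ground truth).
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, geometry, radius_px = NA_integer_) {
  if (!is.matrix(pixels) || !is.logical(pixels) || anyNA(pixels))
    stop("`pixels` must be a logical matrix without NA")
  stopifnot(inherits(geometry, "scan_geometry"))
  if (nrow(pixels) != geometry$grid_rows || ncol(pixels) != geometry$grid_cols)
    stop(sprintf(
      "mask is %d x %d px but geometry declares %d x %d (rows x cols)",
      nrow(pixels), ncol(pixels), geometry$grid_rows, geometry$grid_cols))
  structure(
    list(pixels = pixels, geometry = geometry,
         radius_px = as.integer(radius_px)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %.2f%% deficit (radius_px = %s)\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$pixels),
              ifelse(is.na(x$radius_px), "NA", x$radius_px)))
  invisible(x)
}

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
}

# PNG bit depth lives in byte 25 of the IHDR chunk; png::readPNG() rescales
# to [0, 1] without reporting it, so it is read from the header directly.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop(sprintf("cannot parse PNG header: '%s'", path))
  as.integer(hdr[25L])
}

read_raster <- function(path) {
  fmt <- img_format(path)
  if (fmt == "tiff") {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(x, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    v <- x
    attributes(v) <- list(dim = dim(x))   # drop TIFF metadata attributes
    list(values = v, bit_depth = as.integer(depth))
  } else {
    depth <- png_bit_depth(path)
    x <- png::readPNG(path)
    list(values = x * (2^depth - 1), bit_depth = depth)
  }
}

#' Read an en-face slab image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG raster and attaches the
#' scan geometry. Multi-channel (e.g. RGB) rasters are rejected; the
#' declared geometry must match the file dimensions exactly.
#'
#' @param path Path to a TIFF or PNG file.
#' @param geometry A [scan_geometry()] declaring the expected grid.
#' @param channel Channel tag for the image (see [enface_image()]).
#'
#' @return An [enface_image()].
#' @export
read_enface <- function(path, geometry,
                        channel = c("flow", "structure", "compensated")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s'", path))
  r <- read_raster(path)
  v <- r$values
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] == 1L) v <- v[, , 1L]
    else stop(sprintf("'%s' has %d channels; expected a single-channel image",
                      path, dim(v)[3]))
  }
  enface_image(round(v), r$bit_depth, geometry, channel)
}

#' Write an en-face slab image
#'
#' Writes pixel values losslessly at the image's bit depth. 16-bit images
#' must go to TIFF (PNG output is 8-bit only).
#'
#' @param image An [enface_image()].
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @return Invisibly, `path`.
#' @export
write_enface <- function(image, path) {
  stopifnot(inherits(image, "enface_image"))
  fmt <- img_format(path)
  maxval <- max_intensity(image)
  scaled <- image$pixels / maxval
  if (fmt == "tiff") {
    tiff::writeTIFF(scaled, path, bits.per.sample = image$bit_depth,
                    compression = "none")
  } else {
    if (image$bit_depth != 8L)
      stop("PNG output supports 8-bit images only; use TIFF for 16-bit")
    png::writePNG(scaled, path)
  }
  invisible(path)
}

#' Write a binary flow-deficit mask
#'
#' Serializes the mask as an 8-bit single-channel image with deficit pixels
#' at 0 (black) and flow pixels at 255, so deficits render as contiguous
#' black regions. The encoding round-trips losslessly through [read_mask()].
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  fmt <- img_format(path)
  scaled <- ifelse(mask$pixels, 0, 1)  # deficit -> 0, flow -> 255
  if (fmt == "tiff") {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L, compression = "none")
  } else {
    png::writePNG(scaled, path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @param geometry A [scan_geometry()] declaring the expected grid.
#' @param radius_px Radius tag to attach to the mask (see [binary_mask()]).
#' @export
read_mask <- function(path, geometry, radius_px = NA_integer_) {
  if (!file.exists(path)) stop(sprintf("cannot read mask: '%s'", path))
  r <- read_raster(path)
  v <- r$values
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] == 1L) v <- v[, , 1L]
    else stop(sprintf("'%s' is multi-channel; expected a single-channel mask",
                      path))
  }
  v <- round(v)
  if (!all(v %in% c(0, 2^r$bit_depth - 1)))
    stop(sprintf("'%s' is not a binary 0/full-scale mask image", path))
  binary_mask(v == 0, geometry, radius_px)
}
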