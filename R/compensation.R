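#' Compensation parameters
#'
#' Settings for the shadow-compensation chain applied before thresholding:
#' the structure slab is inverted, Gaussian-smoothed, and multiplied
#' pixelwise into the flow slab, so that regions darkened in the structure
#' image (RPE shadowing) are brightened in the flow image by the same
#' multiplicative factor.
#'
#' @param gaussian_sigma_px Standard deviation of the Gaussian smoothing
#'   kernel in pixels. Default 2, a common choice for this pixel pitch;
#'   the most sensitivity-relevant parameter of the chain.
#' @param output_rescale `"linear_to_full_range"` (default) maps the
#'   floating-point product affinely so its minimum hits 0 and maximum
#'   hits full scale before quantization, avoiding clipping artifacts;
#'   `"none"` clips the raw product at full scale instead.
#'
#' @return An object of class `compensation_params`.
#' @export
compensation_params <- function(gaussian_sigma_px = 2,
                                output_rescale = c("linear_to_full_range",
                                                   "none")) {
  output_rescale <- match.arg(output_rescale)
  if (!is.numeric(gaussian_sigma_px) || length(gaussian_sigma_px) != 1 ||
      !is.finite(gaussian_sigma_px) || gaussian_sigma_px < 0)
    stop("`gaussian_sigma_px` must be a single nonnegative number")
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 output_rescale = output_rescale),
            class = "compensation_params")
}

#' Invert an en-face image
#'
#' Each pixel `v` becomes `(2^bit_depth - 1) - v`; geometry, bit depth and
#' channel are unchanged. Applied to the structure slab so that shadowed
#' (dark) regions become bright multipliers.
#'
#' @param image An [enface_image()].
#' @return The inverted [enface_image()].
#' @export
invert_image <- function(image) {
  stopifnot(inherits(image, "enface_image"))
  enface_image(max_intensity(image) - image$pixels, image$bit_depth,
               image$geometry, image$channel)
}

# Separable Gaussian convolution on a plain numeric matrix with
# edge-replicated borders; kernel truncated at ceiling(3 sigma) taps per
# side and renormalized. Works in doubles; callers quantize.
smooth_matrix <- function(m, sigma_px) {
  if (sigma_px == 0) return(m)
  rad <- max(1L, as.integer(ceiling(3 * sigma_px)))
  off <- (-rad):rad
  w <- exp(-off^2 / (2 * sigma_px^2))
  w <- w / sum(w)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (t in seq_along(off)) {          # vertical pass
    rows <- pmin(pmax(seq_len(nr) + off[t], 1L), nr)
    out <- out + w[t] * m[rows, , drop = FALSE]
  }
  res <- matrix(0, nr, nc)
  for (t in seq_along(off)) {          # horizontal pass
    cols <- pmin(pmax(seq_len(nc) + off[t], 1L), nc)
    res <- res + w[t] * out[, cols, drop = FALSE]
  }
  res
}

quantize <- function(m, maxval) pmin(pmax(floor(m + 0.5), 0), maxval)

#' Gaussian smoothing of an en-face image
#'
#' Convolution with a normalized 2-D Gaussian kernel (applied separably),
#' with borders handled by edge replication. `sigma_px = 0` returns the
#' input unchanged. The result is computed in floating precision and
#' quantized back to the image bit depth by round-half-up.
#'
#' @param image An [enface_image()].
#' @param sigma_px Nonnegative kernel standard deviation in pixels.
#' @return The smoothed [enface_image()].
#' @export
gaussian_smooth <- function(image, sigma_px) {
  stopifnot(inherits(image, "enface_image"))
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || !is.finite(sigma_px) ||
      sigma_px < 0)
    stop("`sigma_px` must be a single nonnegative number")
  if (sigma_px == 0) return(image)
  sm <- smooth_matrix(image$pixels, sigma_px)
  enface_image(quantize(sm, max_intensity(image)), image$bit_depth,
               image$geometry, image$channel)
}

#' Shadow-compensate a flow slab with its structure slab
#'
#' Computes the pixelwise product of the flow image with the inverted,
#' Gaussian-smoothed structure image, in floating precision. Where the RPE
#' attenuates the OCT beam, both slabs darken together; the inverted
#' structure is then bright there, and the multiplication restores the
#' flow signal. With `output_rescale = "linear_to_full_range"` the product
#' is mapped affinely to the full intensity range before quantization
#' (a constant product maps to all zeros); with `"none"` it is clipped at
#' full scale, emulating a saturating integer multiply.
#'
#' @param flow Flow-channel [enface_image()].
#' @param structure Structure-channel [enface_image()] with identical
#'   geometry and bit depth.
#' @param params A [compensation_params()].
#' @return A compensated-channel [enface_image()].
#' @export
compensate <- function(flow, structure, params = compensation_params()) {
  stopifnot(inherits(flow, "enface_image"),
            inherits(structure, "enface_image"),
            inherits(params, "compensation_params"))
  if (!same_geometry(flow$geometry, structure$geometry))
    stop("flow and structure images have mismatched scan geometry")
  if (flow$bit_depth != structure$bit_depth)
    stop("flow and structure images have mismatched bit depth")
  maxval <- max_intensity(flow)
  mult <- smooth_matrix(max_intensity(structure) - structure$pixels,
                        params$gaussian_sigma_px)
  prod <- flow$pixels * mult
  if (params$output_rescale == "linear_to_full_range") {
    rng <- range(prod)
    out <- if (rng[2] > rng[1]) (prod - rng[1]) / (rng[2] - rng[1]) * maxval
           else matrix(0, nrow(prod), ncol(prod))
  } else {
    out <- prod
  }
  enface_image(quantize(out, maxval), flow$bit_depth, flow$geometry,
               "compensated")
}
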