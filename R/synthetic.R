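#' Specification for a synthetic flow/structure slab pair
#'
#' Parameters of the synthetic en-face generator used to validate the
#' pipeline without patient scans. The generator emulates the features the
#' analysis chain relies on: a bright, spatially correlated capillary
#' texture; dark elliptical deficit blobs with a heavy-tailed (lognormal)
#' size distribution covering a controllable fraction of the field;
#' band-shaped multiplicative shadows that darken structure and flow
#' together (the artifact compensation must undo); and additive pixel
#' noise. It does not attempt physically realistic OCTA speckle.
#'
#' The structure base level defaults to 2/3 of full scale: for a
#' multiplicative shadow of factor `a`, invert-and-multiply compensation
#' restores the flow signal exactly when the structure level is
#' `1/(1 + a)`, so with the default band attenuation of 0.5 the default
#' chain is analytically invertible (see the package vignette).
#'
#' @param geometry A [scan_geometry()]; default 6 x 6 mm on 500 x 500 px.
#' @param target_fd_fraction Intended ground-truth deficit area fraction
#'   in `[0, 1]`.
#' @param n_blobs Maximum number of deficit blobs stamped while seeking
#'   the target fraction.
#' @param blob_size_mean_px,blob_size_sd_px Mean and SD (pixels) of the
#'   lognormal blob-area distribution.
#' @param capillary_texture_scale_px Correlation length of the background
#'   flow texture, in pixels.
#' @param shadow_bands List of `c(row_start, row_end, attenuation)`
#'   triples; rows in `[row_start, row_end]` are attenuated by the factor
#'   (in `(0, 1]`), with a raised-cosine penumbra of 8 rows on each side.
#'   Applied to both flow and structure.
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param seed Integer seed; fixes all randomness of the generator.
#' @param bit_depth Output bit depth (8 or 16).
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(geometry = scan_geometry(),
                           target_fd_fraction = 0.25,
                           n_blobs = 2000L,
                           blob_size_mean_px = 150,
                           blob_size_sd_px = 300,
                           capillary_texture_scale_px = 3,
                           shadow_bands = list(),
                           noise_sd = 2,
                           seed = 1L,
                           bit_depth = 8L) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (target_fd_fraction < 0 || target_fd_fraction > 1)
    stop("`target_fd_fraction` must lie in [0, 1]")
  for (b in shadow_bands) {
    if (length(b) != 3 || b[3] <= 0 || b[3] > 1)
      stop("each shadow band is c(row_start, row_end, attenuation in (0, 1])")
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  structure(
    list(geometry = geometry, target_fd_fraction = target_fd_fraction,
         n_blobs = as.integer(n_blobs),
         blob_size_mean_px = blob_size_mean_px,
         blob_size_sd_px = blob_size_sd_px,
         capillary_texture_scale_px = capillary_texture_scale_px,
         shadow_bands = shadow_bands, noise_sd = noise_sd,
         seed = as.integer(seed), bit_depth = as.integer(bit_depth)),
    class = "synthetic_spec"
  )
}

# Run code under a private RNG stream: the global .Random.seed is saved
# and restored, so generation never perturbs (or depends on) caller RNG
# state beyond the spec's own seed.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Smoothed standardized Gaussian field with given correlation length.
correlated_field <- function(nr, nc, scale_px) {
  z <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), scale_px)
  (z - mean(z)) / stats::sd(z)
}

# Stamp one filled ellipse of the requested pixel area at a random centre,
# eccentricity and orientation; returns the updated logical mask.
stamp_ellipse <- function(mask, area_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  rho <- stats::runif(1, 0.4, 1)            # axis ratio b/a
  a <- sqrt(area_px / (pi * rho))
  b <- rho * a
  theta <- stats::runif(1, 0, pi)
  cy <- stats::runif(1, 1, nr)
  cx <- stats::runif(1, 1, nc)
  ry <- pmax(1L, floor(cy - a)):pmin(nr, ceiling(cy + a))
  rx <- pmax(1L, floor(cx - a)):pmin(nc, ceiling(cx + a))
  dy <- outer(ry - cy, rep(1, length(rx)))
  dx <- outer(rep(1, length(ry)), rx - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[ry, rx] <- mask[ry, rx] | inside
  mask
}

# Per-row attenuation profile for the configured shadow bands, with a
# raised-cosine penumbra so the shadow edge is not a hard step.
shadow_profile <- function(nr, bands, ramp = 8L) {
  prof <- rep(1, nr)
  for (b in bands) {
    r0 <- b[1]; r1 <- b[2]; a <- b[3]
    for (r in seq_len(nr)) {
      if (r >= r0 && r <= r1) f <- a
      else if (r >= r0 - ramp && r < r0)
        f <- 1 - (1 - a) * (1 + cos(pi * (r0 - r) / ramp)) / 2
      else if (r > r1 && r <= r1 + ramp)
        f <- 1 - (1 - a) * (1 + cos(pi * (r - r1) / ramp)) / 2
      else next
      prof[r] <- min(prof[r], f)
    }
  }
  prof
}

#' Generate a synthetic flow/structure pair with known ground truth
#'
#' Builds the correlated capillary background, stamps elliptical deficit
#' blobs until the ground-truth deficit fraction is within 0.01 of
#' `target_fd_fraction` (or `n_blobs` is exhausted, in which case the
#' returned truth mask carries a `target_unreached` attribute rather than
#' failing silently), applies the configured shadow bands multiplicatively
#' to both slabs, and adds pixel noise. The truth mask is the pre-shadow,
#' pre-noise deficit mask. Identical specs (including seed) produce
#' bit-identical triplets.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `flow` and `structure`
#'   ([enface_image()]s) and `truth` (a [binary_mask()]).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$geometry
  nr <- g$grid_rows; nc <- g$grid_cols
  maxval <- 2^spec$bit_depth - 1
  with_rng_seed(spec$seed, {
    # background capillary texture in normalized units: bright, mildly
    # fluctuating (mean 0.78, sd 0.045 of full scale)
    flow_n <- 0.78 + 0.045 * correlated_field(nr, nc,
                                              spec$capillary_texture_scale_px)
    flow_n <- pmin(pmax(flow_n, 0.5), 0.98)

    # deficit blobs: lognormal areas, stamped until the target fraction
    truth <- matrix(FALSE, nr, nc)
    total <- nr * nc
    unreached <- FALSE
    if (spec$target_fd_fraction > 0) {
      m <- spec$blob_size_mean_px; s <- spec$blob_size_sd_px
      mlog <- log(m^2 / sqrt(m^2 + s^2))
      slog <- sqrt(log(1 + s^2 / m^2))
      placed <- 0L
      while (spec$target_fd_fraction - sum(truth) / total > 0.01 &&
             placed < spec$n_blobs) {
        area <- stats::rlnorm(1, mlog, slog)
        needed <- (spec$target_fd_fraction - sum(truth) / total) * total
        if (area > needed) area <- needed     # cap the last blob: no overshoot
        truth <- stamp_ellipse(truth, max(area, 1))
        placed <- placed + 1L
      }
      unreached <- spec$target_fd_fraction - sum(truth) / total > 0.01
    }
    flow_n[truth] <- 0.05                     # suppressed toward background floor

    # structure slab: level 2/3 so the default 0.5 shadow is exactly
    # invertible by the compensation chain, plus mild correlated texture
    struct_n <- 2 / 3 + 0.01 * correlated_field(nr, nc,
                                                spec$capillary_texture_scale_px)

    # shadow bands darken structure and flow by the same factor
    prof <- shadow_profile(nr, spec$shadow_bands)
    flow_n <- flow_n * prof
    struct_n <- struct_n * prof

    # pixel noise, clip, quantize
    noisy <- function(x) {
      v <- x * maxval + stats::rnorm(length(x), sd = spec$noise_sd)
      matrix(quantize(v, maxval), nr, nc)
    }
    truth_mask <- binary_mask(truth, g)
    if (unreached) attr(truth_mask, "target_unreached") <- TRUE
    list(flow = enface_image(noisy(flow_n), spec$bit_depth, g, "flow"),
         structure = enface_image(noisy(struct_n), spec$bit_depth, g,
                                  "structure"),
         truth = truth_mask)
  })
}

#' Run the full quantification chain on a synthetic pair
#'
#' Generates a synthetic pair, runs compensation (optionally skipped to
#' measure the benefit of the compensation stage), Phansalkar
#' thresholding and component quantification, and returns the measured
#' report next to the ground-truth deficit percentage.
#'
#' @param spec A [synthetic_spec()].
#' @param thresh A [threshold_params()]; default radius 8.
#' @param comp A [compensation_params()], or `NULL` to threshold the raw
#'   flow slab without compensation.
#' @param connectivity,min_size_px Passed to [quantify_fd()].
#' @return A list with `measured` (an [fd_report()]) and `truth_fraction`
#'   (ground-truth deficit percentage, 0-100 scale).
#' @export
recovery_experiment <- function(spec, thresh = threshold_params(8),
                                comp = compensation_params(),
                                connectivity = 8, min_size_px = 0) {
  pair <- generate_pair(spec)
  img <- if (is.null(comp)) pair$flow
         else compensate(pair$flow, pair$structure, comp)
  mask <- phansalkar_threshold(img, thresh)
  list(measured = quantify_fd(mask, connectivity, min_size_px),
       truth_fraction = 100 * mean(pair$truth$pixels))
}
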