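# Connected components of the deficit phase. Deficit pixels become graph
# vertices; edges join pixels adjacent under the chosen connectivity; the
# components of that graph are the flow deficits. igraph does the union
# find; only the (vectorized) edge construction lives here.
deficit_components <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8")
  px <- mask$pixels
  nr <- nrow(px)
  idx <- which(px)
  if (length(idx) == 0L)
    return(list(idx = integer(0), membership = integer(0), sizes = integer(0)))
  id <- integer(length(px))
  id[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  nc <- ncol(px)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- lapply(shifts, function(s) {
    ok <- row + s[1] >= 1L & row + s[1] <= nr &
          col + s[2] >= 1L & col + s[2] <= nc
    nbr <- idx[ok] + s[1] + s[2] * nr
    both <- px[nbr]
    cbind(id[idx[ok][both]], id[nbr[both]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  list(idx = idx, membership = comp$membership,
       sizes = as.integer(comp$csize))
}

#' Label connected flow-deficit components
#'
#' Partitions the deficit pixels of a binary mask into maximal connected
#' components ("contiguous black pixels") and returns their pixel counts,
#' sorted in decreasing order. With `connectivity = 8` (default),
#' diagonally touching deficit pixels belong to the same component; with
#' `connectivity = 4` only edge-adjacent pixels do.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8.
#' @return Integer vector of component pixel counts, sorted decreasing;
#'   empty when the mask contains no deficit pixels.
#' @export
label_components <- function(mask, connectivity = 8) {
  sort(deficit_components(mask, connectivity)$sizes, decreasing = TRUE)
}

#' Quantify flow deficits in a binary mask
#'
#' Computes the four per-eye flow-deficit biomarkers from a deficit mask:
#' `fd_percent` (deficit pixels over all pixels, as a percentage of the
#' imaged field), `fd_count` (number of connected components),
#' `fd_mean_size_um2` (mean component area) and `fd_total_area_mm2`
#' (summed deficit area), using the physical pixel area from the mask's
#' scan geometry. Components smaller than `min_size_px` are dropped before
#' any metric is computed; the default 0 applies no size filter.
#' Components touching the image border count like any other.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (see [label_components()]).
#' @param min_size_px Drop components with fewer pixels than this.
#' @param eye_id,group Optional identifiers carried into the report.
#' @return An [fd_report()].
#' @examples
#' g <- scan_geometry(6, 6, 10, 10)
#' m <- binary_mask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10), g)
#' quantify_fd(m)
#' @export
quantify_fd <- function(mask, connectivity = 8, min_size_px = 0,
                        eye_id = NA_character_, group = NA_character_) {
  comp <- deficit_components(mask, connectivity)
  keep <- comp$sizes >= min_size_px
  sizes <- comp$sizes[keep]
  npx_total <- length(mask$pixels)
  npx_deficit <- sum(sizes)
  px_area <- pixel_area_um2(mask$geometry)
  n_comp <- length(sizes)
  fd_report(
    fd_percent = 100 * npx_deficit / npx_total,
    fd_count = n_comp,
    fd_mean_size_um2 = if (n_comp > 0) mean(sizes) * px_area else 0,
    fd_total_area_mm2 = npx_deficit * px_area / 1e6,
    radius_px = mask$radius_px,
    geometry = mask$geometry,
    eye_id = eye_id, group = group
  )
}

#' Apply a minimum-size filter to a deficit mask
#'
#' Returns the mask with all connected deficit components smaller than
#' `min_size_px` relabelled as flow. Useful for persisting the exact mask
#' a filtered [quantify_fd()] call measured.
#'
#' @inheritParams quantify_fd
#' @return A [binary_mask()].
#' @export
filter_small_components <- function(mask, connectivity = 8, min_size_px = 0) {
  if (min_size_px <= 0) return(mask)
  comp <- deficit_components(mask, connectivity)
  drop <- comp$idx[comp$sizes[comp$membership] < min_size_px]
  px <- mask$pixels
  px[drop] <- FALSE
  binary_mask(px, mask$geometry, mask$radius_px)
}
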