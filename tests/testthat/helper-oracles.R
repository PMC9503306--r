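# Brute-force reference implementations, independent of the package's
# vectorized/compiled code paths: every oracle extracts each pixel's
# window explicitly and recomputes the statistic from scratch.

# Per-pixel Phansalkar labels with edge-replicated borders.
oracle_phansalkar <- function(pixels, maxval, radius, k = 0.25, r = 0.5,
                              p = 2, q = 10, circular = TRUE) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  out <- matrix(NA, nr, nc)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  if (circular) offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax(i + offs$dy, 1), nr)
      jj <- pmin(pmax(j + offs$dx, 1), nc)
      w <- pixels[cbind(ii, jj)] / maxval
      mu <- mean(w)
      sdev <- sqrt(mean(w^2) - mu^2)
      thr <- mu * (1 + p * exp(-q * mu) + k * (sdev / r - 1))
      out[i, j] <- pixels[i, j] / maxval < thr
    }
  }
  out
}

# Direct (non-separable) 2-D Gaussian convolution at one pixel,
# edge-replicated, kernel truncated at ceiling(3 sigma).
oracle_gauss_at <- function(pixels, i, j, sigma) {
  rad <- max(1, ceiling(3 * sigma))
  nr <- nrow(pixels); nc <- ncol(pixels)
  acc <- 0; wsum <- 0
  for (dy in -rad:rad) {
    for (dx in -rad:rad) {
      w <- exp(-(dy^2 + dx^2) / (2 * sigma^2))
      ii <- min(max(i + dy, 1), nr)
      jj <- min(max(j + dx, 1), nc)
      acc <- acc + w * pixels[ii, jj]
      wsum <- wsum + w
    }
  }
  acc / wsum
}

# Flood-fill component sizes on a logical matrix (queue-based BFS).
oracle_components <- function(px, connectivity = 8) {
  nr <- nrow(px); nc <- ncol(px)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  sizes <- integer(0)
  for (start in which(px)) {
    si <- ((start - 1) %% nr) + 1; sj <- ((start - 1) %/% nr) + 1
    if (seen[si, sj]) next
    queue <- list(c(si, sj)); seen[si, sj] <- TRUE; n <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; n <- n + 1L
      for (t in seq_len(nrow(nbr))) {
        ni <- cur[1] + nbr[t, 1]; nj <- cur[2] + nbr[t, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            px[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sort(sizes, decreasing = TRUE)
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled ranks to group A (no ties assumed).
oracle_mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(ix) sum(ranks[ix]) - na * (na + 1) / 2)
  mid <- na * nb / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

rand_image <- function(nr, nc, maxval = 255, geometry = NULL) {
  if (is.null(geometry)) geometry <- scan_geometry(6, 6, nc, nr)
  px <- matrix(sample(0:maxval, nr * nc, replace = TRUE), nr, nc)
  enface_image(px, if (maxval > 255) 16L else 8L, geometry, "flow")
}

rand_mask <- function(nr, nc, p_deficit = 0.4) {
  g <- scan_geometry(6, 6, nc, nr)
  binary_mask(matrix(stats::runif(nr * nc) < p_deficit, nr, nc), g)
}
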