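#' Gradient segmentation settings
#'
#' @param gradient_sigma_mm Gaussian smoothing scale (mm) used before
#'   gradient estimation; default `NULL` means one voxel spacing (the
#'   smallest spacing component).
#' @param min_seed_suv Minimum SUV required at the seed voxel (default 2.5);
#'   seeds below it are rejected as not lying in an avid lesion.
#' @param max_region_ml Safety cap on the delineated region volume (mL).
#' @param n_directions Number of quasi-uniform ray directions on the sphere.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(gradient_sigma_mm = NULL, min_seed_suv = 2.5,
                                max_region_ml = 200, n_directions = 128) {
  if (!is.null(gradient_sigma_mm) && gradient_sigma_mm <= 0)
    stopf("gradient_sigma_mm must be positive")
  if (max_region_ml <= 0) stopf("max_region_ml must be positive")
  structure(list(gradient_sigma_mm = gradient_sigma_mm,
                 min_seed_suv = min_seed_suv,
                 max_region_ml = max_region_ml,
                 n_directions = as.integer(n_directions)),
            class = "segmentation_config")
}

# Separable 3-D Gaussian smoothing with edge replication. sigma_vox is
# per-axis in voxel units; an axis with sigma < 0.2 voxels is skipped.
gaussian_smooth3 <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 0.2) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    sm <- stats::filter(padded, k, sides = 2)
    sm <- sm[(r + 1L):(r + d[1]), , drop = FALSE]
    arr <- aperm(array(as.numeric(sm), dim = d), order(perm))
  }
  arr
}

# Trilinear interpolation of a 3-D array at continuous voxel coordinates
# (1-based). pts is an n x 3 matrix; coordinates are clamped to the grid.
interp3 <- function(arr, pts) {
  d <- dim(arr)
  cl <- function(x, n) pmin(pmax(x, 1), n)
  x <- cl(pts[, 1], d[1]); y <- cl(pts[, 2], d[2]); z <- cl(pts[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  x0 <- pmax(x0, 1L); y0 <- pmax(y0, 1L); z0 <- pmax(z0, 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);         v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0);     v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1);     v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# 26-connected component of a logical array containing a seed voxel.
connected_component <- function(fg, seed) {
  d <- dim(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  if (!fg[seed[1], seed[2], seed[3]]) return(visited)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                   drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- unique(nb[ok, , drop = FALSE])
    keep <- fg[nb] & !visited[nb]
    nb <- nb[keep, , drop = FALSE]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Gradient-based semi-automated tumour delineation
#'
#' A documented stand-in for commercial gradient-edge PET delineation
#' tools: the volume is Gaussian-smoothed, rays are cast from the lesion's
#' intensity-weighted centroid in quasi-uniform directions, and along each
#' ray the boundary is placed at the maximum of the radial SUV gradient
#' magnitude. The enclosed voxels form the mask, restricted to the
#' 26-connected component containing the seed. Because only the location of
#' the gradient maximum is used, the result is invariant to monotone
#' rescaling of image contrast.
#'
#' @param volume An [suv_volume()].
#' @param seed Integer voxel index triple (1-based) inside the lesion.
#' @param config A [segmentation_config()].
#' @return An [roi_mask()].
#' @export
gradient_segment <- function(volume, seed, config = segmentation_config()) {
  d <- dim(volume$voxels)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stopf("seed voxel %s outside volume", paste(seed, collapse = ","))
  if (volume$voxels[seed[1], seed[2], seed[3]] < config$min_seed_suv)
    stopf("seed not in avid lesion: SUV %.2f < min_seed_suv %.2f",
          volume$voxels[seed[1], seed[2], seed[3]], config$min_seed_suv)

  sigma_mm <- config$gradient_sigma_mm %||% min(volume$spacing)
  sm <- gaussian_smooth3(volume$voxels, sigma_mm / volume$spacing)
  spc <- volume$spacing
  r_cap <- min((3 * config$max_region_ml * 1000 / (4 * pi))^(1 / 3),
               max(d * spc) / 2)
  step <- 0.5 * min(spc)
  dirs <- fibonacci_sphere(config$n_directions)
  rng <- diff(range(sm))
  if (rng <= 1e-12 * max(abs(sm), 1))
    stopf("no gradient maximum: image is flat")

  centroid <- (seed - 1) * spc   # physical mm, voxel (1,1,1) at 0
  for (iter in 1:3) {
    radii <- seq(step, r_cap, by = step)
    # sample smoothed SUV along every ray (n_dir x n_radii)
    pts <- dirs[rep(seq_len(nrow(dirs)), each = length(radii)), ] *
      rep(radii, nrow(dirs))
    pts <- sweep(pts, 2, centroid, "+")
    vox <- sweep(pts, 2, spc, "/") + 1   # continuous voxel coords
    f <- matrix(interp3(sm, vox), nrow = length(radii))
    g <- abs(apply(f, 2, function(col) {
      c(NA, (col[-(1:2)] - col[1:(length(col) - 2)]) / (2 * step), NA)
    }))
    edge_r <- rep(NA_real_, ncol(g))
    gmax <- apply(g, 2, function(col) max(col, na.rm = TRUE))
    found <- gmax > 1e-6 * rng / min(spc)
    for (jj in which(found))
      edge_r[jj] <- radii[which.max(g[, jj])]
    if (!any(found)) stopf("no gradient maximum found before region cap")
    edge_r[!found] <- stats::median(edge_r[found])

    # voxels whose centre lies inside the edge surface
    idx <- which(array(TRUE, dim = d))
    coords <- cbind((arrayInd(idx, d) - 1) %*% diag(spc))
    rel <- sweep(coords, 2, centroid, "-")
    r <- sqrt(rowSums(rel^2))
    cand <- r <= max(edge_r) + 1e-9
    inside <- logical(length(idx))
    inside[r < step] <- TRUE
    cc <- which(cand & r >= step)
    if (length(cc)) {
      dots <- (rel[cc, , drop = FALSE] / r[cc]) %*% t(dirs)
      nearest <- max.col(dots)
      inside[cc] <- r[cc] <= edge_r[nearest]
    }
    fg <- array(inside, dim = d)
    fg[seed[1], seed[2], seed[3]] <- TRUE
    fg <- connected_component(fg, seed)
    w <- volume$voxels[fg]
    new_centroid <- colSums((arrayInd(which(fg), d) - 1) %*% diag(spc) * w) /
      sum(w)
    if (sqrt(sum((new_centroid - centroid)^2)) < 0.25 * min(spc)) {
      centroid <- new_centroid
      break
    }
    centroid <- new_centroid
  }

  vol_ml <- sum(fg) * prod(spc) / 1000
  if (vol_ml > config$max_region_ml)
    stopf("delineated region (%.1f mL) exceeds max_region_ml (%.1f mL)",
          vol_ml, config$max_region_ml)
  roi_mask(fg, reference = volume)
}
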