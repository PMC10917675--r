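#' Scalar volumes in world (template) millimetre space
#'
#' A `voxel_volume` is a 3D scalar grid plus a 4x4 affine mapping 0-based
#' voxel indices to world mm coordinates (NIfTI convention: a voxel's centre
#' maps through the affine). All package statistics run in double precision;
#' files are written as float32.
#'
#' @param data numeric 3D array; non-finite values are rejected (use
#'   [load_volume()] for load-time sanitisation of NaN backgrounds).
#' @param affine 4x4 numeric matrix, voxel-index -> world mm; must be
#'   invertible with last row (0,0,0,1).
#' @param units one of `"V_per_m"`, `"correlation"`, `"count"`, `"unitless"`.
#' @return An object of class `voxel_volume` with fields `data`, `affine`,
#'   `units`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), diag(4))
#' dim(v$data)
#' @export
voxel_volume <- function(data, affine, units = "unitless") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("voxel_volume requires finite values only (sanitise NaN to 0 first)")
  affine <- check_affine(affine)
  units <- match.arg(units, c("V_per_m", "correlation", "count", "unitless"))
  structure(list(data = data, affine = affine, units = units),
            class = "voxel_volume")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  storage.mode(affine) <- "double"
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine last row must be (0,0,0,1)")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is singular")
  affine
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_sizes(x$affine)
  cat(sprintf("<voxel_volume> %dx%dx%d voxels, %.3gx%.3gx%.3g mm, units=%s\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], x$units))
  invisible(x)
}

#' Voxel sizes (mm) implied by an affine
#' @param affine 4x4 affine matrix.
#' @return length-3 numeric, the column norms of the 3x3 block.
#' @export
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Convert between 0-based voxel indices and world mm
#'
#' `voxel_to_world` maps continuous 0-based voxel indices through the affine;
#' `world_to_voxel` applies the inverse. Round-trips are identity to 1e-9.
#'
#' @param vox,world n x 3 matrices (or length-3 vectors) of coordinates.
#' @param affine 4x4 affine.
#' @return n x 3 matrix of transformed coordinates.
#' @export
voxel_to_world <- function(vox, affine) {
  vox <- rbind3(vox)
  t(affine[1:3, 1:3] %*% t(vox) + affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(world, affine) {
  world <- rbind3(world)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(world) + inv[1:3, 4])
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Trilinear interpolation of a volume at world-mm points
#'
#' Points outside the grid contribute 0 (E-fields are compactly supported
#' around the electrode, so out-of-grid means "no stimulation"). At the grid
#' boundary the missing corners contribute 0, giving a smooth fade-out.
#'
#' @param volume a [voxel_volume()].
#' @param world n x 3 matrix of world mm points.
#' @return numeric vector of n interpolated values.
#' @export
sample_volume <- function(volume, world) {
  ijk <- world_to_voxel(world, volume$affine)
  trilinear(volume$data, ijk)
}

# ijk: n x 3 continuous 0-based voxel coordinates
trilinear <- function(data, ijk) {
  d <- dim(data)
  n <- nrow(ijk)
  i0 <- floor(ijk)
  f <- ijk - i0
  acc <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- i0[, 1] + dx; cj <- i0[, 2] + dy; ck <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ci >= 0 & ci <= d[1] - 1 & cj >= 0 & cj <= d[2] - 1 &
          ck >= 0 & ck <= d[3] - 1 & w > 0
    if (any(ok))
      acc[ok] <- acc[ok] + w[ok] *
        data[cbind(ci[ok] + 1, cj[ok] + 1, ck[ok] + 1)]
  }
  acc
}

#' Resample a volume onto another volume's grid
#'
#' Trilinear resampling at the target grid's voxel centres; voxels falling
#' outside the source grid become 0.
#'
#' @param volume source [voxel_volume()].
#' @param grid target [voxel_volume()] (only its shape and affine are used).
#' @return a [voxel_volume()] on the target grid, keeping the source units.
#' @export
resample_volume <- function(volume, grid) {
  centres <- grid_world_centres(grid)
  vals <- sample_volume(volume, centres)
  voxel_volume(array(vals, dim(grid$data)), grid$affine, volume$units)
}

# world coordinates of every voxel centre, in array (column-major) order;
# memoised per (shape, affine) since mapping loops query the same grid often
.centre_cache <- new.env(parent = emptyenv())

grid_world_centres <- function(grid) {
  d <- dim(grid$data)
  key <- paste(c(d, signif(grid$affine, 12)), collapse = "|")
  hit <- .centre_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  out <- voxel_to_world(idx, grid$affine)
  if (length(ls(.centre_cache)) > 32) rm(list = ls(.centre_cache),
                                         envir = .centre_cache)
  .centre_cache[[key]] <- out
  out
}

# precompute trilinear gather indices/weights for a fixed set of points on a
# fixed grid, so many volumes on that grid can be sampled by 8 gathers each
trilinear_prep <- function(dim3, affine, world) {
  ijk <- world_to_voxel(world, affine)
  n <- nrow(ijk)
  i0 <- floor(ijk)
  f <- ijk - i0
  idx <- matrix(1L, n, 8)
  w <- matrix(0, n, 8)
  col <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    col <- col + 1L
    ci <- i0[, 1] + dx; cj <- i0[, 2] + dy; ck <- i0[, 3] + dz
    wt <- (if (dx) f[, 1] else 1 - f[, 1]) *
          (if (dy) f[, 2] else 1 - f[, 2]) *
          (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ci >= 0 & ci <= dim3[1] - 1 & cj >= 0 & cj <= dim3[2] - 1 &
          ck >= 0 & ck <= dim3[3] - 1
    w[, col] <- ifelse(ok, wt, 0)
    lin <- 1L + ci + dim3[1] * (cj + dim3[2] * ck)
    idx[, col] <- ifelse(ok, as.integer(lin), 1L)
  }
  list(idx = idx, w = w, n = n)
}

sample_with_prep <- function(data, prep) {
  rowSums(matrix(data[prep$idx], prep$n, 8) * prep$w)
}

#' Mirror a volume across the template midline (x = 0)
#'
#' Resamples the source volume at x-negated world coordinates of the target
#' grid, i.e. a sign flip of the world x axis about the inter-hemispheric
#' midline. Used to pool left and right hemisphere stimulation fields onto a
#' single hemisphere.
#'
#' @param volume source [voxel_volume()].
#' @param grid target grid (defaults to the source's own grid).
#' @return mirrored [voxel_volume()] on `grid`.
#' @export
mirror_volume <- function(volume, grid = volume) {
  # exact fast path: an axis-aligned grid whose x centres are symmetric
  # about 0 mirrors by reversing the first array axis
  A <- volume$affine
  if (same_grid(volume, grid) &&
      max(abs(A[1:3, 1:3] - diag(diag(A[1:3, 1:3])))) < 1e-12 &&
      abs(2 * A[1, 4] + A[1, 1] * (dim(volume$data)[1] - 1)) < 1e-9) {
    d1 <- dim(volume$data)[1]
    return(voxel_volume(volume$data[d1:1, , , drop = FALSE], A,
                        volume$units))
  }
  centres <- grid_world_centres(grid)
  centres <- cbind(-centres[, 1], centres[, 2:3])
  vals <- sample_volume(volume, centres)
  voxel_volume(array(vals, dim(grid$data)), grid$affine, volume$units)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Separable Gaussian smoothing of a volume
#'
#' Smooths with a Gaussian kernel of the given full width at half maximum
#' (mm), honouring anisotropic voxel sizes (per-axis sigma in voxels equals
#' `fwhm / (2 * sqrt(2 * log(2))) / voxel_size`). The kernel is normalised, so
#' total mass is preserved up to boundary truncation; `fwhm_mm = 0` is the
#' identity.
#'
#' @param volume a [voxel_volume()].
#' @param fwhm_mm kernel FWHM in mm, `>= 0`.
#' @return smoothed [voxel_volume()] with the same affine and units.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || fwhm_mm < 0)
    stop("fwhm_mm must be a single non-negative length in mm")
  if (fwhm_mm == 0) return(volume)
  vs <- voxel_sizes(volume$affine)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  x <- volume$data
  for (ax in 1:3) x <- convolve_axis(x, gauss_kernel(sig[ax]), ax)
  voxel_volume(x, volume$affine, volume$units)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# zero-padded 1D convolution along axis `ax` of a 3D array
convolve_axis <- function(x, k, ax) {
  d <- dim(x)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  n <- dp[1]
  r <- (length(k) - 1L) / 2L
  band <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    rows <- seq_len(n)
    cols <- rows + off
    ok <- cols >= 1 & cols <= n
    band[cbind(rows[ok], cols[ok])] <- band[cbind(rows[ok], cols[ok])] + k[j]
  }
  out <- band %*% m
  dim(out) <- dp
  aperm(out, order(perm))
}
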