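#' Resample a polyline at a maximum arclength spacing
#'
#' Subdivides every segment into equal pieces no longer than `step_mm`; the
#' original vertices are always retained, so sharp features and true peaks at
#' vertices are never lost.
#'
#' @param polyline n x 3 matrix of world-mm points, n >= 2.
#' @param step_mm maximum spacing between consecutive samples, > 0.
#' @return m x 3 matrix of resampled points (m >= n).
#' @export
resample_polyline <- function(polyline, step_mm = 0.5) {
  polyline <- rbind3(polyline)
  if (nrow(polyline) < 2L) stop("polyline must have at least 2 points")
  if (!is.numeric(step_mm) || step_mm <= 0) stop("step_mm must be > 0")
  pieces <- vector("list", nrow(polyline) - 1L)
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]; b <- polyline[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nsub <- max(1L, ceiling(len / step_mm))
    tt <- seq(0, 1, length.out = nsub + 1L)[-(nsub + 1L)]
    pieces[[s]] <- outer(1 - tt, a) + outer(tt, b)
  }
  rbind(do.call(rbind, pieces), polyline[nrow(polyline), , drop = FALSE])
}

#' Sample a volume along a streamline
#'
#' Resamples the polyline at arclength spacing `step_mm` (vertices retained)
#' and evaluates the volume by trilinear interpolation at every sample point.
#' Points outside the grid contribute 0. The maximum of the returned values is
#' the "peak magnitude" used by fiber filtering.
#'
#' @param volume a [voxel_volume()].
#' @param polyline n x 3 matrix of world-mm points, n >= 2.
#' @param step_mm sampling step in mm (default 0.5, below typical voxel size
#'   so that peaks are not missed).
#' @return numeric vector of sampled values.
#' @export
sample_along_streamline <- function(volume, polyline, step_mm = 0.5) {
  pts <- resample_polyline(polyline, step_mm)
  sample_volume(volume, pts)
}

#' Streamline density map
#'
#' Rasterises a streamline set onto a grid: each voxel counts the number of
#' streamlines with at least one sample point inside it (a streamline counts
#' at most once per voxel, so the map is a visitation count, not a point
#' count). Streamlines are resampled at half the smallest voxel size so thin
#' diagonal passages are not skipped.
#'
#' @param set a [streamline_set()].
#' @param grid a [voxel_volume()] template defining shape and affine.
#' @return a [voxel_volume()] of counts on the template grid.
#' @export
streamline_density_map <- function(set, grid) {
  stopifnot(inherits(set, "streamline_set"), inherits(grid, "voxel_volume"))
  d <- dim(grid$data)
  counts <- array(0, d)
  step <- min(voxel_sizes(grid$affine)) / 2
  for (p in set$streamlines) {
    pts <- resample_polyline(p, step)
    ijk <- round(world_to_voxel(pts, grid$affine))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
          ijk[, 2] >= 0 & ijk[, 2] < d[2] &
          ijk[, 3] >= 0 & ijk[, 3] < d[3]
    if (!any(ok)) next
    lin <- unique(ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])) + 1
    counts[lin] <- counts[lin] + 1
  }
  voxel_volume(counts, grid$affine, units = "count")
}
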