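# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops and base R only, so they can certify the
# implementation rather than mirror it.

# per-point trilinear interpolation, one point at a time
oracle_trilinear <- function(data, ijk_row) {
  d <- dim(data)
  i0 <- floor(ijk_row)
  f <- ijk_row - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    c3 <- i0 + c(dx, dy, dz)
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    if (all(c3 >= 0) && all(c3 <= d - 1))
      acc <- acc + w * data[c3[1] + 1, c3[2] + 1, c3[3] + 1]
  }
  acc
}

oracle_sample_volume <- function(volume, world) {
  inv <- solve(volume$affine)
  vapply(seq_len(nrow(world)), function(r) {
    ijk <- (inv %*% c(world[r, ], 1))[1:3]
    oracle_trilinear(volume$data, ijk)
  }, 0)
}

# Spearman rho/p by ranking then base cor.test (Pearson on ranks)
oracle_spearman <- function(x, y) {
  ct <- stats::cor.test(rank(x), rank(y), method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# voxel-loop sweet spot score for one patient
oracle_sweet_score <- function(efields, r_map_data, mask_data) {
  vox <- which(mask_data == 1, arr.ind = TRUE)
  hemi <- vapply(efields, function(v) {
    tot <- 0
    for (r in seq_len(nrow(vox))) {
      i <- vox[r, 1]; j <- vox[r, 2]; k <- vox[r, 3]
      tot <- tot + v$data[i, j, k] * r_map_data[i, j, k]
    }
    tot / nrow(vox)
  }, 0)
  mean(hemi)
}

# sort-and-sum weighted peak-fraction score for one field
oracle_fiber_score_field <- function(rvals, peaks, frac) {
  w <- c()
  for (s in seq_along(rvals)) if (peaks[s] > 0) w <- c(w, rvals[s] * peaks[s])
  if (length(w) == 0) return(0)
  keep <- max(1, ceiling(frac * length(w)))
  sum(sort(w, decreasing = TRUE)[1:keep])
}

# rasterisation oracle: visit count per voxel from densely resampled points
oracle_density <- function(set, grid, step = NULL) {
  d <- dim(grid$data)
  if (is.null(step)) step <- min(voxel_sizes(grid$affine)) / 2
  counts <- array(0, d)
  for (p in set$streamlines) {
    pts <- resample_polyline(p, step)
    seen <- character(0)
    for (r in seq_len(nrow(pts))) {
      ijk <- round(world_to_voxel(pts[r, , drop = FALSE], grid$affine))
      if (all(ijk >= 0) && all(ijk < d)) {
        key <- paste(ijk, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          counts[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <-
            counts[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] + 1
        }
      }
    }
  }
  counts
}

# Mann-Whitney ranking AUC: P(score_pos > score_neg) + 0.5 P(equal)
rank_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
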