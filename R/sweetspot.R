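#' Coverage mask over a set of E-fields
#'
#' Restricts group mapping to voxels covered by enough stimulation fields: a
#' voxel is kept iff at least `coverage_fraction` of the supplied E-fields
#' exceed `magnitude_threshold` there ("at least", so the boundary case is
#' inclusive). This avoids unrepresentative correlations carried by a handful
#' of fields.
#'
#' @param efields list of [voxel_volume()]s on one common grid.
#' @param magnitude_threshold E-field magnitude threshold in V/m
#'   (default 200, the conventional axonal activation estimate).
#' @param coverage_fraction required fraction of fields above threshold,
#'   in (0, 1] (default 0.5).
#' @return a 0/1 [voxel_volume()] (units `count`) on the common grid.
#' @export
coverage_mask <- function(efields, magnitude_threshold = 200,
                          coverage_fraction = 0.5) {
  if (!is.list(efields) || length(efields) == 0L)
    stop("need a non-empty list of E-fields")
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  check_common_grid(efields)
  counts <- Reduce(`+`, lapply(efields,
                               function(v) (v$data > magnitude_threshold) + 0))
  mask <- (counts / length(efields) >= coverage_fraction) + 0
  voxel_volume(mask, efields[[1]]$affine, units = "count")
}

check_common_grid <- function(efields) {
  ref <- efields[[1]]
  for (v in efields)
    if (!same_grid(v, ref))
      stop("E-fields are not on a common grid; resample first ",
           "(see resample_volume)")
  invisible(ref)
}

#' Fit a voxel-wise sweet-spot model
#'
#' Mass-univariate stimulation-outcome mapping: within the coverage mask,
#' each voxel's vector of E-field magnitudes across observations is Spearman
#' rank-correlated with percent clinical improvements. Positive-peak voxels
#' form the "sweet spot" (stimulation there tracks benefit), negative peaks
#' the "sour spot". The observation unit is the E-field: each hemisphere's
#' field is paired with its patient's improvement, pooled across the cohort
#' (set `mirror` to fold one hemisphere onto the other for a unilateral
#' region of interest, or `aggregate = "patient"` to use per-patient voxel-wise
#' maxima instead).
#'
#' The per-voxel p-map is descriptive only: no multiple-testing correction is
#' applied, by design — model validity is established by cross-validation and
#' permutation inference, not voxel-wise significance.
#'
#' @param x a [cohort()] whose records carry E-fields, or a plain list of
#'   [voxel_volume()]s (then `improvement` must be given per volume).
#' @param improvement percent improvements, one per E-field observation;
#'   ignored when `x` is a cohort.
#' @param magnitude_threshold,coverage_fraction mask parameters, see
#'   [coverage_mask()].
#' @param mirror `"none"` (default, bilateral mask), `"left"` or `"right"`:
#'   fields on the other side are reflected about the template midline
#'   (world x = 0) before pooling.
#' @param aggregate `"efield"` (default) or `"patient"` (voxel-wise maximum
#'   over a patient's fields, one observation per patient).
#' @return an object of class `sweetspot_model`: `r_map`, `p_map`, `mask`
#'   ([voxel_volume()]s), `params`, `n_obs`.
#' @export
sweet_spot_map <- function(x, improvement = NULL, magnitude_threshold = 200,
                           coverage_fraction = 0.5,
                           mirror = c("none", "left", "right"),
                           aggregate = c("efield", "patient")) {
  mirror <- match.arg(mirror)
  aggregate <- match.arg(aggregate)
  if (inherits(x, "dbs_cohort")) {
    pool <- pooled_efields(x)
  } else {
    stopifnot(is.list(x), !is.null(improvement),
              length(improvement) == length(x))
    pool <- list(volumes = x, improvement = improvement,
                 patient_id = as.character(seq_along(x)),
                 hemisphere = rep("left", length(x)))
  }
  if (length(pool$volumes) == 0L) stop("no E-fields to map")
  grid <- check_common_grid(pool$volumes)
  if (mirror != "none") {
    # world x < 0 is left; reflect fields whose mass sits on the other side
    ctr <- vapply(pool$volumes, centroid_x, 0)
    flip <- if (mirror == "left") ctr > 0 else ctr < 0
    pool$volumes[flip] <- lapply(pool$volumes[flip], mirror_volume,
                                 grid = grid)
  }
  if (aggregate == "patient") {
    ids <- unique(pool$patient_id)
    vols <- lapply(ids, function(id) {
      vs <- pool$volumes[pool$patient_id == id]
      voxel_volume(Reduce(pmax, lapply(vs, `[[`, "data")), grid$affine,
                   vs[[1]]$units)
    })
    imp <- pool$improvement[match(ids, pool$patient_id)]
    pool <- list(volumes = vols, improvement = imp, patient_id = ids,
                 hemisphere = rep("pooled", length(ids)))
  }
  n <- length(pool$volumes)
  if (length(unique(pool$patient_id)) < 4L)
    stop("need at least 4 patients to map")
  if (stats::sd(pool$improvement) == 0)
    stop("improvement vector is constant; correlation undefined")
  mask <- coverage_mask(pool$volumes, magnitude_threshold, coverage_fraction)
  vox <- which(mask$data == 1)
  if (length(vox) == 0L)
    stop("coverage mask is empty at threshold ", magnitude_threshold,
         " V/m, fraction ", coverage_fraction)
  X <- vapply(pool$volumes, function(v) v$data[vox], numeric(length(vox)))
  X <- matrix(t(X), nrow = n)                      # n_obs x n_vox
  sp <- spearman_map(X, pool$improvement)
  r_map <- array(0, dim(grid$data)); r_map[vox] <- sp$rho
  p_map <- array(0, dim(grid$data)); p_map[vox] <- sp$p
  structure(list(
    r_map = voxel_volume(r_map, grid$affine, "correlation"),
    p_map = voxel_volume(p_map, grid$affine, "unitless"),
    mask = mask,
    params = list(magnitude_threshold = magnitude_threshold,
                  coverage_fraction = coverage_fraction,
                  mirror = mirror, aggregate = aggregate),
    n_obs = n,
    n_patients = length(unique(pool$patient_id))),
    class = "sweetspot_model")
}

centroid_x <- function(v) {
  w <- v$data
  if (sum(w) == 0) return(0)
  ctr <- grid_world_centres(v)
  sum(ctr[, 1] * as.numeric(w)) / sum(w)
}

#' @export
print.sweetspot_model <- function(x, ...) {
  cat(sprintf(
    "Sweet-spot model: %d mask voxels, %d E-field observations (%d patients)\n",
    sum(x$mask$data), x$n_obs, x$n_patients))
  cat(sprintf("  threshold %g V/m, coverage >= %g; peak R = %.3f, trough R = %.3f\n",
              x$params$magnitude_threshold, x$params$coverage_fraction,
              max(x$r_map$data), min(x$r_map$data)))
  invisible(x)
}

#' @export
summary.sweetspot_model <- function(object, ...) {
  r <- object$r_map$data[object$mask$data == 1]
  structure(list(n_vox = length(r), n_obs = object$n_obs,
                 n_patients = object$n_patients,
                 r_range = range(r), r_mean = mean(r),
                 peak_world = sweet_spot_peak(object),
                 params = object$params),
            class = "summary.sweetspot_model")
}

#' @export
print.summary.sweetspot_model <- function(x, ...) {
  cat(sprintf("Sweet-spot model over %d voxels (%d observations, %d patients)\n",
              x$n_vox, x$n_obs, x$n_patients))
  cat(sprintf("  R in [%.3f, %.3f], mean %.3f\n",
              x$r_range[1], x$r_range[2], x$r_mean))
  cat(sprintf("  peak |R| voxel at (%.1f, %.1f, %.1f) mm\n",
              x$peak_world[1], x$peak_world[2], x$peak_world[3]))
  invisible(x)
}

#' World coordinate of the peak-|R| voxel of a sweet-spot model
#' @param model a `sweetspot_model`.
#' @param positive_only if `TRUE`, peak of R rather than |R|.
#' @return length-3 world mm coordinate.
#' @export
sweet_spot_peak <- function(model, positive_only = FALSE) {
  vals <- if (positive_only) model$r_map$data else abs(model$r_map$data)
  idx <- which.max(vals)
  d <- dim(model$r_map$data)
  k <- (idx - 1) %/% (d[1] * d[2])
  j <- ((idx - 1) %/% d[1]) %% d[2]
  i <- (idx - 1) %% d[1]
  as.numeric(voxel_to_world(c(i, j, k), model$r_map$affine))
}

#' Sweet Spot Scores: estimate outcomes from a fitted voxel model
#'
#' Each E-field is multiplied voxel-wise with the model's R-map and averaged
#' over the mask voxels; a patient's score is the mean over their (bilateral)
#' hemisphere scores. Fields peaking in the sweet spot earn high positive
#' scores; fields sitting on the sour spot go negative.
#'
#' @param object a `sweetspot_model`.
#' @param newdata a [cohort()], a [patient_record()], or a list of
#'   [voxel_volume()] E-fields treated as one patient's hemispheres.
#' @param ... unused.
#' @return named numeric vector of scores (one per patient).
#' @export
predict.sweetspot_model <- function(object, newdata, ...) {
  if (inherits(newdata, "dbs_cohort")) {
    out <- vapply(newdata$records, function(rec)
      sweet_spot_score(rec$efields, object), 0)
    names(out) <- vapply(newdata$records, `[[`, "", "patient_id")
    return(out)
  }
  if (inherits(newdata, "patient_record"))
    return(sweet_spot_score(newdata$efields, object))
  sweet_spot_score(newdata, object)
}

sweet_spot_score <- function(efields, model) {
  if (is.null(efields) || length(efields) == 0L)
    stop("patient has no E-fields to score")
  vox <- which(model$mask$data == 1)
  if (length(vox) == 0L) stop("model mask is empty")
  rvals <- model$r_map$data[vox]
  flip <- model$params$mirror
  hemi <- vapply(efields, function(v) {
    if (!same_grid(v, model$r_map)) {
      if (flip != "none") {
        cx <- centroid_x(v)
        if ((flip == "left" && cx > 0) || (flip == "right" && cx < 0))
          v <- mirror_volume(v, model$r_map)
        else v <- resample_volume(v, model$r_map)
      } else stop("E-field grid does not match the model grid; resample first")
    } else if (flip != "none") {
      cx <- centroid_x(v)
      if ((flip == "left" && cx > 0) || (flip == "right" && cx < 0))
        v <- mirror_volume(v, model$r_map)
    }
    mean(v$data[vox] * rvals)
  }, 0)
  mean(hemi)
}

#' @export
plot.sweetspot_model <- function(x, slice = NULL, ...) {
  d <- dim(x$r_map$data)
  if (is.null(slice)) {
    prof <- apply(abs(x$r_map$data), 3, max)
    slice <- which.max(prof)
  }
  img <- x$r_map$data[, , slice]
  m <- max(abs(img), 1e-12)
  cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(d[1]), seq_len(d[2]), img, zlim = c(-m, m),
                  col = cols, xlab = "i", ylab = "j",
                  main = sprintf("sweet-spot R map, slice k=%d", slice), ...)
  invisible(x)
}
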