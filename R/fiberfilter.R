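#' Select candidate streamlines for fiber filtering
#'
#' A streamline enters the analysis only if it is meaningfully stimulated in
#' the cohort: strictly more than `candidate_fraction` of the E-fields must
#' reach a sampled peak magnitude above `candidate_magnitude` along its
#' course ("more than", so the boundary fraction is excluded). The peak
#' criterion itself operationalises "close to active contacts" — E-fields are
#' compactly supported around them, so no separate distance gate is needed.
#'
#' @param set a [streamline_set()].
#' @param efields list of [voxel_volume()] E-fields (the cohort's pooled
#'   observations).
#' @param candidate_magnitude peak-magnitude threshold in V/m (default 800,
#'   i.e. 0.8 V/mm).
#' @param candidate_fraction required fraction of fields, strict (default
#'   0.005).
#' @param step_mm sampling step along streamlines.
#' @param peaks optional precomputed [peak_matrix()] to avoid resampling.
#' @return logical vector, one flag per streamline.
#' @export
select_candidates <- function(set, efields, candidate_magnitude = 800,
                              candidate_fraction = 0.005, step_mm = 0.5,
                              peaks = NULL) {
  if (is.null(peaks))
    peaks <- peak_matrix(set, efields, step_mm = step_mm)
  frac <- rowMeans(peaks$values > candidate_magnitude)
  frac > candidate_fraction
}

#' Streamlines-by-E-fields peak matrix
#'
#' Entry (s, e) is the peak E-field magnitude sampled along streamline s
#' under field e — the "stimulation impact" of that field on that
#' streamline. Streamlines never entering a field's support get 0.
#'
#' @param set a [streamline_set()].
#' @param efields list of [voxel_volume()]s.
#' @param step_mm sampling step along streamlines (default 0.5 mm).
#' @param subset optional integer/logical index restricting the streamlines.
#' @return object of class `peak_matrix`: `values` (streamlines x fields),
#'   `streamline_index`, `step_mm`.
#' @export
peak_matrix <- function(set, efields, step_mm = 0.5, subset = NULL) {
  stopifnot(inherits(set, "streamline_set"), is.list(efields),
            length(efields) >= 1L)
  idx <- seq_along(set$streamlines)
  if (!is.null(subset)) idx <- idx[subset]
  # resample each streamline once, then interpolate every field at its points
  pts <- lapply(set$streamlines[idx], resample_polyline, step_mm = step_mm)
  nper <- vapply(pts, nrow, 0L)
  allpts <- do.call(rbind, pts)
  group <- rep(seq_along(idx), nper)
  split_idx <- split(seq_along(group), group)
  vals <- matrix(0, length(idx), length(efields))
  shared <- length(efields) > 1 &&
    all(vapply(efields[-1], same_grid, TRUE, efields[[1]]))
  prep <- if (shared || length(efields) == 1)
    trilinear_prep(dim(efields[[1]]$data), efields[[1]]$affine, allpts)
  for (e in seq_along(efields)) {
    s <- if (!is.null(prep)) sample_with_prep(efields[[e]]$data, prep)
    else sample_volume(efields[[e]], allpts)
    vals[, e] <- vapply(split_idx, function(ii) max(s[ii]), 0)
  }
  structure(list(values = vals, streamline_index = idx, step_mm = step_mm),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d streamlines x %d E-fields, step %.2g mm\n",
              nrow(x$values), ncol(x$values), x$step_mm))
  invisible(x)
}

#' Fit a fiber-filtering model
#'
#' DBS fiber filtering: every candidate streamline is tagged with the
#' Spearman correlation (and two-sided p) between its per-observation peak
#' stimulation magnitudes and clinical improvements. Streamlines strongly
#' modulated in good responders get high positive R ("sweet streamlines");
#' those modulated in poor responders go negative ("sour"). The sweet subset
#' is the top `sweet_top_fraction` of the candidate R distribution (and
#' strictly positive). Certainty weights are `-log10(p)` (for uncertainty
#' visualisation; the log base is configurable).
#'
#' @param x a [cohort()] with E-fields, or a [peak_matrix()].
#' @param set the [streamline_set()] being filtered.
#' @param improvement percent improvements per E-field observation; taken
#'   from the cohort when `x` is one.
#' @param candidate_magnitude,candidate_fraction see [select_candidates()].
#' @param sweet_top_fraction upper tail of the candidate R distribution kept
#'   as sweet (default 0.01).
#' @param score_peak_fraction fraction of weighted values summed when scoring
#'   (default 0.05); stored for [predict.fiber_model()].
#' @param step_mm sampling step along streamlines.
#' @param mirror `"none"` (default), `"left"` or `"right"`: reflect E-fields
#'   from the other hemisphere about the template midline (world x = 0)
#'   before sampling, so a mirror-symmetric streamline model is informed by
#'   every field. Scoring via [predict.fiber_model()] applies the same
#'   reflection.
#' @param log_base base of the certainty transform (default 10).
#' @return object of class `fiber_model` with per-streamline `r`, `p`,
#'   `certainty`, `candidate`, `sweet` flags (full-set length; NA where no
#'   correlation is defined), `sweet_threshold`, `sweet_ids`,
#'   `sweet_streamlines` (geometry subset for scoring), `params`, `n_obs`.
#' @export
fiber_filter <- function(x, set, improvement = NULL,
                         candidate_magnitude = 800,
                         candidate_fraction = 0.005,
                         sweet_top_fraction = 0.01,
                         score_peak_fraction = 0.05,
                         step_mm = 0.5, mirror = c("none", "left", "right"),
                         log_base = 10) {
  mirror <- match.arg(mirror)
  if (inherits(x, "dbs_cohort")) {
    pool <- pooled_efields(x)
    efields <- lapply(pool$volumes, orient_field, mirror = mirror)
    improvement <- pool$improvement
    peaks <- peak_matrix(set, efields, step_mm = step_mm)
  } else if (inherits(x, "peak_matrix")) {
    peaks <- x
    if (is.null(improvement)) stop("improvement vector required")
  } else stop("x must be a cohort or a peak_matrix")
  n <- ncol(peaks$values)
  if (length(improvement) != n)
    stop("improvement length ", length(improvement),
         " != number of E-field observations ", n)
  if (n < 4L) stop("need at least 4 E-field observations")
  if (stats::sd(improvement) == 0)
    stop("improvement vector is constant; correlation undefined")

  nstream <- length(set$streamlines)
  cand_local <- rowMeans(peaks$values > candidate_magnitude) >
    candidate_fraction
  candidate <- logical(nstream)
  candidate[peaks$streamline_index[cand_local]] <- TRUE

  r <- rep(NA_real_, nstream); p <- rep(NA_real_, nstream)
  if (any(cand_local)) {
    sp <- spearman_map(t(peaks$values[cand_local, , drop = FALSE]),
                       improvement)
    r[peaks$streamline_index[cand_local]] <- sp$rho
    p[peaks$streamline_index[cand_local]] <- sp$p
  }
  rc <- r[candidate]
  if (length(rc) == 0L)
    stop("no candidate streamlines at ", candidate_magnitude, " V/m in > ",
         candidate_fraction * 100, "% of E-fields")
  sweet_threshold <- as.numeric(stats::quantile(rc, 1 - sweet_top_fraction,
                                                names = FALSE, type = 7))
  sweet <- !is.na(r) & candidate & r >= sweet_threshold & r > 0
  certainty <- -log(p, base = log_base)
  structure(list(
    r = r, p = p, certainty = certainty,
    candidate = candidate, sweet = sweet,
    sweet_threshold = sweet_threshold,
    sweet_ids = which(sweet),
    sweet_streamlines = subset_streamlines(set, which(sweet)),
    specificity = NULL,
    params = list(candidate_magnitude = candidate_magnitude,
                  candidate_fraction = candidate_fraction,
                  sweet_top_fraction = sweet_top_fraction,
                  score_peak_fraction = score_peak_fraction,
                  step_mm = step_mm, mirror = mirror, log_base = log_base),
    n_obs = n),
    class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf(
    "Fiber model: %d streamlines, %d candidates, %d sweet (R >= %.3f)\n",
    length(x$r), sum(x$candidate), length(x$sweet_ids), x$sweet_threshold))
  cat(sprintf("  %d E-field observations; candidate R in [%.3f, %.3f]\n",
              x$n_obs, min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.fiber_model <- function(object, ...) {
  rc <- object$r[object$candidate]
  out <- list(n_stream = length(object$r), n_candidate = sum(object$candidate),
              n_sweet = length(object$sweet_ids),
              sweet_threshold = object$sweet_threshold,
              r_candidate = summary(rc), n_obs = object$n_obs,
              params = object$params)
  class(out) <- "summary.fiber_model"
  out
}

#' @export
print.summary.fiber_model <- function(x, ...) {
  cat(sprintf("Fiber model on %d streamlines (%d candidates, %d sweet)\n",
              x$n_stream, x$n_candidate, x$n_sweet))
  cat(sprintf("  sweet R threshold (top %g%% of candidates): %.3f\n",
              x$params$sweet_top_fraction * 100, x$sweet_threshold))
  print(x$r_candidate)
  invisible(x)
}

#' Per-streamline tabular view of a fitted fiber model
#' @param model a `fiber_model`.
#' @return data.frame with streamline_id, r, p, certainty, candidate, sweet
#'   (and specificity when attached).
#' @export
fiber_model_table <- function(model) {
  stopifnot(inherits(model, "fiber_model"))
  df <- data.frame(streamline_id = seq_along(model$r), r = model$r,
                   p = model$p, certainty = model$certainty,
                   candidate = model$candidate, sweet = model$sweet)
  if (!is.null(model$specificity)) df$specificity <- model$specificity
  df
}

#' Fiber R scores: estimate outcomes from a fitted streamline model
#'
#' The "weighted peak 5% of Fiber R" score. Per hemisphere: among sweet
#' streamlines with a nonzero sampled peak under that E-field, each
#' streamline's R is multiplied by its peak magnitude; the largest
#' `ceiling(score_peak_fraction * count)` weighted values (at least one) are
#' summed. A hemisphere touching no sweet streamline scores 0. The patient
#' score is the mean over hemispheres.
#'
#' @param object a `fiber_model`.
#' @param newdata a [cohort()], [patient_record()], or list of
#'   [voxel_volume()] E-fields for one patient.
#' @param ... unused.
#' @return named numeric vector of scores (one per patient).
#' @export
predict.fiber_model <- function(object, newdata, ...) {
  if (length(object$sweet_ids) == 0L)
    stop("fiber model has an empty sweet subset; nothing to score")
  if (inherits(newdata, "dbs_cohort")) {
    out <- vapply(newdata$records, function(rec)
      fiber_r_score(rec$efields, object), 0)
    names(out) <- vapply(newdata$records, `[[`, "", "patient_id")
    return(out)
  }
  if (inherits(newdata, "patient_record"))
    return(fiber_r_score(newdata$efields, object))
  fiber_r_score(newdata, object)
}

fiber_r_score <- function(efields, model) {
  if (is.null(efields) || length(efields) == 0L)
    stop("patient has no E-fields to score")
  rsweet <- model$r[model$sweet_ids]
  frac <- model$params$score_peak_fraction
  mirror <- model$params$mirror
  if (is.null(mirror)) mirror <- "none"
  efields <- lapply(efields, orient_field, mirror = mirror)
  hemi <- vapply(efields, function(v) {
    pk <- peak_matrix(model$sweet_streamlines, list(v),
                      step_mm = model$params$step_mm)$values[, 1]
    touched <- pk > 0
    if (!any(touched)) return(0)
    w <- rsweet[touched] * pk[touched]
    keep <- max(1L, ceiling(frac * length(w)))
    sum(sort(w, decreasing = TRUE)[seq_len(keep)])
  }, 0)
  mean(hemi)
}

# reflect a field about x = 0 when its mass sits on the non-target side
orient_field <- function(v, mirror) {
  if (mirror == "none") return(v)
  cx <- centroid_x(v)
  if ((mirror == "left" && cx > 0) || (mirror == "right" && cx < 0))
    mirror_volume(v) else v
}

#' Cross-disorder specificity ratio per streamline
#'
#' For each disorder's model, each streamline's R is divided by the mean of
#' the R values the same streamline received in the remaining disorders'
#' models. Ratios are only defined where that cross-disorder mean is nonzero;
#' elsewhere the ratio is NA (flagged undefined, never infinite). A
#' streamline with R = 0 in its own model gets ratio 0.
#'
#' @param models named list of >= 2 `fiber_model`s sharing one streamline
#'   index space.
#' @return named list of numeric vectors (one per model, full streamline
#'   length), also attached to each returned model's `specificity` field.
#' @export
specificity_ratio <- function(models) {
  if (!is.list(models) || length(models) < 2L)
    stop("need fiber models from at least 2 disorders")
  stopifnot(all(vapply(models, inherits, TRUE, "fiber_model")))
  ns <- unique(vapply(models, function(m) length(m$r), 0L))
  if (length(ns) != 1L)
    stop("models do not share a streamline index space")
  out <- vector("list", length(models))
  names(out) <- names(models)
  for (i in seq_along(models)) {
    others <- do.call(cbind, lapply(models[-i], `[[`, "r"))
    other_mean <- rowMeans(others)
    ratio <- models[[i]]$r / other_mean
    ratio[!is.na(other_mean) & abs(other_mean) < 1e-15] <- NA_real_
    ratio[!is.na(models[[i]]$r) & models[[i]]$r == 0] <- 0
    out[[i]] <- ratio
  }
  out
}

#' Gaussian contact-seeding control
#'
#' Electrode-placement control analysis: a trivariate Gaussian is fitted to
#' the cohort's standard (second-to-lowest) contact coordinates, and
#' streamlines are "seeded" from that blurred volume — selected iff any
#' sampled point lies within `mahalanobis_cut` Mahalanobis units of the
#' contact cloud. This yields the connectivity profile implied by electrode
#' placement alone, with no outcome information.
#'
#' @param contacts_mm n x 3 matrix of contact coordinates (>= 4 rows).
#' @param set a [streamline_set()].
#' @param mahalanobis_cut selection radius in Mahalanobis units (default 2).
#' @param step_mm streamline sampling step.
#' @return list with `selected` (logical per streamline), `mean`, `cov`,
#'   `min_distance` (per streamline).
#' @export
gaussian_contact_control <- function(contacts_mm, set, mahalanobis_cut = 2,
                                     step_mm = 0.5) {
  contacts_mm <- rbind3(contacts_mm)
  if (nrow(contacts_mm) < 4L) stop("need at least 4 contact coordinates")
  mu <- colMeans(contacts_mm)
  sig <- stats::cov(contacts_mm)
  if (abs(det(sig)) < 1e-10) {
    eps <- max(1e-6, 1e-6 * mean(diag(sig)))
    sig <- sig + diag(eps, 3)
    message("singular contact covariance; ridge-regularised with epsilon ",
            format(eps))
  }
  siginv <- solve(sig)
  mind <- vapply(set$streamlines, function(p) {
    pts <- resample_polyline(p, step_mm)
    dx <- sweep(pts, 2, mu)
    sqrt(min(rowSums((dx %*% siginv) * dx)))
  }, 0)
  list(selected = mind <= mahalanobis_cut, mean = mu, cov = sig,
       min_distance = mind)
}
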