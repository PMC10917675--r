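#' Phantom scene: grid, nucleus, and streamline bundles
#'
#' Builds the synthetic anatomy every simulated cohort stimulates: a small
#' template grid around a bilateral ellipsoidal "nucleus" (a stand-in for a
#' stimulation target such as the subthalamic nucleus), plus named streamline
#' bundle groups coursing from a peri-nucleus waypoint up to distinct
#' "cortical" patches. Bundles are mirrored into both hemispheres. The scene
#' is fully regenerable from its parameters and seed.
#'
#' Default geometry: 1 mm isotropic grid spanning 41 x 25 x 25 mm around the
#' nuclei at (+/-11, -13, -7) mm (semi-axes 4 x 3 x 3 mm); three bundle
#' groups — `bundleA` through the nucleus centre, `bundleB` offset 3 mm
#' (the decoy), `background` offset ~8 mm — of 40 streamlines each per
#' hemisphere.
#'
#' @param seed integer master seed for bundle geometry.
#' @param voxel_mm isotropic voxel size of the template grid.
#' @param nucleus_center left-hemisphere nucleus centre (world mm; the right
#'   nucleus is its x-mirror).
#' @param nucleus_semiaxes ellipsoid semi-axes (mm).
#' @param bundle_offsets named list of waypoint offsets (mm) from the nucleus
#'   centre, one per bundle group.
#' @param n_per_group streamlines per group per hemisphere.
#' @param separation_mm minimum pairwise waypoint separation to enforce.
#' @param jitter_mm waypoint scatter of individual streamlines.
#' @return object of class `phantom_scene`: `grid` ([voxel_volume()]
#'   template), `nucleus` (per-hemisphere centre/semi-axes), `bundles`
#'   (named list of [streamline_set()]s), `params`, `seed`.
#' @export
phantom_scene <- function(seed = 1, voxel_mm = 1,
                          nucleus_center = c(-11, -13, -7),
                          nucleus_semiaxes = c(4, 3, 3),
                          bundle_offsets = list(bundleA = c(0, 0, 0),
                                                bundleB = c(0, 3, 0),
                                                background = c(0, 8, 2)),
                          n_per_group = 40,
                          separation_mm = 3,
                          jitter_mm = 1) {
  stopifnot(voxel_mm > 0, length(bundle_offsets) >= 1)
  half <- c(20, 12, 12)
  # x centres symmetric about the midline so hemisphere mirroring is exact
  hx <- floor(half[1] / voxel_mm)
  shape <- c(2L * hx + 1L, floor(2 * half[2:3] / voxel_mm) + 1L)
  lo <- c(-hx * voxel_mm, nucleus_center[2] - half[2],
          nucleus_center[3] - half[3])
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- lo
  grid <- voxel_volume(array(0, shape), affine)
  waypoints <- t(vapply(bundle_offsets, function(o) nucleus_center + o,
                        numeric(3)))
  cortical <- waypoints
  cortical[, 1] <- cortical[, 1] - 8 - 6 * (seq_len(nrow(cortical)) - 1)
  cortical[, 2] <- cortical[, 2] + 8 * (seq_len(nrow(cortical)) - 1)
  cortical[, 3] <- 40
  bundles <- make_bundles(waypoints, cortical, n_per_group = n_per_group,
                          separation_mm = separation_mm,
                          jitter_mm = jitter_mm, mirror = TRUE, seed = seed)
  names(bundles) <- names(bundle_offsets)
  structure(list(grid = grid,
                 nucleus = list(
                   left = list(center = nucleus_center,
                               semiaxes = nucleus_semiaxes),
                   right = list(center = nucleus_center * c(-1, 1, 1),
                                semiaxes = nucleus_semiaxes)),
                 bundles = bundles,
                 params = list(voxel_mm = voxel_mm,
                               bundle_offsets = bundle_offsets,
                               n_per_group = n_per_group,
                               separation_mm = separation_mm,
                               jitter_mm = jitter_mm),
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> grid %s at %g mm; %d bundle group(s): %s\n",
              paste(dim(x$grid$data), collapse = "x"), x$params$voxel_mm,
              length(x$bundles),
              paste(sprintf("%s(%d)", names(x$bundles),
                            vapply(x$bundles, length, 0L)), collapse = ", ")))
  invisible(x)
}

#' Generate streamline bundle groups
#'
#' Each group is a fan of smooth quadratic-curve polylines rising from a
#' subcortical start below the waypoint, through the waypoint box, to a
#' cortical patch; groups share cortical territory partially but are kept
#' pairwise separated at the waypoint by at least `separation_mm` (an error
#' if the supplied waypoints violate this — the separation is a stated
#' property of the scene, not something silently repaired).
#'
#' @param waypoints k x 3 matrix of group waypoint centres (world mm).
#' @param cortical k x 3 matrix of cortical patch centres.
#' @param n_per_group streamlines per group (per hemisphere when mirrored).
#' @param separation_mm minimum pairwise waypoint distance.
#' @param jitter_mm Gaussian scatter of individual streamlines about the
#'   waypoint and cortical centres.
#' @param mirror also generate the x-mirrored counterpart of every group.
#' @param seed integer seed.
#' @return list of [streamline_set()]s, one per group.
#' @export
make_bundles <- function(waypoints, cortical, n_per_group = 40,
                         separation_mm = 3, jitter_mm = 1, mirror = TRUE,
                         seed = 1) {
  waypoints <- rbind3(waypoints)
  cortical <- rbind3(cortical)
  stopifnot(nrow(waypoints) >= 1, nrow(cortical) == nrow(waypoints),
            n_per_group >= 1)
  if (nrow(waypoints) > 1) {
    dmin <- min(stats::dist(waypoints))
    if (dmin < separation_mm)
      stop(sprintf(
        "waypoint separation infeasible: nearest groups are %.2f mm apart, < %g mm required",
        dmin, separation_mm))
  }
  tt <- seq(0, 1, length.out = 25)
  with_preserved_rng(seed, {
    lapply(seq_len(nrow(waypoints)), function(g) {
      one_side <- function(w0, c0) {
        lapply(seq_len(n_per_group), function(s) {
          w <- w0 + stats::rnorm(3, 0, jitter_mm)
          p0 <- w + c(0, 0, -12) + stats::rnorm(3, 0, jitter_mm)
          p2 <- c0 + c(stats::rnorm(2, 0, 3), 0)
          # quadratic polynomial through p0, w, p2 with the waypoint placed
          # at its arclength fraction, keeping the speed near-constant so
          # the curve stays smooth (no hairpins)
          l1 <- sqrt(sum((w - p0)^2)); l2 <- sqrt(sum((p2 - w)^2))
          tm <- l1 / (l1 + l2)
          D <- p2 - p0; W <- w - p0
          b <- (W - D * tm^2) / (tm * (1 - tm))
          cc <- D - b
          outer(rep(1, length(tt)), p0) + outer(tt, b) + outer(tt^2, cc)
        })
      }
      left <- one_side(waypoints[g, ], cortical[g, ])
      if (mirror) {
        right <- one_side(waypoints[g, ] * c(-1, 1, 1),
                          cortical[g, ] * c(-1, 1, 1))
        streamline_set(c(left, right))
      } else streamline_set(left)
    })
  })
}

#' Analytic E-field magnitude volume
#'
#' Inverse-square stand-in for a simulated stimulation field: magnitude at a
#' voxel is `sum_contacts kappa * amplitude / max(r, r0)^2`, strictly
#' decreasing with distance beyond the singularity cap `r0 = 0.5 mm`. The
#' constant `kappa = 1225 V/m mm^2 / mA` is calibrated so that a 2 mA
#' single-contact field crosses 200 V/m — the conventional activation
#' threshold — at 3.5 mm. This preserves the monotone compact-decay property
#' the mapping methods rely on; it is a geometric stand-in, not a tissue
#' model.
#'
#' @param contacts_mm active contact position(s), k x 3 world mm; must lie
#'   inside the grid's bounding box.
#' @param amplitude stimulation amplitude in mA, > 0.
#' @param grid template [voxel_volume()].
#' @return a [voxel_volume()] with units `V_per_m`.
#' @export
simulate_efield <- function(contacts_mm, amplitude, grid) {
  contacts_mm <- rbind3(contacts_mm)
  stopifnot(amplitude > 0)
  d <- dim(grid$data)
  vox <- world_to_voxel(contacts_mm, grid$affine)
  inside <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
            vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
            vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  if (!all(inside))
    stop("active contact(s) outside the grid: row(s) ",
         paste(which(!inside), collapse = ", "))
  kappa <- 200 * 3.5^2 / 2   # V/m mm^2 per mA; 2 mA -> 200 V/m at 3.5 mm
  centres <- grid_world_centres(grid)
  mag <- numeric(nrow(centres))
  for (ci in seq_len(nrow(contacts_mm))) {
    r2 <- (centres[, 1] - contacts_mm[ci, 1])^2 +
          (centres[, 2] - contacts_mm[ci, 2])^2 +
          (centres[, 3] - contacts_mm[ci, 3])^2
    r2 <- pmax(r2, 0.25)            # r0 = 0.5 mm singularity cap
    mag <- mag + kappa * amplitude / r2
  }
  voxel_volume(array(mag, d), grid$affine, units = "V_per_m")
}

#' Ground truth of a simulated cohort
#'
#' @param target_kind `"spot"` or `"bundle"`.
#' @param planted_spot_center for spot truth, the left-hemisphere target
#'   centre (world mm); the mirrored pair is planted on the right.
#' @param planted_bundle for bundle truth, the name of the driving bundle
#'   group in the scene.
#' @param effect_size outcome-signal SD in percent-improvement points; 0
#'   gives a null cohort whose outcomes are pure Gaussian noise (10-point SD).
#' @param noise_sd_pct Gaussian outcome noise SD, as percent of the signal SD.
#' @param seed integer seed for the cohort draw.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(target_kind = c("spot", "bundle"),
                             planted_spot_center = NULL,
                             planted_bundle = NULL,
                             effect_size = 15, noise_sd_pct = 15, seed = 1) {
  target_kind <- match.arg(target_kind)
  if (target_kind == "spot" && is.null(planted_spot_center))
    stop("spot truth needs planted_spot_center")
  if (target_kind == "bundle" && is.null(planted_bundle))
    stop("bundle truth needs planted_bundle")
  structure(list(target_kind = target_kind,
                 planted_spot_center = planted_spot_center,
                 planted_bundle = planted_bundle,
                 effect_size = effect_size, noise_sd_pct = noise_sd_pct,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate a DBS cohort over a phantom scene
#'
#' Implants a bilateral 4-contact linear lead per patient, aimed at the
#' nucleus centre (plus `target_offset`) with Gaussian placement jitter —
#' emulating the incidental placement variability that group mapping
#' exploits. The second-to-lowest ("standard") contact is activated at a
#' patient-specific amplitude and an analytic E-field generated per
#' hemisphere. Planted-target engagement (E-magnitude at the planted spot,
#' or mean peak over the planted bundle's streamlines, averaged over
#' hemispheres) drives outcomes:
#' `improvement = 50 + effect_size * z(engagement) + noise`, with noise SD a
#' stated percentage of the signal SD. Follow-up scores are back-computed
#' from a fixed baseline of 40 points so percent improvements map linearly
#' onto the engagement signal; improvements are not clipped (worsening is
#' possible, as in real cohorts).
#'
#' @param scene a [phantom_scene()].
#' @param n_patients number of patients (>= 4).
#' @param truth a [simulation_truth()].
#' @param placement_jitter_mm SD of the 3D Gaussian lead placement error
#'   (default 1.5 mm).
#' @param target_offset systematic targeting offset added to the nucleus
#'   centre (mm, left-hemisphere convention; mirrored on the right).
#' @param amplitude_range uniform range of stimulation amplitudes (mA).
#' @param baseline fixed baseline score (synthetic severity scale).
#' @param disorder disorder tag for the generated records.
#' @param seed integer seed (defaults to the truth's).
#' @param write_dir optional directory: when given, writes
#'   `efields/*.nii` (+ JSON sidecars), `bundles.trk`, `cohort.csv`,
#'   `manifest.json` and `truth.json` as a self-contained cohort directory.
#' @return a [cohort()]; metadata carries the truth, per-patient contact
#'   coordinates, engagement values and all derived seeds.
#' @export
make_cohort <- function(scene, n_patients, truth,
                        placement_jitter_mm = 1.5,
                        target_offset = c(0, 0, 0),
                        amplitude_range = c(1.5, 3.5),
                        baseline = 40,
                        disorder = "synthetic",
                        seed = truth$seed,
                        write_dir = NULL) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(truth, "simulation_truth"), n_patients >= 4)
  grid <- scene$grid
  contact_dz <- c(-3, -1, 1, 3)     # 4-contact lead, 2 mm spacing
  active_idx <- 2L                  # second-to-lowest "standard" contact
  res <- with_preserved_rng(seed, {
    pats <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      per_hemi <- list()
      for (h in c("left", "right")) {
        mirr <- if (h == "left") c(1, 1, 1) else c(-1, 1, 1)
        target <- (scene$nucleus$left$center + target_offset) * mirr
        base <- target + stats::rnorm(3, 0, placement_jitter_mm)
        contacts <- cbind(base[1], base[2], base[3] + contact_dz)
        amp <- stats::runif(1, amplitude_range[1], amplitude_range[2])
        ef <- simulate_efield(contacts[active_idx, , drop = FALSE], amp, grid)
        per_hemi[[h]] <- list(efield = ef, contacts = contacts,
                              active_contact = contacts[active_idx, ],
                              amplitude = amp)
      }
      pats[[i]] <- per_hemi
    }
    noise <- stats::rnorm(n_patients)
    list(pats = pats, noise = noise)
  })
  ctx <- engagement_context(scene, truth)
  engagement <- vapply(res$pats, function(p)
    mean(vapply(names(p), function(h)
      target_engagement(p[[h]]$efield, h, truth, ctx), 0)), 0)
  if (stats::sd(engagement) == 0)
    warning("engagement is constant across ", n_patients,
            " patients; no field reaches the planted target")
  z <- if (stats::sd(engagement) > 0)
    (engagement - mean(engagement)) / stats::sd(engagement)
  else rep(0, n_patients)
  # zero-effect (null) cohorts are pure noise; give them a fixed 10-point SD
  # so outcomes still vary (rank-based analyses are scale-free anyway)
  noise_sd <- if (truth$effect_size > 0)
    truth$effect_size * truth$noise_sd_pct / 100 else 10
  improvement <- 50 + truth$effect_size * z + noise_sd * res$noise
  followup <- baseline * (1 - improvement / 100)
  records <- lapply(seq_len(n_patients), function(i) {
    patient_record(sprintf("%s%03d", disorder, i), disorder,
                   baseline, followup[i],
                   efields = lapply(res$pats[[i]], `[[`, "efield"))
  })
  contacts <- lapply(res$pats, function(p) lapply(p, `[[`, "contacts"))
  active <- lapply(res$pats, function(p) lapply(p, `[[`, "active_contact"))
  coh <- cohort(records,
                metadata = list(truth = truth, seed = as.integer(seed),
                                engagement = engagement,
                                contacts = contacts,
                                active_contacts = active,
                                placement_jitter_mm = placement_jitter_mm,
                                target_offset = target_offset,
                                amplitude_range = amplitude_range))
  if (!is.null(write_dir)) write_cohort_dir(coh, scene, write_dir)
  coh
}

# per-hemisphere precomputation of planted-bundle sample points, so the
# engagement of many fields costs one gather each
engagement_context <- function(scene, truth) {
  if (truth$target_kind != "bundle") return(NULL)
  bundle <- scene$bundles[[truth$planted_bundle]]
  if (is.null(bundle)) stop("scene has no bundle '", truth$planted_bundle, "'")
  grid <- scene$grid
  lapply(stats::setNames(c("left", "right"), c("left", "right")),
         function(h) {
    # only the field's own hemisphere engages its copy of the bundle; the
    # other side contributes a constant 0, so restricting is monotone-exact
    side <- vapply(bundle$streamlines, function(p) mean(p[, 1]), 0)
    keep <- if (h == "left") side < 0 else side > 0
    if (!any(keep)) keep <- rep(TRUE, length(side))
    sub <- subset_streamlines(bundle, keep)
    pts <- lapply(sub$streamlines, resample_polyline, step_mm = 0.5)
    allpts <- do.call(rbind, pts)
    group <- rep(seq_along(pts), vapply(pts, nrow, 0L))
    list(prep = trilinear_prep(dim(grid$data), grid$affine, allpts),
         split_idx = split(seq_along(group), group))
  })
}

target_engagement <- function(efield, hemi, truth, ctx = NULL) {
  if (truth$target_kind == "spot") {
    ctr <- truth$planted_spot_center
    if (hemi == "right") ctr <- ctr * c(-1, 1, 1)
    sample_volume(efield, matrix(ctr, 1))
  } else {
    h <- ctx[[hemi]]
    s <- sample_with_prep(efield$data, h$prep)
    mean(vapply(h$split_idx, function(ii) max(s[ii]), 0))
  }
}

#' Write a simulated cohort as a self-contained directory
#'
#' @param coh a cohort from [make_cohort()].
#' @param scene the [phantom_scene()] it was generated over.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(coh, scene, dir) {
  dir.create(file.path(dir, "efields"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list(); man <- list()
  for (rec in coh$records) {
    for (h in names(rec$efields)) {
      fn <- file.path(dir, "efields", sprintf("%s_%s.nii", rec$patient_id, h))
      save_volume(rec$efields[[h]], fn)
      man[[length(man) + 1L]] <- data.frame(patient_id = rec$patient_id,
                                            hemisphere = h, efield_path = fn)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = rec$patient_id, disorder = rec$disorder,
      baseline = rec$baseline, followup = rec$followup,
      improvement_pct = rec$improvement_pct)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, man), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(coh$metadata$contacts)) {
    ids <- vapply(coh$records, `[[`, "", "patient_id")
    ct <- list()
    for (i in seq_along(coh$metadata$contacts)) {
      for (h in names(coh$metadata$contacts[[i]])) {
        cm <- coh$metadata$contacts[[i]][[h]]
        act <- coh$metadata$active_contacts[[i]][[h]]
        ct[[length(ct) + 1L]] <- data.frame(
          patient_id = ids[i], hemisphere = h,
          contact = seq_len(nrow(cm)), x = cm[, 1], y = cm[, 2], z = cm[, 3],
          active = rowSums(abs(sweep(cm, 2, act))) < 1e-9)
      }
    }
    utils::write.csv(do.call(rbind, ct), file.path(dir, "contacts.csv"),
                     row.names = FALSE)
  }
  all_streams <- do.call(c, lapply(scene$bundles, `[[`, "streamlines"))
  save_streamlines(streamline_set(all_streams),
                   file.path(dir, "bundles.trk"),
                   affine = scene$grid$affine, dim = dim(scene$grid$data))
  groups <- rep(names(scene$bundles), vapply(scene$bundles, length, 0L))
  jsonlite::write_json(list(groups = groups),
                       file.path(dir, "bundle_groups.json"))
  tr <- coh$metadata$truth
  jsonlite::write_json(
    list(target_kind = tr$target_kind,
         planted_spot_center = tr$planted_spot_center,
         planted_bundle = tr$planted_bundle,
         effect_size = tr$effect_size, noise_sd_pct = tr$noise_sd_pct,
         seed = tr$seed, cohort_seed = coh$metadata$seed,
         scene_seed = scene$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(n_patients = length(coh$records),
         placement_jitter_mm = coh$metadata$placement_jitter_mm,
         target_offset = coh$metadata$target_offset,
         amplitude_range = coh$metadata$amplitude_range,
         seeds = list(scene = scene$seed, cohort = coh$metadata$seed)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
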