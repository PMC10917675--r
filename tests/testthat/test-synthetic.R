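test_that("the analytic E-field honours its calibration and symmetry", {
  g <- tiny_grid(21)
  f <- simulate_efield(c(0, 0, 0), 2, g)
  # calibration: 200 V/m at 3.5 mm from a 2 mA contact, within 1 %
  # (read at an exact voxel centre 3.5 mm from an offset contact, so the
  # check sees the field itself, not interpolation between centres)
  fo <- simulate_efield(c(-0.5, 0, 0), 2, g)
  at <- fo$data[11 + 3, 11, 11]            # centre (3, 0, 0): r = 3.5 mm
  expect_lt(abs(at - 200) / 200, 0.01)
  # linearity in amplitude
  f2 <- simulate_efield(c(0, 0, 0), 4, g)
  expect_equal(f2$data, 2 * f$data, tolerance = 1e-12)
  # spherical symmetry: equidistant axis voxels are equal
  expect_equal(f$data[11 + 4, 11, 11], f$data[11, 11 + 4, 11],
               tolerance = 1e-9)
  expect_equal(f$data[11 + 4, 11, 11], f$data[11, 11, 11 - 4],
               tolerance = 1e-9)
  # monotone radial decay beyond the cap
  prof <- f$data[11:21, 11, 11]
  expect_true(all(diff(prof[2:11]) < 0))
  expect_error(simulate_efield(c(100, 0, 0), 2, g), "outside the grid")
  expect_error(simulate_efield(c(0, 0, 0), 0, g), "amplitude")
})

test_that("bundle groups respect separation, size and smoothness", {
  w <- matrix(c(-11, -13, -7, -11, -9, -7), 2, 3, byrow = TRUE)
  ct <- matrix(c(-20, -10, 40, -26, -2, 40), 2, 3, byrow = TRUE)
  gr <- make_bundles(w, ct, n_per_group = 15, separation_mm = 3,
                     mirror = FALSE, seed = 5)
  expect_length(gr, 2)
  expect_length(gr[[1]]$streamlines, 15)
  # nearest waypoint distance between the groups is the declared 4 mm
  expect_gte(min(dist(w)), 3)
  # turning angles along every polyline stay below 60 degrees
  for (p in gr[[1]]$streamlines) {
    seg <- diff(p)
    seg <- seg / sqrt(rowSums(seg^2))
    cosang <- rowSums(seg[-nrow(seg), ] * seg[-1, ])
    expect_gt(min(cosang), cos(60 * pi / 180))
  }
  # infeasible separation is an error
  expect_error(make_bundles(w, ct, separation_mm = 10), "infeasible")
  # mirrored generation doubles each group across hemispheres
  grm <- make_bundles(w[1, , drop = FALSE], ct[1, , drop = FALSE],
                      n_per_group = 4, mirror = TRUE, seed = 5)
  xs <- vapply(grm[[1]]$streamlines, function(p) mean(p[, 1]), 0)
  expect_length(xs, 8)
  expect_equal(sum(xs < 0), 4)
})

test_that("scenes regenerate identically from (parameters, seed)", {
  s1 <- phantom_scene(seed = 42, n_per_group = 5)
  s2 <- phantom_scene(seed = 42, n_per_group = 5)
  expect_identical(s1$bundles, s2$bundles)
  s3 <- phantom_scene(seed = 43, n_per_group = 5)
  expect_false(identical(s1$bundles$bundleA$streamlines[[1]],
                         s3$bundles$bundleA$streamlines[[1]]))
  # every planted-bundle streamline passes close to a nucleus centre
  dist_to <- function(p, ctr) min(sqrt(colSums((t(p) - ctr)^2)))
  near <- vapply(s1$bundles$bundleA$streamlines, function(p)
    min(dist_to(p, s1$nucleus$left$center),
        dist_to(p, s1$nucleus$right$center)), 0)
  expect_lt(max(near), 6)
})

test_that("noiseless spot cohorts couple engagement and improvement exactly", {
  scene <- phantom_scene(seed = 101, n_per_group = 5)
  truth <- simulation_truth("spot",
                            planted_spot_center = scene$nucleus$left$center,
                            noise_sd_pct = 0, seed = 102)
  co <- make_cohort(scene, 12, truth)
  eng <- co$metadata$engagement
  expect_equal(spearman(eng, improvements(co))$rho, 1)
  # improvement maps back through the fixed 40-point baseline
  rec <- co$records[[1]]
  expect_equal(rec$improvement_pct,
               percent_improvement(40, rec$followup))
})

test_that("cohort generation is reproducible and writes byte-stable files", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  scene <- phantom_scene(seed = 103, n_per_group = 4)
  truth <- simulation_truth("spot",
                            planted_spot_center = scene$nucleus$left$center,
                            seed = 104)
  co1 <- make_cohort(scene, 5, truth, write_dir = dir1)
  co2 <- make_cohort(scene, 5, truth, write_dir = dir2)
  expect_equal(improvements(co1), improvements(co2))
  for (f in c("cohort.csv", "manifest.json", "truth.json", "bundles.trk")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
  ef1 <- list.files(file.path(dir1, "efields"), pattern = "nii$",
                    full.names = TRUE)
  ef2 <- list.files(file.path(dir2, "efields"), pattern = "nii$",
                    full.names = TRUE)
  expect_length(ef1, 10)
  v1 <- load_volume(ef1[1]); v2 <- load_volume(ef2[1])
  expect_identical(v1$data, v2$data)
  # and the directory round-trips through the cohort loader
  back <- load_cohort(file.path(dir1, "cohort.csv"),
                      file.path(dir1, "manifest.csv"))
  expect_equal(improvements(back), improvements(co1), tolerance = 1e-6)
  expect_length(back$records[[1]]$efields, 2)
})

test_that("bundle-truth outcomes track planted-bundle engagement", {
  scene <- phantom_scene(seed = 105, n_per_group = 6)
  truth <- simulation_truth("bundle", planted_bundle = "bundleA",
                            noise_sd_pct = 0, seed = 106)
  co <- make_cohort(scene, 10, truth)
  expect_equal(spearman(co$metadata$engagement, improvements(co))$rho, 1)
  expect_error(make_cohort(scene, 10,
                           simulation_truth("bundle",
                                            planted_bundle = "nope",
                                            seed = 1)),
               "no bundle")
})

test_that("zero-effect cohorts still vary (pure-noise outcomes)", {
  scene <- phantom_scene(seed = 107, n_per_group = 4)
  truth <- simulation_truth("spot",
                            planted_spot_center = scene$nucleus$left$center,
                            effect_size = 0, seed = 108)
  co <- make_cohort(scene, 10, truth)
  expect_gt(sd(improvements(co)), 1)
})
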