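make_fields <- function(values_by_voxel, grid) {
  # values_by_voxel: n_fields x n_vox matrix filling the first voxels in order
  lapply(seq_len(nrow(values_by_voxel)), function(i) {
    arr <- array(0, dim(grid$data))
    arr[seq_len(ncol(values_by_voxel))] <- values_by_voxel[i, ]
    voxel_volume(arr, grid$affine, "V_per_m")
  })
}

test_that("coverage mask applies the inclusive at-least rule", {
  g <- tiny_grid(4)
  # one interesting voxel; 10 fields
  vals <- matrix(0, 10, 3)
  vals[, 1] <- 300                         # all above -> 1
  vals[1:5, 2] <- 300                      # exactly half -> 1 (inclusive)
  vals[1:4, 3] <- 300                      # 4 of 10 -> 0
  m <- coverage_mask(make_fields(vals, g), 200, 0.5)
  expect_equal(m$data[1:3], c(1, 1, 0))
  expect_error(coverage_mask(list(), 200, 0.5), "non-empty")
})

test_that("raising the magnitude threshold never grows the mask", {
  fx <- cached_spot_fixture()
  pool <- pooled_efields(fx$cohort)
  left <- pool$volumes[pool$hemisphere == "left"]
  masks <- lapply(c(180, 200, 220), function(th)
    coverage_mask(left, th, 0.5)$data)
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
  expect_gt(sum(masks[[1]]), 0)
})

test_that("a voxel driving outcomes monotonically maps to rho 1", {
  g <- tiny_grid(4)
  set.seed(61)
  n <- 12
  vals <- matrix(runif(n * 2, 250, 1000), n, 2)
  fields <- make_fields(vals, g)
  improvement <- 2 * vals[, 1] + 5         # strictly increasing in voxel 1
  m <- sweet_spot_map(fields, improvement, magnitude_threshold = 200,
                      coverage_fraction = 0.5)
  expect_equal(m$r_map$data[1], 1)
  expect_equal(m$r_map$data[3], 0)         # outside mask
  expect_equal(m$mask$data[1], 1)
})

test_that("voxel-wise maps match an independent per-voxel oracle", {
  g <- tiny_grid(4)
  set.seed(62)
  n <- 11
  vals <- matrix(runif(n * 5, 150, 600), n, 5)
  fields <- make_fields(vals, g)
  improvement <- rnorm(n, 50, 10)
  m <- sweet_spot_map(fields, improvement, 200, 0.5)
  for (vx in which(m$mask$data[1:5] == 1)) {
    o <- oracle_spearman(vals[, vx], improvement)
    expect_equal(m$r_map$data[vx], o$rho, tolerance = 1e-12)
    expect_equal(m$p_map$data[vx], o$p, tolerance = 1e-9)
  }
})

test_that("null outcomes give a calibrated fraction of small p-values", {
  fx <- cached_spot_fixture()
  pool <- pooled_efields(fx$cohort)
  vols <- pool$volumes[pool$hemisphere == "left"]   # 20 fields, one per patient
  set.seed(63)
  hits <- 0L; total <- 0L
  for (rep in 1:25) {
    y <- rnorm(20)
    m <- sweet_spot_map(vols, y, 200, 0.5)
    pvals <- m$p_map$data[m$mask$data == 1]
    hits <- hits + sum(pvals < 0.05)
    total <- total + length(pvals)
  }
  rate <- hits / total
  # voxels are spatially correlated, so allow a generous band around 0.05
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})

test_that("constant improvements are refused", {
  g <- tiny_grid(4)
  vals <- matrix(runif(10, 300, 400), 5, 2)
  expect_error(sweet_spot_map(make_fields(vals, g), rep(10, 5)),
               "constant")
})

test_that("sweet spot scores follow the voxel-average formula", {
  g <- tiny_grid(4)
  model_grid <- g
  # single-voxel mask with r = 0.5
  r_map <- array(0, dim(g$data)); r_map[1] <- 0.5
  mask <- array(0, dim(g$data)); mask[1] <- 1
  model <- structure(list(
    r_map = voxel_volume(r_map, g$affine, "correlation"),
    p_map = voxel_volume(array(0, dim(g$data)), g$affine),
    mask = voxel_volume(mask, g$affine, "count"),
    params = list(magnitude_threshold = 200, coverage_fraction = 0.5,
                  mirror = "none", aggregate = "efield"),
    n_obs = 10, n_patients = 5), class = "sweetspot_model")
  f100 <- array(0, dim(g$data)); f100[1] <- 100
  v100 <- voxel_volume(f100, g$affine, "V_per_m")
  expect_equal(predict(model, list(left = v100, right = v100)), 50)
  zero <- voxel_volume(array(0, dim(g$data)), g$affine, "V_per_m")
  expect_equal(predict(model, list(left = zero)), 0)
  # linearity in field magnitude
  v3 <- voxel_volume(3 * f100, g$affine, "V_per_m")
  expect_equal(predict(model, list(left = v3)),
               3 * predict(model, list(left = v100)))
})

test_that("scores equal the brute-force voxel loop on random models", {
  g <- tiny_grid(5)
  set.seed(64)
  for (i in 1:10) {
    n <- 10
    vals <- matrix(runif(n * 8, 100, 500), n, 8)
    fields <- make_fields(vals, g)
    improvement <- rnorm(n, 50, 12)
    m <- sweet_spot_map(fields, improvement, 150, 0.5)
    pat <- make_fields(matrix(runif(16, 0, 400), 2, 8), g)
    got <- predict(m, list(left = pat[[1]], right = pat[[2]]))
    want <- oracle_sweet_score(list(pat[[1]], pat[[2]]), m$r_map$data,
                               m$mask$data)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("r maps are invariant under monotone outcome transforms", {
  g <- tiny_grid(4)
  set.seed(65)
  vals <- matrix(runif(12 * 3, 150, 600), 12, 3)
  fields <- make_fields(vals, g)
  y <- rnorm(12, 50, 10)
  m1 <- sweet_spot_map(fields, y, 140, 0.5)
  m2 <- sweet_spot_map(fields, 3 * exp(y / 20) - 7, 140, 0.5)
  expect_equal(m1$r_map$data, m2$r_map$data, tolerance = 1e-12)
})

test_that("mirrored mapping folds right-hemisphere fields across x = 0", {
  fx <- cached_spot_fixture()
  m <- sweet_spot_map(fx$cohort, mirror = "left")
  pk <- sweet_spot_peak(m)
  expect_lt(pk[1], 0)                      # peak on the left
  d <- sqrt(sum((pk - fx$scene$nucleus$left$center)^2))
  expect_lt(d, 3)
})

test_that("patient-level aggregation uses one observation per patient", {
  fx <- cached_spot_fixture()
  m <- sweet_spot_map(fx$cohort, mirror = "left", aggregate = "patient")
  expect_equal(m$n_obs, length(fx$cohort))
})
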