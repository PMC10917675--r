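# small deterministic fixture: straight streamlines at graded distances from
# a column of point-like field sources
fiber_fixture <- function(n_fields = 12, seed = 71) {
  g <- tiny_grid(17)     # 17^3 at 1 mm, centres -8..8
  set.seed(seed)
  sl <- list(
    through = matrix(c(0, 0, -6, 0, 0, 6), ncol = 3, byrow = TRUE),
    near = matrix(c(2, 0, -6, 2, 0, 6), ncol = 3, byrow = TRUE),
    far = matrix(c(7, 7, -6, 7, 7, 6), ncol = 3, byrow = TRUE),
    outside = matrix(c(60, 60, -6, 60, 60, 6), ncol = 3, byrow = TRUE))
  set <- streamline_set(unname(sl))
  amps <- runif(n_fields, 1, 4)
  fields <- lapply(amps, function(a)
    simulate_efield(c(0, 0, 0), a, g))
  list(grid = g, set = set, fields = fields, amps = amps)
}

test_that("candidate selection applies the strict more-than rule", {
  fx <- fiber_fixture()
  pk <- peak_matrix(fx$set, fx$fields)
  # streamline through every hotspot is always a candidate
  cand <- select_candidates(fx$set, fx$fields, 800, 0.005, peaks = pk)
  expect_true(cand[1])
  expect_false(cand[4])                    # never enters any field
  # boundary: exactly the threshold fraction of fields above -> not candidate
  vals <- matrix(0, 1, 200); vals[1, 1] <- 900   # 1/200 fields = 0.5 %
  pk2 <- structure(list(values = vals, streamline_index = 1L, step_mm = 0.5),
                   class = "peak_matrix")
  expect_false(select_candidates(NULL, NULL, 800, 0.005, peaks = pk2))
  vals[1, 2] <- 900                               # 2/200 = 1 % > 0.5 %
  pk3 <- structure(list(values = vals, streamline_index = 1L, step_mm = 0.5),
                   class = "peak_matrix")
  expect_true(select_candidates(NULL, NULL, 800, 0.005, peaks = pk3))
})

test_that("raising the candidate magnitude never grows the candidate set", {
  fx <- fiber_fixture()
  pk <- peak_matrix(fx$set, fx$fields)
  sets <- lapply(c(400, 800, 1600), function(th)
    select_candidates(fx$set, fx$fields, th, 0.005, peaks = pk))
  expect_true(all(sets[[2]] <= sets[[1]]))
  expect_true(all(sets[[3]] <= sets[[2]]))
})

test_that("peak matrix equals per-point brute force and scales with the field", {
  fx <- fiber_fixture()
  pk <- peak_matrix(fx$set, fx$fields, step_mm = 0.5)
  # brute force: resample then interpolate point by point
  for (s in 1:4) for (e in c(1, 5)) {
    pts <- resample_polyline(fx$set$streamlines[[s]], 0.5)
    want <- max(oracle_sample_volume(fx$fields[[e]], pts))
    expect_equal(pk$values[s, e], want, tolerance = 1e-9)
  }
  expect_true(all(pk$values[4, ] == 0))
  # constant field gives a constant column for intersecting streamlines
  cf <- voxel_volume(array(42, dim(fx$grid$data)), fx$grid$affine, "V_per_m")
  pkc <- peak_matrix(fx$set, list(cf))
  expect_equal(pkc$values[1:3, 1], rep(42, 3))
  # doubling a field doubles its column
  dbl <- voxel_volume(2 * fx$fields[[1]]$data, fx$grid$affine, "V_per_m")
  pk2 <- peak_matrix(fx$set, list(dbl))
  expect_equal(pk2$values[, 1], 2 * pk$values[, 1], tolerance = 1e-12)
})

test_that("a streamline whose peaks drive outcomes gets r = 1 and is sweet", {
  fx <- fiber_fixture()
  pk <- peak_matrix(fx$set, fx$fields)
  improvement <- 10 + 0.05 * pk$values[1, ]   # strictly increasing
  fm <- fiber_filter(pk, fx$set, improvement)
  expect_equal(fm$r[1], 1)
  expect_true(1 %in% fm$sweet_ids)
  expect_true(all(fm$r[fm$sweet_ids] >= fm$sweet_threshold))
  expect_true(is.na(fm$r[4]))               # non-candidate: no correlation
  expect_equal(fm$certainty[1], -log10(fm$p[1]))
})

test_that("the sweet threshold keeps the top 1% of distinct candidate r values", {
  set.seed(72)
  n_obs <- 20
  vals <- matrix(runif(200 * n_obs, 900, 1000), 200, n_obs)
  pk <- structure(list(values = vals, streamline_index = 1:200,
                       step_mm = 0.5), class = "peak_matrix")
  sl <- lapply(1:200, function(i) matrix(rnorm(6), 2, 3))
  fm <- fiber_filter(pk, streamline_set(sl), rnorm(n_obs),
                     candidate_magnitude = 800, candidate_fraction = 0.005)
  expect_true(all(fm$candidate))
  expect_length(fm$sweet_ids, 2)            # top 1 % of 200 distinct values
  expect_equal(fm$sweet_ids, order(fm$r, decreasing = TRUE)[1:2])
})

test_that("fiber r scores follow the weighted peak-fraction rule", {
  fx <- fiber_fixture()
  pk <- peak_matrix(fx$set, fx$fields)
  improvement <- 10 + 0.05 * pk$values[1, ] + rnorm(12, 0, 0.5)
  fm <- fiber_filter(pk, fx$set, improvement, sweet_top_fraction = 0.5)
  expect_gte(length(fm$sweet_ids), 1)
  # a compact field whose support misses every sweet streamline scores zero
  arr <- array(0, dim(fx$grid$data)); arr[17, 17, 1] <- 500
  far_field <- voxel_volume(arr, fx$grid$affine, "V_per_m")
  expect_equal(predict(fm, list(left = far_field)), 0, tolerance = 1e-12)
  # random instances match the sort-and-sum oracle
  set.seed(73)
  for (i in 1:5) {
    f <- simulate_efield(runif(3, -2, 2), runif(1, 1, 3), fx$grid)
    got <- predict(fm, list(left = f))
    pks <- peak_matrix(fm$sweet_streamlines, list(f))$values[, 1]
    want <- oracle_fiber_score_field(fm$r[fm$sweet_ids], pks, 0.05)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the peak-fraction count is ceil with a floor of one", {
  # 20 intersected values at default 5 %: ceil(1) = 1, the single largest
  model <- structure(list(
    r = rep(0.5, 20), sweet_ids = 1:20,
    sweet_streamlines = streamline_set(
      lapply(seq(-4.75, 4.75, by = 0.5), function(x)
        matrix(c(x, 0, -4, x, 0, 4), 2, 3, byrow = TRUE))),
    params = list(score_peak_fraction = 0.05, step_mm = 0.5,
                  mirror = "none")),
    class = "fiber_model")
  g <- tiny_grid(21)
  f <- simulate_efield(c(0, 0, 0), 2, g)
  pks <- peak_matrix(model$sweet_streamlines, list(f))$values[, 1]
  expect_true(all(pks > 0))
  got <- predict(model, list(left = f))
  expect_equal(got, max(0.5 * pks))
})

test_that("empty sweet subsets refuse to score", {
  model <- structure(list(r = numeric(0), sweet_ids = integer(0)),
                     class = "fiber_model")
  expect_error(predict(model, list()), "empty sweet subset")
})

test_that("fiber r values are invariant to outcome transforms and order", {
  fx <- fiber_fixture()
  pk <- peak_matrix(fx$set, fx$fields)
  set.seed(74)
  y <- rnorm(12, 50, 10)
  f1 <- fiber_filter(pk, fx$set, y, candidate_magnitude = 100)
  f2 <- fiber_filter(pk, fx$set, 2 * exp(y / 30), candidate_magnitude = 100)
  expect_equal(f1$r, f2$r, tolerance = 1e-12)
  # reordering observations consistently leaves r unchanged
  ord <- sample(12)
  pk_perm <- structure(list(values = pk$values[, ord],
                            streamline_index = pk$streamline_index,
                            step_mm = 0.5), class = "peak_matrix")
  f3 <- fiber_filter(pk_perm, fx$set, y[ord], candidate_magnitude = 100)
  expect_equal(f3$r, f1$r, tolerance = 1e-12)
})

test_that("specificity ratios follow the cross-model mean formula", {
  mk <- function(r) structure(list(r = r), class = "fiber_model")
  models <- list(a = mk(c(0.6, 0, 0.5)),
                 b = mk(c(0.2, 0.1, 0)),
                 c = mk(c(0.1, 0.2, 0)),
                 d = mk(c(0.3, -0.3, 0)))
  sp <- specificity_ratio(models)
  expect_equal(sp$a[1], 0.6 / mean(c(0.2, 0.1, 0.3)))   # 3.0
  expect_equal(sp$a[2], 0)                               # own r = 0
  expect_true(is.na(sp$a[3]))                            # others mean 0
  expect_error(specificity_ratio(models["a"]), "at least 2")
})

test_that("Gaussian contact seeding selects by Mahalanobis distance", {
  set.seed(75)
  sl <- streamline_set(list(
    matrix(c(0, 0, -5, 0, 0, 5), 2, 3, byrow = TRUE),
    matrix(c(6, 0, -5, 6, 0, 5), 2, 3, byrow = TRUE)))
  # degenerate cloud at a point: ridge kicks in, only the passing line kept
  pts0 <- matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE)
  expect_message(res0 <- gaussian_contact_control(pts0, sl, 2), "ridge")
  expect_equal(res0$selected, c(TRUE, FALSE))
  # infinite cut selects everything
  pts <- matrix(rnorm(30), ncol = 3)
  res <- gaussian_contact_control(pts, sl, Inf)
  expect_true(all(res$selected))
  # rotation equivariance for an isotropic-ish cloud
  contacts <- matrix(rnorm(60, sd = 1.5), ncol = 3)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- function(m) t(R %*% t(m))
  sl_rot <- streamline_set(lapply(sl$streamlines, rot))
  a <- gaussian_contact_control(contacts, sl, 2)
  b <- gaussian_contact_control(rot(contacts), sl_rot, 2)
  expect_equal(a$min_distance, b$min_distance, tolerance = 1e-6)
  expect_identical(a$selected, b$selected)
})
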