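# Small in-code fixtures shared across test files.

# random axis-aligned-ish invertible affine with jittered spacing and origin
random_affine <- function() {
  A <- diag(4)
  A[1:3, 1:3] <- diag(runif(3, 0.4, 2.5)) + matrix(runif(9, -0.05, 0.05), 3)
  A[1:3, 4] <- runif(3, -30, 30)
  A
}

random_volume <- function(shape = c(6, 7, 5), affine = random_affine(),
                          units = "unitless") {
  voxel_volume(array(runif(prod(shape)), shape), affine, units)
}

# tiny uniform-grid template centred at the origin
tiny_grid <- function(n = 10, voxel = 1) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -voxel * (n - 1) / 2
  voxel_volume(array(0, c(n, n, n)), aff)
}

# coarse phantom for fast cross-validation tests
coarse_scene <- function(seed = 1) {
  phantom_scene(seed = seed, voxel_mm = 1.5, n_per_group = 10)
}

# round a double vector through its float32 representation
as.single_round <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4)
  bytes <- rawConnectionValue(con)
  close(con)
  con2 <- rawConnection(bytes)
  out <- readBin(con2, "double", n = length(x), size = 4)
  close(con2)
  out
}

# one mid-sized cohort + model reused by several test files
cached_spot_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scene <- phantom_scene(seed = 401, n_per_group = 10)
      truth <- simulation_truth("spot",
                                planted_spot_center =
                                  scene$nucleus$left$center,
                                seed = 402)
      coh <- make_cohort(scene, 20, truth)
      cache <<- list(scene = scene, truth = truth, cohort = coh)
    }
    cache
  }
})
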