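test_that("permutation p: degenerate and boundary behaviour", {
  y <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 7, 0.2) * 10
  # estimates identical to outcomes: no permutation beats |rho| = 1 except ties
  res <- permutation_p(y, y, n_iter = 5000, seed = 4)
  expect_equal(res$rho_obs, 1)
  expect_equal(res$p, 1 / 5001)
  # n_iter = 1 admits only 1/2 or 1
  p1 <- permutation_p(rnorm(10), rnorm(10), n_iter = 1, seed = 5)$p
  expect_true(p1 %in% c(0.5, 1))
  # seed reproducibility, caller RNG untouched
  set.seed(1)
  x <- rnorm(12); yy <- rnorm(12)
  before <- .Random.seed
  a <- permutation_p(x, yy, n_iter = 200, seed = 9)
  expect_identical(.Random.seed, before)
  b <- permutation_p(x, yy, n_iter = 200, seed = 9)
  expect_identical(a$p, b$p)
})

test_that("permutation p is approximately uniform under the null", {
  set.seed(81)
  ps <- vapply(1:200, function(i)
    permutation_p(rnorm(15), rnorm(15), n_iter = 99, seed = i)$p, 0)
  rate <- mean(ps <= 0.05)
  # binomial 95% band around 0.05 for 200 draws
  expect_gte(rate, 4 / 200)
  expect_lte(rate, 16 / 200)
})

test_that("permutation p converges with the iteration count", {
  set.seed(82)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)        # moderate association
  p1 <- permutation_p(x, y, n_iter = 5000, seed = 1)$p
  p2 <- permutation_p(x, y, n_iter = 50000, seed = 2)$p
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("fold assignment partitions the cohort with near-equal sizes", {
  fx <- cached_spot_fixture()
  co <- fx$cohort
  fit <- function(train) sweet_spot_map(train, mirror = "left")
  prd <- function(m, rec) predict(m, rec)
  cv <- kfold_cv(co, fit, prd, k = 5, n_permutations = 200, seed = 3)
  expect_setequal(names(cv$fold_of_patient), names(improvements(co)))
  sizes <- table(cv$fold_of_patient)
  expect_length(sizes, 5)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_gt(cv$p_perm, 0)
  expect_lte(cv$p_perm, 1)
  # determinism: same seed, same folds and estimates
  cv2 <- kfold_cv(co, fit, prd, k = 5, n_permutations = 200, seed = 3)
  expect_identical(cv$fold_of_patient, cv2$fold_of_patient)
  expect_identical(cv$estimates, cv2$estimates)
  expect_identical(cv$p_perm, cv2$p_perm)
  # different seed, different folds
  cv3 <- kfold_cv(co, fit, prd, k = 5, n_permutations = 200, seed = 4)
  expect_false(identical(cv$fold_of_patient, cv3$fold_of_patient))
})

test_that("leave-one-out produces a partition of singletons", {
  fx <- cached_spot_fixture()
  co <- subset_cohort(fx$cohort, 1:8)
  cv <- kfold_cv(co, function(train) sweet_spot_map(train, mirror = "left"),
                 function(m, rec) predict(m, rec),
                 k = 8, n_permutations = 50, seed = 2)
  expect_equal(sort(unique(cv$fold_of_patient)), 1:8)
  expect_true(all(table(cv$fold_of_patient) == 1))
})

test_that("held-out outcomes never influence fitted fold models", {
  fx <- cached_spot_fixture()
  co <- fx$cohort
  fit <- function(train) sweet_spot_map(train, mirror = "left")
  prd <- function(m, rec) predict(m, rec)
  cv <- kfold_cv(co, fit, prd, k = 5, n_permutations = 50, seed = 7)
  # corrupt one patient's outcome; their own estimate must be unchanged
  victim <- names(cv$fold_of_patient)[1]
  co2 <- co
  idx <- which(vapply(co2$records, `[[`, "", "patient_id") == victim)
  co2$records[[idx]]$improvement_pct <- 999
  cv2 <- kfold_cv(co2, fit, prd, k = 5, n_permutations = 50, seed = 7)
  expect_identical(cv$fold_of_patient, cv2$fold_of_patient)
  expect_equal(cv$estimates[[victim]], cv2$estimates[[victim]],
               tolerance = 1e-12)
})

test_that("refit-permutation CV reproduces the generic fold estimates", {
  fx <- cached_spot_fixture()
  co <- fx$cohort
  cv1 <- kfold_cv(co, function(tr) sweet_spot_map(tr, mirror = "left"),
                  function(m, rec) predict(m, rec),
                  k = 5, n_permutations = 20, seed = 13)
  cv2 <- sweet_spot_cv(co, k = 5, n_permutations = 20, seed = 13,
                       mirror = "left")
  expect_identical(cv1$fold_of_patient, cv2$fold_of_patient)
  expect_equal(cv1$estimates, cv2$estimates, tolerance = 1e-10)
  expect_equal(cv1$rho_obs, cv2$rho_obs, tolerance = 1e-10)
  expect_identical(cv2$scheme, "refit")
  # determinism of the refit path
  cv3 <- sweet_spot_cv(co, k = 5, n_permutations = 20, seed = 13,
                       mirror = "left")
  expect_identical(cv2$p_perm, cv3$p_perm)
})

test_that("unfittable folds are reported with the fold number", {
  fx <- cached_spot_fixture()
  co <- fx$cohort
  fit <- function(train) stop("mask empty")
  expect_error(kfold_cv(co, fit, function(m, r) 0, k = 5, seed = 1),
               "fold 1")
})

test_that("cross-disorder matrices: identical inputs are symmetric", {
  fx <- cached_spot_fixture()
  co <- fx$cohort
  m <- sweet_spot_map(co, mirror = "left")
  res <- cross_disorder_matrix(list(a = m, b = m), list(a = co, b = co))
  expect_equal(res$rho[1, 1], res$rho[2, 2])
  expect_equal(res$rho[1, 2], res$rho[2, 1])
  # single disorder: 1x1 equal to the in-sample fit
  one <- cross_disorder_matrix(list(a = m), list(a = co))
  insample <- spearman(predict(m, co), improvements(co))
  expect_equal(one$rho[1, 1], insample$rho)
  expect_equal(one$p[1, 1], insample$p)
})

test_that("equality-of-proportions tests match closed-form chi-square", {
  eq <- equality_of_proportions(c(5, 5), c(10, 10))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # hand-computed 2x2 Pearson chi-square for 90/100 vs 10/100
  got <- equality_of_proportions(c(90, 10), c(100, 100))
  o <- matrix(c(90, 10, 10, 90), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(got$chi2, sum((o - e)^2 / e), tolerance = 1e-9)
  expect_equal(got$pairwise$chi2[1], got$chi2)
  # four equal groups
  eq4 <- equality_of_proportions(rep(7, 4), rep(20, 4))
  expect_equal(eq4$p, 1)
  expect_equal(nrow(eq4$pairwise), 6)
  expect_error(equality_of_proportions(c(1, 2), c(10, 0)), "> 0")
})

test_that("two-sample t-tests match the closed-form pooled statistic", {
  a <- c(5.1, 4.9, 6.2, 5.8, 5.5)
  b <- c(4.2, 4.8, 4.4, 4.9, 4.1, 4.6)
  got <- two_sample_ttest(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(got$t, tt, tolerance = 1e-12)
  expect_equal(got$df, length(a) + length(b) - 2)
  expect_equal(got$p, 2 * pt(-abs(tt), got$df), tolerance = 1e-12)
  same <- two_sample_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # large location shift is detected
  set.seed(91)
  expect_lt(two_sample_ttest(rnorm(100), rnorm(100, 1))$p, 0.001)
  # Welch flag changes the degrees of freedom
  expect_lt(two_sample_ttest(c(rnorm(5), 10), rnorm(50), welch = TRUE)$df,
            length(a) + 50 - 2)
  expect_error(two_sample_ttest(1, rnorm(5)), "at least 2")
})
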