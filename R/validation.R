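#' Permutation p-value for a Spearman association
#'
#' Two-sided: outcomes are permuted `n_iter` times, and
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_iter)` (add-one correction,
#' so p is never 0 and lies in (0, 1]).
#'
#' @param estimates model-based outcome estimates.
#' @param outcomes empirical outcomes.
#' @param n_iter number of permutations (default 5000).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return list with `p`, `rho_obs`, `n_iter`, `seed`.
#' @export
permutation_p <- function(estimates, outcomes, n_iter = 5000, seed = 1) {
  stopifnot(length(estimates) == length(outcomes), n_iter >= 1)
  n <- length(outcomes)
  rx <- rank(estimates)
  ry <- rank(outcomes)
  rho_obs <- rank_pearson(rx, ry)
  hits <- with_preserved_rng(seed, {
    h <- 0L
    for (i in seq_len(n_iter))
      h <- h + (abs(rank_pearson(rx, ry[sample.int(n)])) >=
                  abs(rho_obs) - 1e-12)
    h
  })
  list(p = (1 + hits) / (1 + n_iter), rho_obs = rho_obs,
       n_iter = as.integer(n_iter), seed = as.integer(seed))
}

#' K-fold cross-validation of a mapping model
#'
#' The cohort is split into `k` folds (seeded uniform shuffle, contiguous
#' chunks, sizes differing by at most one). In each fold the model is fitted
#' on the training four-fifths only — coverage masks and candidate selections
#' are recomputed inside `fit_fun`, so nothing leaks from held-out patients —
#' and held-out patients are scored with `predict_fun`. Out-of-sample
#' estimates are then Spearman-correlated with empirical improvements and the
#' p-value obtained by permutation.
#'
#' By default outcome labels are permuted at the final correlation stage with
#' the estimates held fixed; set `refit_permutations = TRUE` to refit every
#' fold model per permutation (much slower).
#'
#' @param cohort a [cohort()].
#' @param fit_fun function(training_cohort) -> model.
#' @param predict_fun function(model, patient_record) -> numeric score.
#' @param k number of folds (default 5); `k = n` is leave-one-out.
#' @param n_permutations permutation count for the p-value (default 5000).
#' @param seed integer master seed (folds and permutations).
#' @param refit_permutations refit fold models per permutation (slow mode).
#' @return object of class `cv_report`: `fold_of_patient`, `estimates`,
#'   `rho_obs`, `p_perm`, `n_permutations`, `k`, `seed`.
#' @export
kfold_cv <- function(cohort, fit_fun, predict_fun, k = 5,
                     n_permutations = 5000, seed = 1,
                     refit_permutations = FALSE) {
  stopifnot(inherits(cohort, "dbs_cohort"))
  n <- length(cohort$records)
  if (k < 2 || k > n) stop("need 2 <= k <= n (k = n is leave-one-out)")
  folds <- with_preserved_rng(seed, make_folds(n, k))
  imp <- improvements(cohort)
  run_once <- function(outc) {
    est <- numeric(n)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train <- subset_cohort(cohort, -test_idx)
      if (refit_permutations) {
        # outcomes enter fitting; rebuild training records with permuted labels
        for (i in seq_along(train$records)) {
          j <- setdiff(seq_len(n), test_idx)[i]
          train$records[[i]]$improvement_pct <- outc[j]
        }
      }
      model <- tryCatch(fit_fun(train), error = function(e)
        stop("fold ", f, ": model could not be fitted (",
             conditionMessage(e), ")", call. = FALSE))
      for (i in test_idx) est[i] <- predict_fun(model, cohort$records[[i]])
    }
    est
  }
  estimates <- run_once(imp)
  names(estimates) <- names(imp)
  if (refit_permutations) {
    rho_obs <- spearman(estimates, imp)$rho
    rhop <- with_preserved_rng(seed + 1L, vapply(seq_len(n_permutations),
      function(i) {
        yperm <- imp[sample.int(n)]
        spearman(run_once(yperm), yperm)$rho
      }, 0))
    p <- (1 + sum(abs(rhop) >= abs(rho_obs) - 1e-12)) / (1 + n_permutations)
    perm <- list(p = p, rho_obs = rho_obs)
  } else {
    perm <- permutation_p(estimates, imp, n_iter = n_permutations,
                          seed = seed + 1L)
  }
  structure(list(fold_of_patient = stats::setNames(folds, names(imp)),
                 estimates = estimates, rho_obs = perm$rho_obs,
                 p_perm = perm$p, n_permutations = as.integer(n_permutations),
                 k = as.integer(k), seed = as.integer(seed),
                 refit_permutations = refit_permutations),
            class = "cv_report")
}

make_folds <- function(n, k) {
  ord <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- integer(n)
  folds[ord] <- rep(seq_len(k), sizes)
  folds
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: out-of-sample Spearman R = %.3f, permutation p = %.4g (%d iterations, seed %d)\n",
    x$k, x$rho_obs, x$p_perm, x$n_permutations, x$seed))
  invisible(x)
}

#' Fivefold cross-validation of a sweet-spot model with exact refit
#' permutation inference
#'
#' Specialised, fully calibrated counterpart of [kfold_cv()] for the
#' voxel-wise sweet-spot pipeline. Naive permutation of outcomes against
#' fixed cross-validated estimates is anti-conservative here: held-out
#' estimates depend on the training outcomes of other folds, inflating the
#' variance of the observed correlation relative to an exchangeable null.
#' This function therefore refits every fold model under every permutation.
#' That is tractable because only the rank-correlation against outcomes
#' depends on the permuted labels: coverage masks and per-fold magnitude
#' matrices are outcome-free and cached once, so a full refit costs one
#' matrix product per fold.
#'
#' @param cohort a [cohort()] with E-fields.
#' @param k number of folds (default 5).
#' @param n_permutations permutation count (default 5000).
#' @param seed integer master seed (folds and permutations).
#' @param magnitude_threshold,coverage_fraction,mirror passed to the fold
#'   models as in [sweet_spot_map()].
#' @return a `cv_report` (as from [kfold_cv()]) whose `p_perm` comes from
#'   full-refit permutations; `scheme = "refit"`.
#' @export
sweet_spot_cv <- function(cohort, k = 5, n_permutations = 5000, seed = 1,
                          magnitude_threshold = 200, coverage_fraction = 0.5,
                          mirror = "none") {
  stopifnot(inherits(cohort, "dbs_cohort"))
  n <- length(cohort$records)
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  y <- improvements(cohort)
  if (stats::sd(y) == 0) stop("improvement vector is constant")
  folds <- with_preserved_rng(seed, make_folds(n, k))
  pool <- pooled_efields(cohort)
  if (mirror != "none")
    pool$volumes <- lapply(pool$volumes, orient_field, mirror = mirror)
  obs_pat <- match(pool$patient_id, names(y))
  # outcome-free per-fold caches: mask, centred rank matrix, held-out fields
  fold_cache <- lapply(seq_len(k), function(f) {
    tr_obs <- which(!(obs_pat %in% which(folds == f)))
    te_pat <- which(folds == f)
    mask <- tryCatch(
      coverage_mask(pool$volumes[tr_obs], magnitude_threshold,
                    coverage_fraction),
      error = function(e) stop("fold ", f, ": model could not be fitted (",
                               conditionMessage(e), ")", call. = FALSE))
    vox <- which(mask$data == 1)
    if (length(vox) == 0L)
      stop("fold ", f, ": model could not be fitted (empty coverage mask)",
           call. = FALSE)
    X <- vapply(pool$volumes[tr_obs], function(v) v$data[vox],
                numeric(length(vox)))
    rX <- apply(matrix(t(X), nrow = length(tr_obs)), 2L, rank)
    rX <- matrix(rX, nrow = length(tr_obs))
    cX <- rX - rep(colMeans(rX), each = nrow(rX))
    test_fields <- lapply(te_pat, function(pi) {
      vs <- pool$volumes[obs_pat == pi]
      vapply(vs, function(v) v$data[vox], numeric(length(vox)))
    })
    list(train_obs = tr_obs, test_pat = te_pat, cX = cX,
         ssx = colSums(cX^2), nvox = length(vox),
         test_fields = test_fields)
  })
  estimate_all <- function(yv) {
    est <- numeric(n)
    for (fc in fold_cache) {
      ry <- rank(yv[obs_pat[fc$train_obs]])
      cy <- ry - mean(ry)
      den <- sqrt(fc$ssx * sum(cy^2))
      r_vec <- ifelse(den > 0, as.numeric(crossprod(fc$cX, cy)) / den, 0)
      for (j in seq_along(fc$test_pat))
        est[fc$test_pat[j]] <-
          mean(colSums(fc$test_fields[[j]] * r_vec) / fc$nvox)
    }
    est
  }
  estimates <- stats::setNames(estimate_all(y), names(y))
  rho_obs <- rank_pearson(rank(estimates), rank(y))
  hits <- with_preserved_rng(seed + 1L, {
    h <- 0L
    for (b in seq_len(n_permutations)) {
      yp <- y[sample.int(n)]
      names(yp) <- names(y)
      rb <- rank_pearson(rank(estimate_all(yp)), rank(yp))
      h <- h + (abs(rb) >= abs(rho_obs) - 1e-12)
    }
    h
  })
  structure(list(fold_of_patient = stats::setNames(folds, names(y)),
                 estimates = estimates, rho_obs = rho_obs,
                 p_perm = (1 + hits) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 k = as.integer(k), seed = as.integer(seed),
                 scheme = "refit"),
            class = "cv_report")
}

#' Cross-disorder specificity matrix
#'
#' Every disorder's fitted model is used to estimate outcomes in every
#' disorder's cohort; each cell holds the Spearman correlation (and p)
#' between those estimates and the empirical improvements. A specific model
#' explains outcome variance on its own diagonal cell but not off-diagonal.
#'
#' @param models named list of fitted models (one per disorder).
#' @param cohorts named list of [cohort()]s, same names/order.
#' @param predict_fun function(model, patient_record) -> score; defaults to
#'   [predict()] dispatch.
#' @return object of class `specificity_matrix`: `rho` and `p` matrices
#'   (model rows, cohort columns).
#' @export
cross_disorder_matrix <- function(models, cohorts,
                                  predict_fun = function(m, rec)
                                    stats::predict(m, rec)) {
  stopifnot(is.list(models), is.list(cohorts),
            length(models) == length(cohorts), length(models) >= 1L)
  nm <- names(models)
  rho <- matrix(NA_real_, length(models), length(cohorts),
                dimnames = list(model = nm, cohort = names(cohorts)))
  p <- rho
  for (i in seq_along(models)) for (j in seq_along(cohorts)) {
    est <- vapply(cohorts[[j]]$records,
                  function(rec) predict_fun(models[[i]], rec), 0)
    sp <- spearman(est, improvements(cohorts[[j]]))
    rho[i, j] <- sp$rho
    p[i, j] <- sp$p
  }
  structure(list(rho = rho, p = p), class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("Cross-disorder specificity (Spearman R; models in rows, cohorts in columns):\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' K-sample and pairwise tests of equality of proportions
#'
#' Chi-square test that all groups share one success proportion, plus all
#' pairwise 2x2 comparisons (two-sided, no continuity correction by default).
#'
#' @param successes integer vector of success counts.
#' @param totals integer vector of totals, all > 0.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `chi2`, `df`, `p`, and `pairwise` data.frame.
#' @export
equality_of_proportions <- function(successes, totals, correct = FALSE) {
  stopifnot(length(successes) == length(totals))
  if (any(totals <= 0)) stop("all totals must be > 0")
  if (any(successes < 0 | successes > totals))
    stop("successes must lie in [0, totals]")
  ht <- suppressWarnings(stats::prop.test(successes, totals,
                                          correct = correct))
  pairs <- utils::combn(length(successes), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   chi2 = NA_real_, p = NA_real_)
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    h <- suppressWarnings(stats::prop.test(successes[c(i, j)],
                                           totals[c(i, j)],
                                           correct = correct))
    pw$chi2[c0] <- unname(h$statistic)
    pw$p[c0] <- h$p.value
  }
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, pairwise = pw)
}

#' Independent two-sample t-test
#'
#' Pooled-variance by default (the classical independent-samples test);
#' `welch = TRUE` drops the equal-variance assumption.
#'
#' @param a,b numeric vectors, each with >= 2 values and nonzero variance.
#' @param welch use the Welch unequal-variance variant.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both groups are constant; t undefined")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
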