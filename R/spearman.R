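#' Spearman rank correlation with small-sample exact inference
#'
#' Average ranks for ties; the correlation is the product-moment correlation
#' of the rank vectors. Two-sided p-values use the t approximation for
#' `n >= 10`; below that, exact enumeration of all `n!` permutations when
#' `n <= 7`, otherwise 10,000 Monte-Carlo permutations (internally seeded so
#' the result is reproducible; the caller's RNG state is untouched).
#'
#' @param x,y numeric vectors of equal length `>= 4`, neither constant.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- rank_pearson(rx, ry)
  list(rho = rho, p = spearman_p(rho, rx, ry))
}

rank_pearson <- function(rx, ry) {
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) return(0)
  min(1, max(-1, sum(cx * cy) / den))
}

spearman_p <- function(rho, rx, ry) {
  n <- length(rx)
  if (n >= 10L) return(spearman_p_t(rho, n))
  if (n <= 7L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(ix) rank_pearson(rx, ry[ix]))
    return(mean(abs(rhos) >= abs(rho) - 1e-12))
  }
  # n = 8 or 9: Monte-Carlo permutations under a private, restored RNG state
  with_preserved_rng(2718L, {
    hits <- 0L
    for (i in seq_len(10000L))
      hits <- hits + (abs(rank_pearson(rx, ry[sample.int(n)])) >=
                        abs(rho) - 1e-12)
    (1 + hits) / (1 + 10000L)
  })
}

spearman_p_t <- function(rho, n) {
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# evaluate expr under set.seed(seed), restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Column-wise Spearman correlation of a matrix against one outcome vector
#'
#' The mass-univariate workhorse behind sweet-spot maps and fiber filtering:
#' every column of `X` (a voxel's or a streamline's magnitude vector across
#' observations) is rank-correlated with `y`. Constant columns get
#' `rho = 0, p = 1` (no association measurable). Inference rules as in
#' [spearman()].
#'
#' @param X n_obs x m numeric matrix.
#' @param y numeric outcome vector of length n_obs, not constant.
#' @return list with numeric vectors `rho` and `p` of length m.
#' @export
spearman_map <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must match nrow(X)")
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(y) == 0) stop("outcome vector is constant")
  if (ncol(X) == 0L) return(list(rho = numeric(0), p = numeric(0)))
  rX <- apply(X, 2L, rank)
  if (is.null(dim(rX))) rX <- matrix(rX, nrow = n)
  ry <- rank(y)
  cy <- ry - mean(ry)
  cX <- rX - rep(colMeans(rX), each = n)
  ssx <- colSums(cX^2)
  num <- colSums(cX * cy)
  den <- sqrt(ssx * sum(cy^2))
  rho <- ifelse(den > 0, num / den, 0)
  rho <- pmin(1, pmax(-1, rho))
  if (n >= 10L) {
    p <- spearman_p_t(rho, n)
    p[den == 0] <- 1
  } else {
    p <- vapply(seq_len(ncol(rX)), function(j) {
      if (ssx[j] == 0) return(1)
      spearman_p(rho[j], rX[, j], ry)
    }, 0)
  }
  list(rho = as.numeric(rho), p = as.numeric(p))
}
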