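# Rank tests with exact small-sample enumeration.
#
# Both tests use midranks for ties.  The exact paths enumerate the full
# permutation null (group assignments for Mann-Whitney, sign assignments
# for the signed-rank test) and define the two-sided p-value as the
# probability of a rank statistic at least as far from its null mean as
# the observed one, which reduces to the classical two-sided p in the
# untied case.  Larger samples use the normal approximation with tie
# correction.

#' Two-sided Mann-Whitney (rank-sum) test
#'
#' Exact permutation enumeration when `n_x + n_y <= exact_max`, normal
#' approximation with midrank tie correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest pooled size for the exact path.
#' @return List with `statistic` (rank sum of `x`), `p_value`, `n_x`,
#'   `n_y`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0L, ny > 0L)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  if (nx + ny <= exact_max) {
    combos <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_x = nx, n_y = ny, method = method)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; `|d|` values are midranked.  Exact sign
#' enumeration (2^n outcomes) when the number of nonzero differences is at
#' most `exact_max`, normal approximation with tie correction otherwise.
#'
#' @param x,y Paired numeric samples (or pass differences as `x` with
#'   `y = NULL`).
#' @param exact_max Largest n for the exact path.
#' @return List with `statistic` (positive-rank sum), `p_value`, `n`
#'   (nonzero pairs), `method`.
#' @export
wilcoxon_signed_rank_test <- function(x, y = NULL, exact_max = 15L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    # distribute signs exhaustively
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    p <- mean(abs(sums - mu) >= abs(wpos - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (wpos - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(statistic = wpos, p_value = p, n = n, method = method)
}
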