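#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @description
#' Rank-sum test with average ranks for ties. For small samples
#' (`choose(nx + ny, nx) <= exactLimit`) the p-value is computed by exact
#' enumeration of all group assignments of the pooled values — this is
#' valid in the presence of ties, where the classical exact distribution
#' is not. Larger samples use the normal approximation with tie
#' correction and continuity correction. The two-sided p-value is the
#' probability of a rank sum at least as far from its null mean as the
#' observed one.
#'
#' @param x,y numeric vectors, each nonempty.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends
#'   larger), or `"less"`.
#' @param exactLimit enumerate exactly when the number of assignments
#'   `choose(nx + ny, nx)` does not exceed this (default 20000).
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`
#'   (`"exact"` or `"normal"`), and `degenerate` (`TRUE` when all pooled
#'   values are identical, in which case `p_value = 1`).
#' @examples
#' wilcoxonRankSum(1:3, 4:6)$p_value        # 2/20 = 0.1
#' wilcoxonRankSum(c(1, 1, 1), c(3, 3, 3))$p_value  # ties, still 0.1
#' @export
wilcoxonRankSum <- function(x, y,
                            alternative = c("two.sided", "greater", "less"),
                            exactLimit = 20000) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty")
  }
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = nx * (N + 1) / 2, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2

  if (choose(N, nx) <= exactLimit) {
    idx <- utils::combn(N, nx)
    ws <- colSums(matrix(r[idx], nrow = nx))
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(ws - mu) >= abs(W - mu) - eps),
      greater = mean(ws >= W - eps),
      less = mean(ws <= W + eps)
    )
    return(list(statistic = W, p_value = p, method = "exact",
                degenerate = FALSE))
  }

  ties <- table(r)
  sigma2 <- nx * ny / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
    two.sided = (W - mu - sign(W - mu) * 0.5) / sigma,
    greater = (W - mu - 0.5) / sigma,
    less = (W - mu + 0.5) / sigma
  )
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm(-abs(z))),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z)
  )
  list(statistic = W, p_value = p, method = "normal", degenerate = FALSE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' @description
#' Two-sided signed-rank test on the pairwise differences `x - y`
#' (zero differences dropped, average ranks for tied magnitudes). For
#' `n <= 15` nonzero differences the p-value is exact, by enumeration of
#' all `2^n` sign patterns (valid under ties); beyond that the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length; `y` may be omitted
#'   to test differences supplied directly in `x`.
#' @return list with `statistic` (V, the sum of ranks of positive
#'   differences), `n` (nonzero pairs), `p_value`, `method`, and
#'   `degenerate` (`TRUE` with `p_value = 1` when all differences are
#'   zero).
#' @examples
#' wilcoxonSignedRank(6:10, c(1, 2, 3, 4, 5))$p_value  # 2/32 = 0.0625
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired vectors differ in length")
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n = 0L, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  if (n < 3L) {
    # the test cannot reach significance; report the trivially exact p
    # rather than refusing
    warning("fewer than 3 nonzero differences; p-value is uninformative")
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4

  if (n <= 15L) {
    pats <- as.matrix(expand.grid(rep(list(c(0, 1)), n),
                                  KEEP.OUT.ATTRS = FALSE))
    vs <- as.numeric(pats %*% r)
    p <- mean(abs(vs - mu) >= abs(V - mu) - 1e-9)
    return(list(statistic = V, n = n, p_value = p, method = "exact",
                degenerate = FALSE))
  }
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  z <- (V - mu - sign(V - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, n = n, p_value = p, method = "normal",
       degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Average-rank Pearson correlation of the two rank vectors, with the
#' t-distribution approximation for the p-value
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `rho`, `p_value`, `n`, and `reason` (`NA` normally;
#'   `"constant_input"` with `rho = NA` when either vector is constant).
#' @examples
#' spearmanRho(1:3, c(3, 1, 2))$rho  # -0.5
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "constant_input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, reason = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, order preserved). Inputs
#' outside `[0, 1]` are an error; `NA`s propagate and do not count toward
#' the family size.
#'
#' @param p numeric vector of p-values.
#' @return adjusted vector, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03, 0.005))  # 0.02 0.04 0.04 0.02
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad)) {
    stop("p-value(s) outside [0, 1] at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}
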