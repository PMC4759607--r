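# Group-comparison statistics used by the burden and somatic reports.
#
# These are authored here rather than wrapped from stats:: so the test
# suite can cross-check them against both enumeration oracles and the
# base-R implementations as independent routes.

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Exact two-sided p-value by summation of all hypergeometric outcomes
#' whose probability does not exceed that of the observed table (the usual
#' "probability-based" two-sided definition, with a one-part-in-1e7
#' relative tolerance against floating-point ties).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("input error: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("input error: counts must be nonnegative integers")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  d <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Pearson's chi-squared test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson statistic with a 1-df
#' chi-squared p-value.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `statistic` and `p_value`.
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("input error: need a 2x2 table")
  if (any(tab < 0)) stop("input error: negative counts")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("degenerate-table error: zero margin")
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Family size (number of tests), `m >= 1`.
#' @return `min(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop("input error: family size m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("input error: p outside [0, 1]")
  pmin(1, p * m)
}

# Exact distribution of the doubled rank-sum of the first group under the
# permutation null, by the shift (generating-function convolution)
# algorithm. Ranks are midranks, doubled so the support is integer.
.ranksum_distribution <- function(r2, n) {
  # r2: doubled midranks of the combined sample; n: size of group A
  N <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = n + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(N)) {
    kmax <- min(i, n)
    for (k in kmax:1) {
      shift <- r2[i]
      cols <- (shift + 1L):(smax + 1L)
      f[k + 1L, cols] <- f[k + 1L, cols] + f[k, cols - shift]
    }
  }
  f[n + 1L, ]  # counts over doubled sums 0..smax
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. For small samples
#' (`n + m <= exact_limit`) the two-sided p-value is exact under the
#' permutation null (shift-algorithm distribution of the rank sum,
#' two-sided as `P(|U - nm/2| >= |U_obs - nm/2|)`); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Fully tied data give p = 1.
#'
#' @param x,y Numeric vectors (both nonempty). `U` counts pairs where an
#'   `x` value exceeds a `y` value (ties count 1/2).
#' @param exact_limit Use the exact distribution when `length(x) +
#'   length(y)` is at most this (default 20).
#' @return List with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("input error: both groups must be nonempty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  mu <- n * m / 2
  if (N <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    cnt <- .ranksum_distribution(r2, n)
    sums2 <- seq_along(cnt) - 1L           # doubled rank sums
    U_all <- sums2 / 2 - n * (n + 1) / 2   # corresponding U values
    tot <- sum(cnt)
    dev <- abs(U - mu)
    p <- sum(cnt[abs(U_all - mu) >= dev - 1e-9]) / tot
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  tie <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- 2 * pnorm(-max(0, z))
  list(U = U, p_value = min(1, p), method = "normal")
}
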