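# Exact-test primitives used by every screening stage. All discrete
# two-sided p-values follow the point-probability (minimum-likelihood) rule:
# sum the probabilities of all outcomes no more likely than the observed one.
# A relative slack of 1e-7 absorbs floating-point noise in the comparison.

.point_prob_slack <- 1e-7

fisher_p_one <- function(a, b, c, d) {
  m <- a + b           # row 1 margin ("successes" in pool)
  n <- c + d
  k <- a + c           # column 1 margin (draws)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  supp <- lo:hi
  dens <- dhyper(supp, m, n, k)
  pobs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= pobs * (1 + .point_prob_slack)]))
}

# vectorized over per-COG counts x1, x2 with library sizes n1, n2:
# table is (x1, n1 - x1; x2, n2 - x2)
fisher_p_vec <- function(x1, n1, x2, n2) {
  mapply(function(a, b, c, d) fisher_p_one(a, b, c, d),
         x1, n1 - x1, x2, n2 - x2, USE.NAMES = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test conditioning on both margins of the table
#' \eqn{(a, b; c, d)}; p is the sum of hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table. Vectorised over the four entries.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1: `a`, `b`;
#'   row 2: `c`, `d`).
#' @return A tibble with one row per table: `statistic` (the sample odds
#'   ratio \eqn{ad/bc}), `p_value`, `method`.
#' @export
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3)  # p = 0.1
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  x <- cbind(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop_validation("table entries must be non-negative integers")
  }
  if (any(rowSums(x) == 0)) stop_validation("at least one margin must be positive")
  p <- mapply(fisher_p_one, a, b, c, d, USE.NAMES = FALSE)
  tibble(statistic = (a * d) / (b * c), p_value = p,
         method = "Fisher exact 2x2, two-sided (point probability)")
}

binom_p_one <- function(x1, t, q) {
  if (t == 0) return(1)
  supp <- 0:t
  dens <- dbinom(supp, t, q)
  pobs <- dbinom(x1, t, q)
  min(1, sum(dens[dens <= pobs * (1 + .point_prob_slack)]))
}

#' Exact conditional binomial test for two count samples
#'
#' Dispersion-free exact comparison of one COG's counts `x1`, `x2` in two
#' libraries of sizes `n1`, `n2`: conditional on the total \eqn{x_1+x_2},
#' `x1` is Binomial with success probability \eqn{n_1/(n_1+n_2)} under the
#' null of equal relative abundance. Two-sided p by the point-probability
#' rule. Vectorised.
#'
#' @param x1,x2 Non-negative integer counts.
#' @param n1,n2 Positive integer library sizes (`x1 <= n1`, `x2 <= n2`).
#' @return Tibble with `statistic` (difference of sample proportions),
#'   `p_value`, `method`. A zero total gives p = 1, flagged in `method`.
#' @export
binomial_exact_counts <- function(x1, x2, n1, n2) {
  n <- max(length(x1), length(x2), length(n1), length(n2))
  x1 <- rep_len(as.numeric(x1), n); x2 <- rep_len(as.numeric(x2), n)
  n1 <- rep_len(as.numeric(n1), n); n2 <- rep_len(as.numeric(n2), n)
  if (any(c(x1, x2) < 0) || any(c(x1, x2, n1, n2) != round(c(x1, x2, n1, n2)))) {
    stop_validation("counts must be non-negative integers")
  }
  if (any(n1 <= 0) || any(n2 <= 0)) stop_validation("library sizes must be positive")
  if (any(x1 > n1) || any(x2 > n2)) stop_validation("count exceeds its library size")
  t <- x1 + x2
  q <- n1 / (n1 + n2)
  p <- mapply(binom_p_one, x1, t, q, USE.NAMES = FALSE)
  method <- ifelse(t == 0,
                   "conditional binomial exact (zero total: no information)",
                   "conditional binomial exact, two-sided (point probability)")
  tibble(statistic = x1 / n1 - x2 / n2, p_value = p, method = method)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test without the equal-variance assumption:
#' \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch--Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric vectors, each of length >= 2; not both constant.
#' @return Tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop_validation("welch_t needs at least two observations per sample")
  }
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    stop_degenerate("both samples are constant; Welch's t is undefined")
  }
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  p <- 2 * pt(-abs(t), df)
  tibble(statistic = t, df = df, p_value = min(1, max(p, .Machine$double.xmin)),
         method = "Welch two-sample t, two-sided")
}

# Row-wise Welch over a matrix: columns split by a logical index.
# Returns a tibble (statistic, df, p_value, mean1, mean2); rows where both
# group variances are zero get NA p (degenerate, excluded downstream).
welch_rows <- function(mat, grp1, grp2) {
  m1 <- mat[, grp1, drop = FALSE]
  m2 <- mat[, grp2, drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(t), df)
  degen <- v1 == 0 & v2 == 0
  t[degen] <- NA_real_; df[degen] <- NA_real_; p[degen] <- NA_real_
  tibble(statistic = t, df = df, p_value = pmin(p, 1),
         mean1 = mu1, mean2 = mu2)
}

#' Exact Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties; the two-sided p-value is
#' computed by full enumeration of all assignments of the pooled values to
#' the two groups whenever \eqn{\binom{n_x+n_y}{n_x}} does not exceed
#' `exact_limit` (p is the fraction of assignments whose rank sum deviates
#' from its null mean by at least the observed amount). Beyond the limit a
#' tie-corrected normal approximation is used and flagged in `method`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_limit Maximum number of assignments to enumerate
#'   (default 1e6).
#' @return Tibble with `statistic` (rank sum of `x`, midranks), `p_value`,
#'   `method`.
#' @export
#' @examples
#' ranksum_exact(c(1, 2), c(3, 4))  # p = 1/3
ranksum_exact <- function(x, y, exact_limit = 1e6) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_validation("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  if (choose(N, nx) <= exact_limit) {
    idx <- combn(N, nx)
    sums <- colSums(matrix(r[idx], nrow = nx))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    method <- "Wilcoxon rank-sum, exact enumeration, two-sided"
  } else {
    tie.sum <- sum(r^2)
    sigma2 <- nx * ny / (N * (N - 1)) * (tie.sum - N * (N + 1)^2 / 4)
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum, normal approximation (enumeration bound exceeded)"
  }
  tibble(statistic = W, p_value = max(p, .Machine$double.xmin), method = method)
}

# Fast path: rank-sum p-values for many rows against a fixed group split.
# Enumerates the C(N, n_low) index combinations once.
ranksum_rows <- function(mat, low_idx, exact_limit = 1e6) {
  N <- ncol(mat)
  nl <- length(low_idx)
  exact <- choose(N, nl) <= exact_limit
  comb <- if (exact) combn(N, nl) else NULL
  apply(mat, 1L, function(v) {
    r <- rank(v)
    W <- sum(r[low_idx])
    mu <- nl * (N + 1) / 2
    if (exact) {
      sums <- colSums(matrix(r[comb], nrow = nl))
      mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    } else {
      sigma2 <- nl * (N - nl) / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
      if (sigma2 == 0) 1 else min(1, 2 * pnorm(-abs((W - mu) / sqrt(sigma2))))
    }
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in the
#' input order. `NA` entries are passed through and do not count towards
#' `m` (degenerate tests that produced no p-value).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_validation("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv)
    q <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
    out[ok][o] <- q
  }
  out
}
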