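# Independent brute-force oracles for the exact tests. These enumerate the
# discrete null distributions directly from binomial coefficients (not via
# the d* density functions the implementation uses).

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(N, k)
  pobs <- pr[supp == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

oracle_binom_p <- function(x1, t, q) {
  if (t == 0) return(1)
  k <- 0:t
  pr <- choose(t, k) * q^k * (1 - q)^(t - k)
  pobs <- pr[k == x1]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# midranks computed by positional averaging over sorted ties (independent of
# base rank())
oracle_midranks <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_ranksum_p <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- oracle_midranks(c(x, y))
  obs <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  subsets <- utils::combn(N, nx)
  sums <- apply(subsets, 2, function(s) sum(r[s]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
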