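# Independent brute-force oracles for the rank statistics.

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(n+m, n) group labelings of the pooled sample (tie-free data).
mwu_enumeration_oracle <- function(x, y) {
  n <- length(x)
  m <- length(y)
  u_x <- sum(outer(x, y, ">"))
  pool <- c(x, y)
  labelings <- utils::combn(n + m, n)
  u_all <- apply(labelings, 2, function(ii)
    sum(outer(pool[ii], pool[-ii], ">")))
  p <- if (u_x > n * m / 2) 2 * mean(u_all >= u_x) else 2 * mean(u_all <= u_x)
  list(U = min(u_x, n * m - u_x), p = min(1, p))
}

# Kruskal-Wallis H from the defining rank formula (no ties assumed).
kw_rank_formula <- function(groups) {
  pool <- unlist(groups)
  r <- rank(pool)
  n_tot <- length(pool)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(r, idx, mean)
  ni <- tapply(r, idx, length)
  12 / (n_tot * (n_tot + 1)) * sum(ni * (rbar - (n_tot + 1) / 2)^2)
}
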