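# Independent oracles.  These deliberately avoid the package's fitting and
# resampling code paths: matrices are tabulated with plain loops and the
# permutation null is enumerated exhaustively (feasible for pooled sizes
# <= 10, i.e. C(n, n1) allocations).

oracle_matrices <- function(initial, fate, recruits, m) {
  U <- matrix(0, m, m)
  Fm <- matrix(0, m, m)
  for (j in seq_len(m)) {
    who <- which(initial == j)
    nj <- length(who)
    if (nj == 0) next
    for (i in seq_len(m)) {
      U[i, j] <- sum(fate[who] == i) / nj
      Fm[i, j] <- sum(recruits[who, i]) / nj
    }
  }
  list(U = U, F = Fm)
}

oracle_lambda <- function(initial, fate, recruits, m) {
  f <- oracle_matrices(initial, fate, recruits, m)
  ev <- eigen(f$U + f$F)$values
  re <- Re(ev[abs(Im(ev)) < 1e-9])
  if (length(re)) max(re) else max(Re(ev))
}

# exact permutation distribution for a two-group comparison: every subset of
# size n1 of the pooled individuals forms group 1.  `value_fun(idx)` returns
# the scalar parameter (or probability vector) for a group of pooled indices;
# the statistic is |x1 - x2| or the half-L1 distance.
oracle_exhaustive_test <- function(pooled_initial, pooled_fate, pooled_recruits,
                                   m, n1, value_fun = NULL) {
  n <- length(pooled_initial)
  stopifnot(n <= 10)
  if (is.null(value_fun)) {
    value_fun <- function(idx) oracle_lambda(pooled_initial[idx],
                                             pooled_fate[idx],
                                             pooled_recruits[idx, , drop = FALSE],
                                             m)
  }
  subsets <- utils::combn(n, n1, simplify = FALSE)
  stat_of <- function(idx1) {
    v1 <- value_fun(idx1)
    v2 <- value_fun(setdiff(seq_len(n), idx1))
    if (length(v1) == 1) abs(v1 - v2) else sum(abs(v1 - v2)) / 2
  }
  stats_all <- vapply(subsets, stat_of, numeric(1))
  observed <- stat_of(seq_len(n1))
  list(observed = observed, stats = stats_all,
       p = mean(stats_all > observed))
}

# percentile-quantile oracle: direct sort + linear interpolation between
# order statistics (type-7 definition written out by hand)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
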