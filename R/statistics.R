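#' Test statistics for comparing demographic parameters
#'
#' Four statistics express differences among populations, depending on
#' whether the parameter is scalar (\eqn{\lambda}, \eqn{R_0}, T) or a
#' probability vector (stable stage structure, reproductive value, the
#' composition of individual histories), and whether the comparison is
#' pairwise or global:
#'
#' * `stat_scalar_pairwise`: \eqn{d_w = |x_1 - x_2|}
#' * `stat_scalar_global`: \eqn{d_g = \sum_i (x_i - \bar x)^2}
#' * `stat_vector_pairwise`: \eqn{D_w = \frac{1}{2} \sum_j |p_{1j} - p_{2j}|},
#'   the Keyfitz distance: 0 for identical vectors, 1 for disjoint support
#' * `stat_vector_global`:
#'   \eqn{D_g = \frac{1}{2(n-1)} \sum_j \sum_i |p_{ij} - \bar p_{.j}|},
#'   the average distance of populations from the mean composition
#'
#' For two populations \eqn{D_g} equals \eqn{D_w}, and
#' \eqn{d_g = d_w^2 / 2}. All four are nonnegative; the vector statistics lie
#' in \[0, 1\].
#'
#' @param x1,x2 scalar parameter values for two populations.
#' @param x numeric vector of scalar parameter values, one per population
#'   (length at least 2).
#' @param p1,p2 aligned probability vectors (same stage/history enumeration).
#' @param P matrix of aligned probability vectors, one row per population.
#' @return A single nonnegative number.
#' @name test_statistics
NULL

#' @rdname test_statistics
#' @export
stat_scalar_pairwise <- function(x1, x2) abs(x1 - x2)

#' @rdname test_statistics
#' @export
stat_scalar_global <- function(x) {
  if (length(x) < 2L) stop("need at least two populations", call. = FALSE)
  sum((x - mean(x))^2)
}

#' @rdname test_statistics
#' @export
stat_vector_pairwise <- function(p1, p2) keyfitz_delta(p1, p2)

#' @rdname test_statistics
#' @export
stat_vector_global <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 2L) stop("need at least two populations", call. = FALSE)
  pbar <- colMeans(P)
  sum(abs(sweep(P, 2L, pbar))) / (2 * (n - 1))
}

# statistic dispatcher used by the resampling tests: `values` is a numeric
# vector (scalar parameter) or a matrix of composition rows.
.compute_statistic <- function(values, scalar, pairwise) {
  if (scalar) {
    if (anyNA(values)) return(NA_real_)
    if (pairwise) stat_scalar_pairwise(values[1], values[2])
    else stat_scalar_global(values)
  } else {
    if (anyNA(values)) return(NA_real_)
    if (pairwise) sum(abs(values[1, ] - values[2, ])) / 2
    else stat_vector_global(values)
  }
}
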