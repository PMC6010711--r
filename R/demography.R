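#' Dominant eigenvalue of a projection matrix
#'
#' The asymptotic population growth rate \eqn{\lambda} of a stage-structured
#' population is the dominant eigenvalue of its projection matrix
#' \eqn{A = F + U}. For a nonnegative matrix this is real and nonnegative
#' (Perron-Frobenius); the function returns the eigenvalue of maximum real
#' part among the (numerically) real eigenvalues.
#'
#' @param A square nonnegative numeric matrix.
#' @return The dominant eigenvalue, a single nonnegative number.
#' @details If no eigenvalue is numerically real (a complex dominant pair,
#'   which can arise for periodic/reducible life cycles), a warning is issued
#'   and the real part of the largest-modulus eigenvalue is returned.
#' @export
#' @examples
#' dominant_eigenvalue(matrix(c(0, 0.5, 2, 0), 2, 2))
dominant_eigenvalue <- function(A) {
  .check_projection_matrix(A)
  .dominant_eigen(A, vectors = "none")$lambda
}

#' Stable stage structure
#'
#' Right eigenvector of the projection matrix associated with the dominant
#' eigenvalue, rescaled so that all entries are nonnegative and sum to 1:
#' the proportion of individuals in each stage that any initial population
#' vector converges to.
#'
#' @inheritParams dominant_eigenvalue
#' @return Numeric probability vector of length `nrow(A)`.
#' @details When the dominant eigenvalue is not simple (e.g. the identity
#'   matrix) the tied eigenvectors are averaged, with a warning, so the
#'   result is still a well-defined probability vector.
#' @export
stable_stage_structure <- function(A) {
  .check_projection_matrix(A)
  .dominant_eigen(A, vectors = "right")$w
}

#' Reproductive value
#'
#' Left eigenvector of the projection matrix associated with the dominant
#' eigenvalue, expressed as the proportional contribution of each stage to
#' the long-run abundance of all stages (entries nonnegative, summing to 1).
#'
#' @inheritParams dominant_eigenvalue
#' @return Numeric probability vector of length `nrow(A)`.
#' @export
reproductive_value <- function(A) {
  .check_projection_matrix(A)
  .dominant_eigen(A, vectors = "left")$v
}

#' Fundamental matrix of the transition matrix
#'
#' \eqn{N = (I - U)^{-1}}; entry \eqn{n_{ij}} is the expected number of
#' projection intervals an individual now in stage j will spend in stage i
#' before death.
#'
#' @param U square nonnegative transition (survival/growth) matrix with
#'   column sums at most 1.
#' @return Square numeric matrix of the same dimension.
#' @export
fundamental_matrix <- function(U) {
  .check_projection_matrix(U, what = "U")
  ev <- eigen(U, only.values = TRUE)$values
  if (max(Mod(ev)) >= 1 - 1e-12) {
    bad <- which(colSums(U) >= 1 - 1e-12)
    stop("transition matrix has spectral radius >= 1 (immortal individuals); ",
         "offending column(s): ",
         if (length(bad)) paste(bad, collapse = ", ") else "none with unit sum, matrix is cyclic",
         call. = FALSE)
  }
  solve(diag(nrow(U)) - U)
}

#' Net reproductive rate
#'
#' \eqn{R_0}, the expected number of recruits produced by a newborn over its
#' lifetime: the dominant eigenvalue of \eqn{R = F N} where N is the
#' fundamental matrix of U.
#'
#' @param F square nonnegative fecundity matrix.
#' @param U square nonnegative transition matrix (spectral radius < 1).
#' @return A single nonnegative number.
#' @export
net_reproductive_rate <- function(F, U) {
  .check_projection_matrix(F, what = "F")
  N <- fundamental_matrix(U)
  .dominant_eigen(F %*% N, vectors = "none")$lambda
}

#' Generation time
#'
#' The time needed for the population to grow by a factor of \eqn{R_0};
#' since \eqn{\lambda^T = R_0}, \eqn{T = \ln R_0 / \ln \lambda}.
#'
#' @param lambda asymptotic growth rate (> 0).
#' @param R0 net reproductive rate (> 0).
#' @return Generation time in projection intervals, or `NA` with a `"reason"`
#'   attribute when undefined. A population exactly at replacement
#'   (\eqn{\lambda = 1}) is legal data but has no finite generation time by
#'   this formula, so `NA` is returned rather than an error.
#' @export
generation_time <- function(lambda, R0) {
  if (!is.finite(lambda) || !is.finite(R0) || lambda <= 0 || R0 <= 0) {
    return(structure(NA_real_, reason = "lambda or R0 nonpositive or missing"))
  }
  if (abs(lambda - 1) < 1e-12) {
    return(structure(NA_real_, reason = "population at replacement (lambda = 1)"))
  }
  log(R0) / log(lambda)
}

#' Sensitivity matrix
#'
#' Absolute change in \eqn{\lambda} per absolute change in each matrix entry:
#' \eqn{s_{ij} = v_i w_j / \langle v, w \rangle} with w, v the right and left
#' dominant eigenvectors.
#'
#' @inheritParams dominant_eigenvalue
#' @return Square numeric matrix of sensitivities.
#' @export
sensitivity_matrix <- function(A) {
  .check_projection_matrix(A)
  eg <- .dominant_eigen(A)
  denom <- sum(eg$v * eg$w)
  if (denom <= 0) {
    warning("degenerate eigenstructure: <v, w> not positive; sensitivities unreliable")
    denom <- max(denom, .Machine$double.eps)
  }
  outer(eg$v, eg$w) / denom
}

#' Elasticity matrix
#'
#' Proportional change in \eqn{\lambda} per proportional change in each
#' entry: \eqn{e_{ij} = (a_{ij}/\lambda) s_{ij}}. Elasticities of a matrix
#' with \eqn{\lambda > 0} sum to 1.
#'
#' @inheritParams dominant_eigenvalue
#' @return Square numeric matrix of elasticities.
#' @export
elasticity_matrix <- function(A) {
  .check_projection_matrix(A)
  lam <- dominant_eigenvalue(A)
  if (lam <= 0) stop("elasticities undefined: dominant eigenvalue is 0", call. = FALSE)
  (A / lam) * sensitivity_matrix(A)
}

#' Keyfitz distance between two probability vectors
#'
#' Half the L1 distance, \eqn{\Delta = \frac{1}{2}\sum_j |p_j - q_j|}: 0 when
#' the vectors are identical, 1 when their supports are disjoint. Used both
#' to measure the distance of an observed stage distribution from the stable
#' stage structure and as the pairwise test statistic for vector-valued
#' demographic parameters.
#'
#' @param p,q probability vectors of equal length (each summing to 1 within
#'   1e-9).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' keyfitz_delta(c(0.5, 0.5), c(0.8, 0.2)) # 0.3
keyfitz_delta <- function(p, q) {
  if (length(p) != length(q)) {
    stop("probability vectors have different lengths (populations must share the same stages)",
         call. = FALSE)
  }
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("inputs must be probability vectors summing to 1", call. = FALSE)
  }
  sum(abs(p - q)) / 2
}

#' Demographic summary of a projection model
#'
#' Computes the full set of deterministic demographic parameters for one
#' population: \eqn{\lambda}, \eqn{R_0}, generation time, stable stage
#' structure, reproductive value, sensitivity and elasticity matrices, and —
#' when individuals were sampled at random so the observed stage counts
#' estimate the stage distribution — the Keyfitz distance between the
#' observed stage distribution and the stable stage structure. Under a
#' fixed-per-stage sampling design the observed stage proportions are set by
#' the experimenter, so that distance is meaningless and omitted.
#'
#' @param model a [projection_model].
#' @return A list of class `"demographic_summary"`.
#' @export
demographic_summary <- function(model) {
  stopifnot(inherits(model, "projection_model"))
  A <- model$A
  eg <- .dominant_eigen(A)
  lam <- eg$lambda
  # R0 is undefined when the sampled transition matrix traps individuals
  # (no observed deaths in some closed set of stages); report NA, not an error
  R0 <- tryCatch(net_reproductive_rate(model$F, model$U),
                 error = function(e)
                   structure(NA_real_, reason = conditionMessage(e)))
  out <- list(
    stage_names = model$stage_names,
    lambda = lam,
    R0 = R0,
    T = generation_time(lam, R0),
    sss = stats::setNames(eg$w, model$stage_names),
    rv = stats::setNames(eg$v, model$stage_names),
    sensitivity = sensitivity_matrix(A),
    elasticity = if (lam > 0) elasticity_matrix(A) else NULL
  )
  if (identical(model$sampling, "random") && sum(model$n_per_stage) > 0) {
    p_obs <- model$n_per_stage / sum(model$n_per_stage)
    out$observed_structure <- stats::setNames(p_obs, model$stage_names)
    out$keyfitz_to_sss <- keyfitz_delta(p_obs, out$sss)
  }
  class(out) <- "demographic_summary"
  out
}

#' @export
print.demographic_summary <- function(x, digits = 4, ...) {
  cat("Demographic summary\n")
  cat("  lambda:", format(x$lambda, digits = digits),
      " R0:", format(x$R0, digits = digits),
      " T:", if (is.na(x$T)) paste0("undefined (", attr(x$T, "reason"), ")")
             else format(x$T, digits = digits), "\n")
  cat("  stable stage structure:", paste(format(x$sss, digits = digits), collapse = " "), "\n")
  cat("  reproductive value:    ", paste(format(x$rv, digits = digits), collapse = " "), "\n")
  if (!is.null(x$keyfitz_to_sss)) {
    cat("  Keyfitz distance of observed structure to SSS:",
        format(x$keyfitz_to_sss, digits = digits), "\n")
  }
  invisible(x)
}

# ---- internal ---------------------------------------------------------------

.check_projection_matrix <- function(A, what = "A") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(A) || any(!is.finite(A))) {
    stop(what, " must be finite and numeric", call. = FALSE)
  }
  if (any(A < 0)) stop(what, " must be nonnegative", call. = FALSE)
  invisible(TRUE)
}

# Dominant eigenvalue plus normalized right (w) and left (v) eigenvectors.
# Eigenvalues with |Im| < 1e-9 count as real; among those the maximum real
# part is dominant.  Ties (non-simple dominant root) average the tied
# eigenvectors with a warning; a fully complex dominant pair falls back to
# the real part of the largest-modulus eigenvalue, also with a warning.
.dominant_eigen <- function(A, vectors = c("both", "right", "left", "none")) {
  vectors <- match.arg(vectors)
  m <- nrow(A)
  if (m == 1L) {
    return(list(lambda = A[1, 1], w = 1, v = 1, simple = TRUE))
  }
  er <- eigen(A, symmetric = FALSE,
              only.values = identical(vectors, "left") ||
                            identical(vectors, "none"))
  vals <- er$values
  real_idx <- which(abs(Im(vals)) < 1e-9)
  if (length(real_idx) == 0L) {
    warning("no real eigenvalue found (complex dominant pair); using real part")
    k <- which.max(Mod(vals))
    lam <- Re(vals[k])
    tied <- k
  } else {
    re <- Re(vals[real_idx])
    lam <- max(re)
    tied <- real_idx[re > lam - 1e-9 * max(1, abs(lam))]
    if (length(tied) > 1L && vectors != "none") {
      warning("dominant eigenvalue is not simple; averaging tied eigenvectors")
    }
  }
  out <- list(lambda = lam, simple = length(tied) == 1L)
  if (vectors %in% c("both", "right")) {
    out$w <- .average_eigvecs(er$vectors, tied)
  }
  if (vectors %in% c("both", "left")) {
    el <- eigen(t(A), symmetric = FALSE)
    # match left eigenvectors to the same eigenvalue(s)
    lidx <- order(abs(el$values - lam))[seq_along(tied)]
    out$v <- .average_eigvecs(el$vectors, lidx)
  }
  out
}

# Make each eigenvector nonnegative and sum-1, then average across ties.
.average_eigvecs <- function(vecs, idx) {
  cols <- lapply(idx, function(k) {
    x <- Re(vecs[, k])
    if (sum(x) < 0) x <- -x
    x[abs(x) < 1e-12] <- 0
    if (any(x < 0)) x <- abs(x)  # numerically tiny negatives only
    x / sum(x)
  })
  out <- Reduce(`+`, cols) / length(cols)
  out / sum(out)
}
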