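#' Randomization test comparing demographic parameters among populations
#'
#' Tests the null hypothesis that the populations have a common origin: that
#' the observed differences in a demographic parameter are no larger than
#' expected from random allocation of individuals (with their life
#' histories) to populations. The pooled individuals are repeatedly
#' reallocated without replacement to groups of the original sizes, the
#' parameter is re-extracted per group and the test statistic recomputed;
#' the p-value is the proportion of permutation replicates with a statistic
#' strictly greater than the observed one. Only two-tailed tests are
#' offered: every statistic is a nonnegative distance, folding both tails
#' into its upper tail.
#'
#' @param tables list of [history_table]s (at least two) with identical
#'   stage sets, data types and sampling designs.
#' @param parameter one of `"lambda"`, `"R0"`, `"T"` (scalar statistics
#'   \eqn{d_w}/\eqn{d_g}) or `"sss"`, `"rv"`, `"histories"` (vector
#'   statistics \eqn{D_w}/\eqn{D_g}).
#' @param mode `"global"` (all populations at once) or `"pairwise"`.
#' @param pair for `mode = "pairwise"`, indices (or population ids) of the
#'   two populations compared; defaults to the first two.
#' @param plan a [resampling_plan].
#' @return A `"null_distribution"` object: observed statistic, the vector of
#'   replicated statistics, the p-value, and accounting of replicates
#'   skipped because the parameter was undefined (e.g. generation time in a
#'   replicate at replacement). More than 10% skipped replicates flags the
#'   result unreliable. The p-value denominator is the number of valid
#'   replicates.
#' @export
randomization_test <- function(tables,
                               parameter = c("lambda", "R0", "T", "sss", "rv",
                                             "histories"),
                               mode = c("global", "pairwise"), pair = NULL,
                               plan = resampling_plan()) {
  parameter <- match.arg(parameter)
  mode <- match.arg(mode)
  tables <- .as_table_list(tables)
  if (!is.null(pair)) {
    mode <- "pairwise"
    tables <- tables[.resolve_pops(pair, tables)]
  } else if (mode == "pairwise") {
    tables <- tables[1:2]
  }
  .check_comparable(tables)
  pairwise <- mode == "pairwise"

  ctx <- .test_context(tables, parameter)
  observed_values <- .group_values(ctx$orig_groups, ctx)
  observed <- .compute_statistic(observed_values, ctx$scalar, pairwise)
  if (is.na(observed)) {
    stop("parameter '", parameter, "' is undefined for the observed data",
         call. = FALSE)
  }

  set.seed(plan$seed)
  stratify <- .should_stratify(plan, tables)
  strata_of <- if (stratify) lapply(tables, `[[`, "initial") else NULL
  reps <- numeric(plan$n_reps)
  for (b in seq_len(plan$n_reps)) {
    groups <- .permutation_indices(ctx$initial, ctx$m, ctx$sizes, strata_of)
    reps[b] <- .compute_statistic(.group_values(groups, ctx), ctx$scalar,
                                  pairwise)
  }
  new_null_distribution(observed, reps,
                        statistic = .stat_label(ctx$scalar, pairwise),
                        parameter = parameter, mode = mode,
                        n_tables = length(tables), plan = plan,
                        stratified = stratify)
}

#' Planned (a priori) comparisons among groups of populations
#'
#' For each requested contrast, the individuals of the populations in each
#' group are collapsed into a single larger population (no averaging of
#' parameters: the parameter is re-extracted from the pooled individuals)
#' and a randomization test is run between the pooled groups. Contrast sets
#' may be nonorthogonal (a population re-used across contrasts); this is
#' flagged in the result. No multiplicity correction is applied — the number
#' of tests performed is reported and interpretation is left to the user.
#'
#' @param tables list of [history_table]s.
#' @param contrasts list of contrasts; each contrast is a list of two or
#'   more groups, each group a vector of population indices or ids. Groups
#'   within one contrast must be disjoint.
#' @inheritParams randomization_test
#' @return List of `"null_distribution"` objects (one per contrast), with
#'   attributes `nonorthogonal` and `n_tests`.
#' @export
planned_comparison <- function(tables, contrasts, parameter = "lambda",
                               plan = resampling_plan()) {
  tables <- .as_table_list(tables)
  used <- integer(0)
  results <- vector("list", length(contrasts))
  for (k in seq_along(contrasts)) {
    groups <- lapply(contrasts[[k]], .resolve_pops, tables = tables)
    if (length(groups) < 2L) stop("a contrast needs at least two groups", call. = FALSE)
    idx_all <- unlist(groups)
    if (anyDuplicated(idx_all)) {
      stop("contrast ", k, ": a population appears in more than one group",
           call. = FALSE)
    }
    used <- c(used, unique(idx_all))
    pooled_groups <- lapply(groups, function(g) {
      pool_tables(tables[g],
                  population_id = paste(vapply(tables[g], `[[`, character(1),
                                               "population_id"),
                                        collapse = "+"))
    })
    results[[k]] <- randomization_test(
      pooled_groups, parameter = parameter,
      mode = if (length(groups) == 2L) "pairwise" else "global",
      plan = resampling_plan(plan$n_reps,
                             seed = plan$seed + 7919L * (k - 1L),
                             stratify = plan$stratify))
    names(results)[k] <- paste(vapply(pooled_groups, `[[`, character(1),
                                      "population_id"),
                               collapse = " vs ")
  }
  attr(results, "nonorthogonal") <- anyDuplicated(used) > 0L
  attr(results, "n_tests") <- length(results)
  results
}

#' Significance of the distance between observed structure and SSS
#'
#' Measures the Keyfitz distance between the observed stage distribution and
#' the stable stage structure of the fitted matrix, and assesses its
#' significance by a randomization (bootstrap) test: histories are resampled
#' with replacement, both the resampled stage distribution and the resampled
#' model's SSS recomputed, and the p-value is the proportion of replicate
#' distances strictly greater than the observed one.
#'
#' Only meaningful under pure random sampling, where the sample's stage
#' proportions estimate the population stage structure. Under a
#' fixed-per-stage design the observed stage distribution is an artifact of
#' the design, so the function refuses.
#'
#' @param table a [history_table] with `sampling = "random"`.
#' @param plan a [resampling_plan].
#' @return A `"null_distribution"` with statistic `"keyfitz_delta"`.
#' @export
sss_distance_test <- function(table, plan = resampling_plan()) {
  stopifnot(inherits(table, "history_table"))
  if (!identical(table$sampling, "random")) {
    stop("distance to SSS is meaningless under a fixed-per-stage design: ",
         "the sampled stage distribution is set by the experimenter, not an ",
         "estimate of the population structure", call. = FALSE)
  }
  m <- length(table$stage_names)
  n <- n_individuals(table)
  anon1 <- identical(table$reproduction_type, "anon1")
  delta_of <- function(idx) {
    fit <- .fit_UF(table$initial[idx], table$fate[idx],
                   if (anon1) NULL else table$recruits[idx, , drop = FALSE],
                   m, anon1 = anon1, recruit_totals = table$recruit_totals,
                   reproductive_stages = table$reproductive_stages)
    eg <- suppressWarnings(.dominant_eigen(fit$F + fit$U, vectors = "right"))
    p_obs <- tabulate(table$initial[idx], m) / length(idx)
    sum(abs(p_obs - eg$w)) / 2
  }
  observed <- delta_of(seq_len(n))
  set.seed(plan$seed)
  reps <- numeric(plan$n_reps)
  for (b in seq_len(plan$n_reps)) {
    reps[b] <- delta_of(.bootstrap_indices(table$initial, m, stratify = FALSE))
  }
  new_null_distribution(observed, reps, statistic = "keyfitz_delta",
                        parameter = "observed structure vs SSS",
                        mode = "bootstrap", n_tables = 1L, plan = plan,
                        stratified = FALSE)
}

# ---- null distribution object ----------------------------------------------

new_null_distribution <- function(observed, reps, statistic, parameter, mode,
                                  n_tables, plan, stratified) {
  valid <- !is.na(reps)
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("all replicates undefined", call. = FALSE)
  p <- sum(reps[valid] > observed) / n_valid
  structure(list(statistic = statistic, parameter = parameter, mode = mode,
                 observed = observed, replicates = reps[valid],
                 p_value = p, n_reps = length(reps),
                 n_skipped = sum(!valid),
                 unreliable = sum(!valid) > 0.1 * length(reps),
                 n_tables = n_tables, seed = plan$seed,
                 stratified = stratified),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, digits = 4, ...) {
  cat("Randomization test (", x$mode, "), parameter: ", x$parameter, "\n",
      sep = "")
  cat("  statistic ", x$statistic, " = ", format(x$observed, digits = digits),
      ",  p = ", format(x$p_value, digits = digits),
      "  (", length(x$replicates), " replicates",
      if (x$n_skipped > 0) paste0(", ", x$n_skipped, " skipped"), ")\n",
      sep = "")
  if (isTRUE(x$unreliable)) {
    cat("  WARNING: >10% of replicates undefined; result unreliable\n")
  }
  invisible(x)
}

#' Histogram of a permutation null distribution
#'
#' Plots the replicated test statistics with the observed value marked — the
#' distribution of between-group differences expected by chance under a
#' common origin of individuals.
#'
#' @param x a `"null_distribution"`.
#' @param ... passed to [graphics::hist].
#' @export
plot.null_distribution <- function(x, ...) {
  graphics::hist(x$replicates,
                 main = paste0("Null distribution of ", x$statistic,
                               " (", x$parameter, ")"),
                 xlab = x$statistic, col = "steelblue", border = "white", ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  graphics::mtext(sprintf("observed = %.4g, p = %.4g", x$observed, x$p_value),
                  side = 3)
  invisible(x)
}

#' Export binned counts of a null distribution
#'
#' @param x a `"null_distribution"`.
#' @param breaks passed to [graphics::hist] (computed, not plotted).
#' @return Data frame with bin midpoints and counts.
#' @export
null_distribution_bins <- function(x, breaks = "Sturges") {
  h <- graphics::hist(x$replicates, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

# ---- internal parameter machinery -------------------------------------------

.as_table_list <- function(tables) {
  if (inherits(tables, "history_table")) tables <- list(tables)
  if (!is.list(tables) || !all(vapply(tables, inherits, logical(1), "history_table"))) {
    stop("expected a list of history_table objects", call. = FALSE)
  }
  tables
}

.resolve_pops <- function(which, tables) {
  ids <- vapply(tables, `[[`, character(1), "population_id")
  if (is.character(which)) {
    idx <- match(which, ids)
    if (anyNA(idx)) stop("unknown population id(s): ",
                         paste(which[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  } else as.integer(which)
}

.check_comparable <- function(tables) {
  if (length(tables) < 2L) stop("need at least two populations", call. = FALSE)
  .shared_stage_check(tables)
  for (f in c("reproduction_type", "census", "sampling")) {
    if (length(unique(vapply(tables, `[[`, character(1), f))) > 1L) {
      stop("all populations must share the same ", f,
           " (data of the same type with identical sampling designs)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.stat_label <- function(scalar, pairwise) {
  if (scalar) { if (pairwise) "dw" else "dg" }
  else        { if (pairwise) "Dw" else "Dg" }
}

# Precompute everything replicate evaluation needs: pooled individual arrays,
# original group index blocks, and (for the histories parameter) the global
# canonical enumeration of distinct histories, fixed across replicates so
# composition vectors stay aligned.
.test_context <- function(tables, parameter) {
  m <- length(tables[[1]]$stage_names)
  pooled <- pool_tables(tables)
  sizes <- vapply(tables, n_individuals, integer(1))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  orig_groups <- lapply(seq_along(sizes), function(g) starts[g]:ends[g])
  ctx <- list(m = m, sizes = sizes, orig_groups = orig_groups,
              initial = pooled$initial, fate = pooled$fate,
              recruits = pooled$recruits,
              anon1 = identical(pooled$reproduction_type, "anon1"),
              recruit_totals = pooled$recruit_totals,
              reproductive_stages = pooled$reproductive_stages,
              parameter = parameter,
              scalar = parameter %in% c("lambda", "R0", "T"))
  if (parameter == "histories") {
    ids <- .history_ids(tables)
    ctx$hist_ids <- unlist(ids$per_table)
    ctx$n_hist <- ids$n_distinct
  }
  ctx
}

# Values of the chosen parameter for each index group: a numeric vector for
# scalars, a matrix of aligned probability rows for vector parameters.
.group_values <- function(groups, ctx) {
  if (identical(ctx$parameter, "histories")) {
    P <- matrix(0, length(groups), ctx$n_hist)
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      P[g, ] <- tabulate(ctx$hist_ids[idx], ctx$n_hist) / length(idx)
    }
    return(P)
  }
  if (ctx$anon1) {
    nrep_g <- vapply(groups, function(idx)
      sum(ctx$initial[idx] %in% ctx$reproductive_stages), numeric(1))
    tot_share <- if (sum(nrep_g) > 0) nrep_g / sum(nrep_g)
                 else rep(1 / length(groups), length(groups))
  }
  one <- function(g) {
    idx <- groups[[g]]
    fit <- .fit_UF(ctx$initial[idx], ctx$fate[idx],
                   if (ctx$anon1) NULL else ctx$recruits[idx, , drop = FALSE],
                   ctx$m, anon1 = ctx$anon1,
                   recruit_totals = if (ctx$anon1)
                     ctx$recruit_totals * tot_share[g] else NULL,
                   reproductive_stages = ctx$reproductive_stages)
    if (ctx$scalar) .scalar_from_fit(fit, ctx$parameter, ctx$m)
    else {
      eg <- suppressWarnings(.dominant_eigen(
        fit$F + fit$U,
        vectors = if (identical(ctx$parameter, "sss")) "right" else "left"))
      if (identical(ctx$parameter, "sss")) eg$w else eg$v
    }
  }
  if (ctx$scalar) vapply(seq_along(groups), one, numeric(1))
  else t(vapply(seq_along(groups), one, numeric(ctx$m)))
}

# lambda / R0 / T from a fitted (U, F) pair; NA where undefined (generation
# time at replacement, R0 when the transition matrix traps individuals).
.scalar_from_fit <- function(fit, parameter, m) {
  lam <- .lambda_of(fit$F + fit$U)
  if (parameter == "lambda") return(lam)
  ev <- eigen(fit$U, only.values = TRUE, symmetric = FALSE)$values
  if (max(Mod(ev)) >= 1 - 1e-12) return(NA_real_)
  R0 <- .lambda_of(fit$F %*% solve(diag(m) - fit$U))
  if (parameter == "R0") return(R0)
  as.numeric(generation_time(lam, R0))
}

.lambda_of <- function(A) {
  vals <- eigen(A, only.values = TRUE, symmetric = FALSE)$values
  real <- Re(vals[abs(Im(vals)) < 1e-9])
  if (!length(real)) Re(vals[which.max(Mod(vals))]) else max(real)
}
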