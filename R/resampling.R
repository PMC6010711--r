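#' Resampling plan
#'
#' Number of replicates, random seed and sampling-design handling shared by
#' the bootstrap, the randomization tests and the power analysis.
#'
#' Reproducibility contract: each top-level resampling function seeds one
#' generator stream from `seed` on entry and all replicates consume it
#' sequentially, so identical seed + inputs give bit-identical resample
#' sequences.
#'
#' @param n_reps number of replicates (default 10000; values below 999 give
#'   coarse p-values and trigger a warning).
#' @param seed integer seed.
#' @param stratify `NA` (default) stratifies resampling by initial stage
#'   exactly when the data's sampling design is `"fixed_per_stage"`;
#'   `TRUE`/`FALSE` force the choice (the escape hatch for unstratified
#'   permutation under a fixed design).
#' @return An object of class `"resampling_plan"`.
#' @export
resampling_plan <- function(n_reps = 10000, seed = 1, stratify = NA) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (n_reps < 999) warning("fewer than 999 replicates: p-values will be coarse")
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 stratify = stratify),
            class = "resampling_plan")
}

.should_stratify <- function(plan, tables) {
  if (!is.na(plan$stratify)) return(isTRUE(plan$stratify))
  any(vapply(tables, function(t) identical(t$sampling, "fixed_per_stage"),
             logical(1)))
}

#' Bootstrap resample of a history table
#'
#' Samples individuals with replacement, keeping the total size. Under pure
#' random sampling individuals are resampled with no restriction; under a
#' fixed-per-stage design resampling is restricted to each initial stage, so
#' per-stage counts are preserved (the experimentally fixed quantity).
#'
#' Draws from the current RNG stream; callers wanting reproducibility seed
#' the stream (the top-level functions do this from their plan's seed).
#'
#' @param table a [history_table].
#' @param stratify logical; stratify by initial stage.
#' @return A [history_table] of the same size.
#' @export
bootstrap_sample <- function(table,
                             stratify = identical(table$sampling, "fixed_per_stage")) {
  idx <- .bootstrap_indices(table$initial, length(table$stage_names), stratify)
  .subset_history_table(table, idx)
}

.bootstrap_indices <- function(initial, m, stratify) {
  n <- length(initial)
  if (!stratify) return(sample.int(n, n, replace = TRUE))
  idx <- integer(n)
  pos <- 1L
  for (j in seq_len(m)) {
    who <- which(initial == j)
    if (length(who)) {
      idx[pos:(pos + length(who) - 1L)] <-
        who[sample.int(length(who), length(who), replace = TRUE)]
      pos <- pos + length(who)
    }
  }
  idx
}

.subset_history_table <- function(table, idx) {
  out <- table
  out$initial <- table$initial[idx]
  out$fate <- table$fate[idx]
  if (!is.null(table$recruits)) out$recruits <- table$recruits[idx, , drop = FALSE]
  out
}

#' Permute individuals among populations
#'
#' Pools the individuals of all tables and reallocates them, without
#' replacement, to groups of the original sizes — the resampling step of the
#' randomization tests, simulating a common origin for all individuals.
#' When stratified, allocation is performed within initial-stage strata so
#' each group keeps its original per-stage counts (mirroring the
#' fixed-per-stage bootstrap restriction).
#'
#' For `"anon1"` tables the population recruit totals are pooled and
#' re-credited to the output groups in proportion to each group's number of
#' reproductive individuals (individual histories carry no recruit counts to
#' permute).
#'
#' @param tables list of [history_table]s sharing the same stages.
#' @param stratify logical; permute within initial-stage strata.
#' @return List of [history_table]s with the original sizes.
#' @export
permutation_split <- function(tables, stratify = FALSE) {
  .shared_stage_check(tables)
  pooled <- pool_tables(tables)
  sizes <- vapply(tables, n_individuals, integer(1))
  groups <- .permutation_indices(pooled$initial, length(pooled$stage_names),
                                 sizes,
                                 strata_of = if (stratify)
                                   lapply(tables, `[[`, "initial") else NULL)
  out <- lapply(seq_along(tables), function(g) {
    tab <- .subset_history_table(pooled, groups[[g]])
    tab$population_id <- tables[[g]]$population_id
    tab$sampling <- tables[[g]]$sampling
    tab
  })
  if (identical(pooled$reproduction_type, "anon1")) {
    out <- .recredit_anon1(out, tables, pooled)
  }
  out
}

# Allocation of pooled indices to groups.  Unstratified: one global
# permutation cut into blocks.  Stratified: each initial-stage stratum is
# permuted separately and dealt back so group g receives as many stratum-j
# individuals as it originally had.
.permutation_indices <- function(initial, m, sizes, strata_of = NULL) {
  n <- length(initial)
  if (is.null(strata_of)) {
    perm <- sample.int(n, n)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    return(lapply(seq_along(sizes), function(g) perm[starts[g]:ends[g]]))
  }
  counts <- vapply(strata_of, function(v) tabulate(v, m), integer(m))
  if (m == 1L) counts <- matrix(counts, nrow = 1L)
  groups <- lapply(sizes, function(s) integer(0))
  for (j in seq_len(m)) {
    who <- which(initial == j)
    if (!length(who)) next
    who <- who[sample.int(length(who), length(who))]
    pos <- 1L
    for (g in seq_along(sizes)) {
      k <- counts[j, g]
      if (k > 0L) {
        groups[[g]] <- c(groups[[g]], who[pos:(pos + k - 1L)])
        pos <- pos + k
      }
    }
  }
  groups
}

#' Pool history tables into one
#'
#' Concatenates the individuals of several history tables (shared stage
#' space required) into a single table — the pooled population used by the
#' randomization tests and by planned comparisons among groups of
#' populations. No averaging of parameters takes place: pooled parameters
#' are re-extracted from the larger collection of individuals.
#'
#' @param tables list of [history_table]s.
#' @param population_id label for the pooled table.
#' @return A [history_table].
#' @export
pool_tables <- function(tables, population_id = "pooled") {
  .shared_stage_check(tables)
  rt <- unique(vapply(tables, `[[`, character(1), "reproduction_type"))
  cs <- unique(vapply(tables, `[[`, character(1), "census"))
  if (length(rt) > 1L || length(cs) > 1L) {
    stop("populations must share reproduction type and census", call. = FALSE)
  }
  t1 <- tables[[1]]
  out <- t1
  out$population_id <- population_id
  out$initial <- unlist(lapply(tables, `[[`, "initial"))
  out$fate <- unlist(lapply(tables, `[[`, "fate"))
  if (!is.null(t1$recruits)) {
    out$recruits <- do.call(rbind, lapply(tables, `[[`, "recruits"))
  }
  if (identical(rt, "anon1")) {
    out$recruit_totals <- Reduce(`+`, lapply(tables, `[[`, "recruit_totals"))
  }
  out
}

# Re-credit pooled anon1 recruit totals to permuted groups proportionally to
# each group's count of reproductive individuals.
.recredit_anon1 <- function(out, tables, pooled) {
  rs <- pooled$reproductive_stages
  nrep <- vapply(out, function(t) sum(t$initial %in% rs), numeric(1))
  share <- if (sum(nrep) > 0) nrep / sum(nrep) else rep(1 / length(out), length(out))
  for (g in seq_along(out)) {
    out[[g]]$recruit_totals <- pooled$recruit_totals * share[g]
  }
  out
}
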