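#' Table of individual life histories
#'
#' A population is represented as the collection of its individual life
#' histories over one projection interval. Each history records the
#' individual's initial stage, its fate (destination stage, or death), and
#' the number of recruits it produced per recruit stage. All resampling
#' inference (bootstrap, permutation) operates on these tables.
#'
#' Under anonymous reproduction of type 1 (`reproduction_type = "anon1"`)
#' parents are not identified, so recruit counts cannot be attached to
#' individual histories; instead a population-level recruit total per
#' recruit stage is stored together with the set of reproductive stages.
#'
#' @param initial integer vector (one entry per individual) of initial stage
#'   indices in `1..m`.
#' @param fate integer vector of the same length: destination stage index,
#'   or `0` for death.
#' @param recruits integer matrix (individuals x stages) of recruits
#'   produced, credited per recruit stage; `NULL` under `"anon1"`.
#' @param stage_names character vector of stage labels (defines m).
#' @param reproduction_type one of `"identified"`, `"anon1"`, `"anon2"`,
#'   `"anon3"` (parent identification classes for reproduction data).
#' @param census,sampling see [projection_model].
#' @param recruit_totals (`"anon1"` only) numeric vector of length m:
#'   population-level recruit totals per recruit stage.
#' @param reproductive_stages (`"anon1"` only) integer vector of stage
#'   indices treated as reproductive.
#' @param population_id label.
#' @return An object of class `"history_table"`.
#' @export
history_table <- function(initial, fate, recruits = NULL, stage_names,
                          reproduction_type = c("identified", "anon1", "anon2", "anon3"),
                          census = c("prebreeding", "postbreeding"),
                          sampling = c("random", "fixed_per_stage"),
                          recruit_totals = NULL, reproductive_stages = NULL,
                          population_id = "pop") {
  reproduction_type <- match.arg(reproduction_type)
  census <- match.arg(census)
  sampling <- match.arg(sampling)
  m <- length(stage_names)
  n <- length(initial)
  if (n == 0L) stop("empty population: a history table needs at least one individual",
                    call. = FALSE)
  initial <- as.integer(initial); fate <- as.integer(fate)
  if (length(fate) != n) stop("initial and fate lengths differ", call. = FALSE)
  if (any(initial < 1L | initial > m)) stop("initial stage out of range", call. = FALSE)
  if (any(fate < 0L | fate > m)) stop("fate out of range (0 = death)", call. = FALSE)
  if (reproduction_type == "anon1") {
    if (!is.null(recruits)) {
      stop("per-individual recruits supplied but reproduction_type is 'anon1' ",
           "(anonymous reproduction stores a population-level total only)", call. = FALSE)
    }
    if (is.null(recruit_totals) || length(recruit_totals) != m || any(recruit_totals < 0)) {
      stop("'anon1' requires nonnegative recruit_totals of length m", call. = FALSE)
    }
    if (is.null(reproductive_stages) ||
        any(!reproductive_stages %in% seq_len(m))) {
      stop("'anon1' requires reproductive_stages within 1..m", call. = FALSE)
    }
    reproductive_stages <- sort(unique(as.integer(reproductive_stages)))
  } else {
    if (is.null(recruits)) recruits <- matrix(0L, n, m)
    recruits <- as.matrix(recruits)
    storage.mode(recruits) <- "integer"
    if (nrow(recruits) != n || ncol(recruits) != m) {
      stop("recruits must be an individuals x stages matrix", call. = FALSE)
    }
    if (any(recruits < 0L)) stop("recruit counts must be nonnegative", call. = FALSE)
    recruit_totals <- NULL
  }
  structure(list(population_id = population_id, stage_names = stage_names,
                 initial = initial, fate = fate, recruits = recruits,
                 reproduction_type = reproduction_type, census = census,
                 sampling = sampling, recruit_totals = recruit_totals,
                 reproductive_stages = reproductive_stages),
            class = "history_table")
}

#' Number of individuals in a history table
#' @param table a [history_table].
#' @return Integer count.
#' @export
n_individuals <- function(table) length(table$initial)

#' @export
print.history_table <- function(x, ...) {
  m <- length(x$stage_names)
  cat("History table '", x$population_id, "': ", n_individuals(x),
      " individuals, ", m, " stages (", x$reproduction_type, ", ", x$census,
      " census, ", x$sampling, " sampling)\n", sep = "")
  cat("  individuals per initial stage:",
      paste(tabulate(x$initial, m), collapse = " "), "\n")
  if (identical(x$reproduction_type, "anon1")) {
    cat("  population recruit totals:",
        paste(x$recruit_totals, collapse = " "),
        " reproductive stages:", paste(x$reproductive_stages, collapse = " "), "\n")
  }
  invisible(x)
}

#' Convert raw demographic records to history tables
#'
#' Raw demographic data hold one record per individual: its initial stage,
#' its final stage (or `"DEAD"`), and the recruits it produced, encoded as
#' `stage:count` pairs separated by `;`. Records are split by population and
#' each population becomes a [history_table].
#'
#' @param raw data frame with columns `individual_id`, `population_id`,
#'   `initial_stage`, `final_stage`, `recruits`.
#' @param stages ordered character vector of stage labels shared by all
#'   populations.
#' @param reproduction_type,census,sampling metadata, see [history_table].
#' @param recruit_totals for `"anon1"`: named list, one numeric vector of
#'   per-stage recruit totals per population.
#' @param reproductive_stages for `"anon1"`: stage labels (or indices) of
#'   reproductive stages.
#' @return Named list of [history_table] objects, one per population.
#' @export
histories_from_raw <- function(raw, stages,
                               reproduction_type = "identified",
                               census = "prebreeding",
                               sampling = "random",
                               recruit_totals = NULL,
                               reproductive_stages = NULL) {
  need <- c("individual_id", "population_id", "initial_stage", "final_stage")
  if (!all(need %in% names(raw))) {
    stop("raw data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("raw data are empty", call. = FALSE)
  m <- length(stages)
  stage_index <- function(x, allow_dead = FALSE) {
    idx <- match(as.character(x), stages)
    if (allow_dead) idx[as.character(x) %in% c("DEAD", "dead", "D")] <- 0L
    if (anyNA(idx)) {
      stop("unknown stage label(s): ",
           paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    idx
  }
  if (is.character(reproductive_stages)) {
    reproductive_stages <- match(reproductive_stages, stages)
  }
  pops <- split(raw, raw$population_id)
  out <- lapply(names(pops), function(pid) {
    d <- pops[[pid]]
    if (nrow(d) == 0L) stop("empty population '", pid, "'", call. = FALSE)
    initial <- stage_index(d$initial_stage)
    fate <- stage_index(d$final_stage, allow_dead = TRUE)
    if (identical(reproduction_type, "anon1")) {
      has_rec <- "recruits" %in% names(d) &&
        any(nzchar(trimws(as.character(d$recruits))), na.rm = TRUE)
      if (has_rec) {
        stop("per-individual recruits present but reproduction_type is 'anon1'",
             call. = FALSE)
      }
      rt <- recruit_totals[[pid]]
      if (is.null(rt)) stop("missing recruit_totals for population '", pid, "'",
                            call. = FALSE)
      history_table(initial, fate, NULL, stages,
                    reproduction_type = "anon1", census = census,
                    sampling = sampling, recruit_totals = rt,
                    reproductive_stages = reproductive_stages,
                    population_id = pid)
    } else {
      rec <- .parse_recruits(if ("recruits" %in% names(d)) d$recruits else
                               rep("", nrow(d)), stages)
      history_table(initial, fate, rec, stages,
                    reproduction_type = reproduction_type, census = census,
                    sampling = sampling, population_id = pid)
    }
  })
  stats::setNames(out, names(pops))
}

# "stage:count;stage:count" -> integer matrix n x m
.parse_recruits <- function(txt, stages) {
  m <- length(stages)
  txt <- as.character(txt)
  txt[is.na(txt)] <- ""
  out <- matrix(0L, length(txt), m)
  for (k in which(nzchar(trimws(txt)))) {
    parts <- strsplit(trimws(txt[k]), ";", fixed = TRUE)[[1]]
    for (p in parts) {
      kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed recruit entry '", p, "'", call. = FALSE)
      j <- match(kv[1], stages)
      if (is.na(j)) stop("unknown recruit stage '", kv[1], "'", call. = FALSE)
      out[k, j] <- out[k, j] + as.integer(kv[2])
    }
  }
  out
}

#' Estimate a projection model from a history table
#'
#' Transition probabilities are observed frequencies:
#' `u_ij = (# individuals starting in j with fate i) / n_j`. Fecundities are
#' average recruit production per stage-j individual; recruits are credited
#' to the parent's initial stage (under a postbreeding census the recruit
#' counts already embody survival-then-reproduction, so the tabulation is the
#' same). Under `"anon1"` the population recruit total per recruit stage is
#' divided by the total number of reproductive individuals and assigned to
#' the reproductive-stage columns.
#'
#' @param table a [history_table].
#' @return A [projection_model] with `n_per_stage` set to the observed
#'   per-stage counts.
#' @export
project_matrix <- function(table) {
  stopifnot(inherits(table, "history_table"))
  m <- length(table$stage_names)
  fit <- .fit_UF(table$initial, table$fate, table$recruits, m,
                 anon1 = identical(table$reproduction_type, "anon1"),
                 recruit_totals = table$recruit_totals,
                 reproductive_stages = table$reproductive_stages)
  projection_model(F = fit$F, U = fit$U, n_per_stage = fit$n,
                   stage_names = table$stage_names, census = table$census,
                   sampling = table$sampling,
                   population_id = table$population_id)
}

#' Reconstruct integer life histories from a projection model
#'
#' Inverts [project_matrix] approximately: for each stage j, `n_per_stage[j]`
#' individuals are allocated to fates by largest-remainder rounding of
#' `n_j * u_ij` (the residual probability is death; remainder ties break
#' toward survival, then toward the lower destination stage, so the
#' reconstruction is deterministic). Recruits to stage i from stage j total
#' `round(n_j * f_ij)` and are spread as evenly as possible across the
#' stage-j individuals (anonymous-reproduction semantics: individual
#' attribution of recruits is a convention, only totals are data).
#'
#' The round trip `project_matrix(histories_from_matrix(M, n))` reproduces M
#' exactly whenever every `n_j * u_ij` and `n_j * f_ij` is an integer.
#'
#' @param model a [projection_model].
#' @param n_per_stage optional integer vector overriding `model$n_per_stage`.
#' @return A [history_table] with `reproduction_type = "identified"`.
#' @export
histories_from_matrix <- function(model, n_per_stage = NULL) {
  stopifnot(inherits(model, "projection_model"))
  m <- length(model$stage_names)
  n <- if (is.null(n_per_stage)) model$n_per_stage else as.integer(n_per_stage)
  if (length(n) != m || any(n < 0)) stop("bad n_per_stage", call. = FALSE)
  need <- colSums(model$U) > 0 | colSums(model$F) > 0
  if (any(need & n == 0L)) {
    stop("stage(s) with nonzero vital rates but zero individuals: ",
         paste(which(need & n == 0L), collapse = ", "), call. = FALSE)
  }
  initial <- fate <- integer(0)
  recruits <- matrix(0L, 0L, m)
  for (j in seq_len(m)) {
    if (n[j] == 0L) next
    pdeath <- 1 - sum(model$U[, j])
    if (pdeath < -1e-9) stop("negative implied death probability in column ", j,
                             call. = FALSE)
    probs <- c(model$U[, j], max(pdeath, 0))
    counts <- largest_remainder(n[j] * probs, total = n[j],
                                tie_order = c(seq_len(m), m + 1L))
    fates_j <- rep.int(c(seq_len(m), 0L), counts)
    rec_j <- matrix(0L, n[j], m)
    for (i in seq_len(m)) {
      tot <- round(n[j] * model$F[i, j])
      if (tot > 0) {
        base <- tot %/% n[j]
        extra <- tot %% n[j]
        rec_j[, i] <- base + c(rep(1L, extra), rep(0L, n[j] - extra))
      }
    }
    initial <- c(initial, rep.int(j, n[j]))
    fate <- c(fate, fates_j)
    recruits <- rbind(recruits, rec_j)
  }
  history_table(initial, fate, recruits, model$stage_names,
                reproduction_type = "identified", census = model$census,
                sampling = model$sampling, population_id = model$population_id)
}

#' Largest-remainder integer apportionment
#'
#' Rounds a nonnegative vector to integers summing to `total`: floor each
#' entry, then give the remaining units to the entries with the largest
#' fractional parts. Ties in the fractional part are broken by position in
#' `tie_order` (earlier wins), which makes the apportionment deterministic.
#'
#' @param x nonnegative numeric vector.
#' @param total target integer sum (default `round(sum(x))`).
#' @param tie_order permutation of `seq_along(x)` giving tie-break priority.
#' @return Integer vector of the same length summing to `total`.
#' @export
largest_remainder <- function(x, total = round(sum(x)),
                              tie_order = seq_along(x)) {
  stopifnot(all(x >= -1e-12))
  x <- pmax(x, 0)
  base <- floor(x + 1e-9)          # guard against 0.9999999 floors
  deficit <- as.integer(total - sum(base))
  out <- as.integer(base)
  if (deficit > 0L) {
    frac <- x - base
    prio <- order(-frac, match(seq_along(x), tie_order))
    take <- prio[seq_len(deficit)]
    out[take] <- out[take] + 1L
  } else if (deficit < 0L) {
    # over-allocation can only come from the floor guard; remove from the
    # smallest fractional parts, last in tie priority
    frac <- x - base
    prio <- order(frac, -match(seq_along(x), tie_order))
    k <- 0L
    for (i in prio) {
      if (k == -deficit) break
      if (out[i] > 0L) { out[i] <- out[i] - 1L; k <- k + 1L }
    }
  }
  out
}

#' Composition of distinct life histories
#'
#' Enumerates the distinct individual histories across one or more history
#' tables (canonical order: initial stage, then fate with death last, then
#' recruit vector lexicographically) and returns, for each table, the
#' relative frequency of each distinct history — a probability vector on a
#' shared support, directly comparable across populations.
#'
#' @param tables a [history_table] or list of them sharing the same stages.
#' @return A matrix with one row per table and one column per distinct
#'   history (rows sum to 1), with history keys as column names.
#' @export
composition_vector <- function(tables) {
  if (inherits(tables, "history_table")) tables <- list(tables)
  .shared_stage_check(tables)
  ids <- .history_ids(tables)
  H <- ids$n_distinct
  P <- matrix(0, length(tables), H)
  for (g in seq_along(ids$per_table)) {
    v <- ids$per_table[[g]]
    P[g, ] <- tabulate(v, H) / length(v)
  }
  colnames(P) <- ids$keys
  rownames(P) <- vapply(tables, function(t) t$population_id, character(1))
  P
}

# ---- internal ---------------------------------------------------------------

.shared_stage_check <- function(tables) {
  m <- length(tables[[1]]$stage_names)
  ok <- vapply(tables, function(t) length(t$stage_names) == m, logical(1))
  if (!all(ok)) {
    stop("populations must have the same number of stages", call. = FALSE)
  }
  invisible(TRUE)
}

# Canonical distinct-history enumeration across tables.  A history key is
# (initial, fate-with-death-last, recruit vector); anon1 histories carry no
# recruits so the key is (initial, fate).  Returns integer history ids per
# table plus the ordered keys.
.history_ids <- function(tables) {
  m <- length(tables[[1]]$stage_names)
  keys <- unlist(lapply(tables, .history_keys, m = m))
  per_len <- vapply(tables, n_individuals, integer(1))
  ord_levels <- sort(unique(keys))
  ids <- match(keys, ord_levels)
  split_idx <- rep(seq_along(tables), per_len)
  list(per_table = split(ids, split_idx),
       keys = ord_levels, n_distinct = length(ord_levels))
}

.history_keys <- function(table, m) {
  fate_sort <- ifelse(table$fate == 0L, m + 1L, table$fate)  # death sorts last
  base <- sprintf("%03d-%03d", table$initial, fate_sort)
  if (is.null(table$recruits)) return(base)
  rec <- apply(table$recruits, 1L, function(r) paste(sprintf("%05d", r), collapse = ""))
  paste0(base, "-", rec)
}

# Fast tabulation of U and F from individual-level vectors.  `credit` is the
# stage whose column each individual's recruits count toward (initial stage;
# see package docs for the census discussion).
.fit_UF <- function(initial, fate, recruits, m, anon1 = FALSE,
                    recruit_totals = NULL, reproductive_stages = NULL) {
  n_j <- tabulate(initial, m)
  scale_col <- rep(1 / pmax(n_j, 1L), each = m)   # columnwise 1/n_j
  alive <- fate > 0L
  U <- matrix(if (any(alive))
    tabulate(fate[alive] + m * (initial[alive] - 1L), m * m) * scale_col
    else 0, m, m)
  Fm <- matrix(0, m, m)
  if (anon1) {
    nrep <- sum(n_j[reproductive_stages])
    if (nrep > 0L && sum(recruit_totals) > 0) {
      Fm[, reproductive_stages] <- recruit_totals / nrep
    }
  } else if (!is.null(recruits) && sum(recruits) > 0) {
    rs <- rowsum(recruits, initial)
    Fm[, as.integer(rownames(rs))] <- t(rs)
    Fm <- Fm * scale_col
  }
  list(U = U, F = Fm, n = n_j)
}
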