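#' Specification of vital rates for simulating demographic data
#'
#' Declares the generating process for a synthetic stage-structured
#' population: per-stage fate distributions (a transition-probability
#' matrix whose column deficits from 1 are death probabilities) and
#' per-stage recruit production (Poisson mean, or a fixed integer count,
#' of recruits to each recruit stage per stage-j individual).
#'
#' @param transitions m x m matrix of fate probabilities (entry i,j:
#'   probability that a stage-j individual ends the interval in stage i);
#'   column sums at most 1, the deficit being the death probability.
#' @param recruit_means m x m matrix: expected (or, with
#'   `recruit_dist = "fixed"`, exact integer) recruits to stage i produced
#'   per stage-j individual per interval.
#' @param n_per_stage integer vector: individuals observed per initial
#'   stage (used directly when `sampling = "fixed_per_stage"`; under
#'   `"random"` sampling it is taken as the expected stage composition and
#'   the realized counts are multinomial).
#' @param stage_names optional stage labels.
#' @param recruit_dist `"poisson"` (default) or `"fixed"`.
#' @param census,sampling see [projection_model].
#' @return An object of class `"vital_rate_spec"`.
#' @export
vital_rate_spec <- function(transitions, recruit_means, n_per_stage,
                            stage_names = NULL,
                            recruit_dist = c("poisson", "fixed"),
                            census = c("prebreeding", "postbreeding"),
                            sampling = c("random", "fixed_per_stage")) {
  recruit_dist <- match.arg(recruit_dist)
  census <- match.arg(census)
  sampling <- match.arg(sampling)
  .check_projection_matrix(transitions, "transitions")
  .check_projection_matrix(recruit_means, "recruit_means")
  m <- nrow(transitions)
  if (nrow(recruit_means) != m) stop("dimension mismatch", call. = FALSE)
  if (any(colSums(transitions) > 1 + 1e-9)) {
    stop("fate probabilities exceed 1 in some column", call. = FALSE)
  }
  if (recruit_dist == "fixed" && any(recruit_means != round(recruit_means))) {
    stop("fixed recruit counts must be integers", call. = FALSE)
  }
  if (length(n_per_stage) != m || any(n_per_stage < 0)) {
    stop("n_per_stage must be nonnegative of length m", call. = FALSE)
  }
  if (is.null(stage_names)) stage_names <- paste0("stage", seq_len(m))
  structure(list(stage_names = stage_names, transitions = transitions,
                 recruit_means = recruit_means,
                 n_per_stage = as.integer(round(n_per_stage)),
                 recruit_dist = recruit_dist, census = census,
                 sampling = sampling),
            class = "vital_rate_spec")
}

#' Implied projection model of a vital-rate specification
#'
#' The (U, F) pair a simulated population converges to as the number of
#' individuals grows: U is the declared transition matrix and F the recruit
#' means.
#'
#' @param spec a [vital_rate_spec].
#' @return A [projection_model].
#' @export
implied_model <- function(spec) {
  stopifnot(inherits(spec, "vital_rate_spec"))
  projection_model(F = spec$recruit_means, U = spec$transitions,
                   n_per_stage = spec$n_per_stage,
                   stage_names = spec$stage_names, census = spec$census,
                   sampling = spec$sampling, population_id = "implied")
}

#' Simulate raw demographic data from declared vital rates
#'
#' Draws each individual's fate from its stage's fate distribution
#' (multinomial over destinations and death) and its recruit production per
#' recruit stage from the declared recruit distribution. Returns records in
#' the raw-data layout (one row per individual); convert with
#' [histories_from_raw] or use [simulate_history_table] directly. Parents
#' are identified by default; anonymous-reproduction variants are obtained
#' by erasing parentage afterwards.
#'
#' @param spec a [vital_rate_spec].
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @param population_id label for the records.
#' @return Data frame with columns `individual_id`, `population_id`,
#'   `initial_stage`, `final_stage`, `recruits`.
#' @export
simulate_population <- function(spec, seed = NULL, population_id = "pop") {
  tab <- simulate_history_table(spec, seed = seed, population_id = population_id)
  as_raw_data(tab)
}

#' @rdname simulate_population
#' @return `simulate_history_table` returns the [history_table] directly.
#' @export
simulate_history_table <- function(spec, seed = NULL, population_id = "pop") {
  stopifnot(inherits(spec, "vital_rate_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(spec$stage_names)
  n_j <- spec$n_per_stage
  if (identical(spec$sampling, "random")) {
    # realized stage counts are themselves a random-sampling outcome
    n_tot <- sum(n_j)
    n_j <- as.vector(stats::rmultinom(1, n_tot, n_j / n_tot))
  }
  if (sum(n_j) == 0L) stop("no individuals to simulate", call. = FALSE)
  initial <- rep.int(seq_len(m), n_j)
  fate <- integer(sum(n_j))
  recruits <- matrix(0L, sum(n_j), m)
  for (j in seq_len(m)) {
    who <- which(initial == j)
    if (!length(who)) next
    pj <- c(spec$transitions[, j], max(1 - sum(spec$transitions[, j]), 0))
    fate[who] <- sample(c(seq_len(m), 0L), length(who), replace = TRUE, prob = pj)
    for (i in seq_len(m)) {
      mu <- spec$recruit_means[i, j]
      if (mu > 0) {
        recruits[who, i] <- if (identical(spec$recruit_dist, "fixed"))
          as.integer(mu) else stats::rpois(length(who), mu)
      }
    }
  }
  history_table(initial, fate, recruits, spec$stage_names,
                reproduction_type = "identified", census = spec$census,
                sampling = spec$sampling, population_id = population_id)
}

#' Perturb one vital rate of a specification
#'
#' Returns a copy of the specification with one fate probability shifted by
#' `delta` (the death probability absorbing the change) or one recruit mean
#' shifted — the effect-size dial for power studies.
#'
#' @param spec a [vital_rate_spec].
#' @param entry length-2 integer vector `c(i, j)`: the matrix entry to
#'   shift.
#' @param delta amount added to the entry.
#' @param what `"transition"` or `"recruit"`.
#' @return A [vital_rate_spec].
#' @export
perturb_spec <- function(spec, entry, delta, what = c("transition", "recruit")) {
  stopifnot(inherits(spec, "vital_rate_spec"), length(entry) == 2L)
  what <- match.arg(what)
  out <- spec
  i <- entry[1]; j <- entry[2]
  if (what == "transition") {
    x <- out$transitions[i, j] + delta
    if (x < -1e-12 || x > 1 + 1e-12) {
      stop("perturbed fate probability outside [0, 1]", call. = FALSE)
    }
    out$transitions[i, j] <- min(max(x, 0), 1)
    if (sum(out$transitions[, j]) > 1 + 1e-9) {
      stop("perturbed column sum exceeds 1 (negative death probability)",
           call. = FALSE)
    }
  } else {
    x <- out$recruit_means[i, j] + delta
    if (x < 0) stop("perturbed recruit mean negative", call. = FALSE)
    out$recruit_means[i, j] <- x
  }
  out
}
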