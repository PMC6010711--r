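#' Resampling estimate of the power of a comparison test
#'
#' Builds the distribution of the test statistic under a true null
#' hypothesis (pooling and permuting individuals, as in
#' [randomization_test]) and under a false one (resampling each population
#' independently with replacement, simulating a fresh sample from each
#' original population). The critical value leaves out the fraction `alpha`
#' of largest null replicates; power is the proportion of alternative
#' replicates strictly greater than that critical value.
#'
#' @inheritParams randomization_test
#' @param alpha significance level (default 0.05).
#' @return An object of class `"power_result"`: `alpha`, `critical`,
#'   `power`, and the null and alternative replicate vectors (for
#'   dual-histogram display).
#' @export
estimate_power <- function(tables,
                           parameter = c("lambda", "R0", "T", "sss", "rv",
                                         "histories"),
                           mode = c("global", "pairwise"), pair = NULL,
                           alpha = 0.05, plan = resampling_plan()) {
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
  stratify <- .should_stratify(plan, tables)
  strata_of <- if (stratify) lapply(tables, `[[`, "initial") else NULL

  set.seed(plan$seed)
  B <- plan$n_reps
  null_reps <- numeric(B)
  for (b in seq_len(B)) {
    groups <- .permutation_indices(ctx$initial, ctx$m, ctx$sizes, strata_of)
    null_reps[b] <- .compute_statistic(.group_values(groups, ctx), ctx$scalar,
                                       pairwise)
  }
  valid_null <- sort(null_reps[!is.na(null_reps)])
  crit <- valid_null[ceiling((1 - alpha) * length(valid_null))]

  # alternative: independent stratified-or-not bootstrap within each group
  alt_reps <- numeric(B)
  for (b in seq_len(B)) {
    groups <- lapply(ctx$orig_groups, function(idx)
      idx[.bootstrap_indices(ctx$initial[idx], ctx$m, stratify)])
    alt_reps[b] <- .compute_statistic(.group_values(groups, ctx), ctx$scalar,
                                      pairwise)
  }
  valid_alt <- alt_reps[!is.na(alt_reps)]
  structure(list(parameter = parameter, mode = mode,
                 statistic = .stat_label(ctx$scalar, pairwise),
                 alpha = alpha, critical = crit,
                 power = sum(valid_alt > crit) / length(valid_alt),
                 null_replicates = null_reps[!is.na(null_reps)],
                 alt_replicates = valid_alt,
                 n_reps = B,
                 n_skipped = (B - length(valid_null)) + (B - length(valid_alt)),
                 seed = plan$seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, digits = 4, ...) {
  cat("Power analysis (", x$mode, "), parameter: ", x$parameter, "\n", sep = "")
  cat("  critical ", x$statistic, " at alpha = ", x$alpha, ": ",
      format(x$critical, digits = digits),
      ";  power = ", format(x$power, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Dual histogram of null and alternative statistic distributions
#'
#' Overlays the distribution of the test statistic when the null hypothesis
#' is true (permutation) and false (independent bootstrap), with the
#' critical value marked — power is the area of the alternative
#' distribution to the right of the critical value.
#'
#' @param x a `"power_result"`.
#' @param ... passed to [graphics::hist].
#' @export
plot.power_result <- function(x, ...) {
  rng <- range(x$null_replicates, x$alt_replicates)
  breaks <- seq(rng[1], rng[2], length.out = 40)
  h0 <- graphics::hist(x$null_replicates, breaks = breaks, plot = FALSE)
  h1 <- graphics::hist(x$alt_replicates, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(h0$counts, h1$counts))
  graphics::plot(h0, col = grDevices::adjustcolor("steelblue", 0.6),
                 border = "white", ylim = ylim,
                 main = "Test statistic under true (blue) and false (yellow) null",
                 xlab = x$statistic, ...)
  graphics::plot(h1, col = grDevices::adjustcolor("gold", 0.6),
                 border = "white", add = TRUE)
  graphics::abline(v = x$critical, col = "red", lwd = 2)
  graphics::mtext(sprintf("critical = %.4g, power = %.4g", x$critical, x$power),
                  side = 3)
  invisible(x)
}

#' Scale a population's sample size at constant vital rates
#'
#' Answers "what would happen if more individuals had been sampled and
#' identical vital rates obtained": the count of each distinct history is
#' multiplied by `factor` and integerized by largest-remainder apportionment
#' so the new total is `round(factor * n)` and history proportions are
#' preserved as closely as possible. This is an idealization — a real larger
#' sample would, by chance, show a different composition of vital rates —
#' but it indicates approximate sample sizes needed to detect differences.
#'
#' @param table a [history_table].
#' @param factor scale factor, at least 1.
#' @return A [history_table] with `round(factor * n)` individuals. For
#'   `"anon1"` tables the population recruit totals are scaled by the same
#'   factor (rounded).
#' @export
scale_counts <- function(table, factor) {
  stopifnot(inherits(table, "history_table"), factor >= 1)
  if (factor == 1) return(table)
  n <- n_individuals(table)
  ids <- .history_ids(list(table))
  id <- ids$per_table[[1]]
  counts <- tabulate(id, ids$n_distinct)
  new_counts <- largest_remainder(factor * counts, total = round(factor * n))
  first_of <- match(seq_len(ids$n_distinct), id)   # representative individual
  idx <- rep.int(first_of, new_counts)
  out <- .subset_history_table(table, idx)
  if (identical(table$reproduction_type, "anon1")) {
    out$recruit_totals <- round(factor * table$recruit_totals)
  }
  out
}

#' Power, p-value and CI width across increasing sample sizes
#'
#' Re-runs the randomization test, the power estimate and a bootstrap
#' confidence interval after inflating every population's sample size by
#' 20% per step (factor `1.2^k`, k = 0..`n_steps`; step 0 is the original
#' data) while holding the realized vital rates constant via
#' [scale_counts]. Produces the classic sample-size curves: p-values fall,
#' power rises, confidence intervals shrink roughly as \eqn{1/\sqrt{n}}.
#'
#' @inheritParams estimate_power
#' @param n_steps number of 20% inflation steps beyond the original size.
#' @param ci_parameter parameter for the per-step confidence interval
#'   (default the test's own parameter; for vector parameters the interval
#'   of element `ci_element` of the first compared population is tracked).
#' @param ci_element stage index tracked when `ci_parameter` is a vector
#'   parameter (default 1).
#' @return An object of class `"scaling_curve"`: a data frame `steps` with
#'   columns `step`, `factor`, `n_total`, `p_value`, `power`, `ci_lower`,
#'   `ci_upper`, `ci_width` (95% interval), plus the per-step result
#'   objects. Step seeds are derived from the plan's master seed, and step 0
#'   reproduces the unscaled analyses exactly.
#' @export
scaling_analysis <- function(tables, parameter = "lambda",
                             mode = c("global", "pairwise"), pair = NULL,
                             alpha = 0.05, n_steps = 6,
                             ci_parameter = NULL, ci_element = 1,
                             plan = resampling_plan()) {
  mode <- match.arg(mode)
  tables <- .as_table_list(tables)
  if (!is.null(pair)) {
    mode <- "pairwise"
    tables <- tables[.resolve_pops(pair, tables)]
  } else if (mode == "pairwise") {
    tables <- tables[1:2]
  }
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (is.null(ci_parameter)) {
    ci_parameter <- if (parameter %in% c("sss", "rv")) parameter else
                    if (parameter == "histories") "lambda" else parameter
  }
  ci_vector <- ci_parameter %in% c("sss", "rv")
  steps <- vector("list", n_steps + 1L)
  for (k in 0:n_steps) {
    fac <- 1.2^k
    scaled <- lapply(tables, scale_counts, factor = fac)
    step_plan <- resampling_plan(plan$n_reps, seed = .step_seed(plan$seed, k),
                                 stratify = plan$stratify)
    test_k <- randomization_test(scaled, parameter = parameter, mode = mode,
                                 plan = step_plan)
    pow_k <- estimate_power(scaled, parameter = parameter, mode = mode,
                            alpha = alpha, plan = step_plan)
    ci_k <- bootstrap_ci(scaled[[1]], parameter = ci_parameter,
                         plan = step_plan, levels = 0.95)
    lo <- if (ci_vector) ci_k$ci[["95%"]]$lower[ci_element] else ci_k$ci[["95%"]]$lower
    hi <- if (ci_vector) ci_k$ci[["95%"]]$upper[ci_element] else ci_k$ci[["95%"]]$upper
    steps[[k + 1L]] <- list(step = k, factor = fac,
                            n_total = sum(vapply(scaled, n_individuals, integer(1))),
                            test = test_k, power = pow_k, ci = ci_k,
                            row = data.frame(step = k, factor = fac,
                                             n_total = sum(vapply(scaled, n_individuals, integer(1))),
                                             p_value = test_k$p_value,
                                             power = pow_k$power,
                                             ci_lower = lo, ci_upper = hi,
                                             ci_width = hi - lo))
  }
  structure(list(parameter = parameter, mode = mode, alpha = alpha,
                 ci_parameter = ci_parameter, ci_element = ci_element,
                 steps = do.call(rbind, lapply(steps, `[[`, "row")),
                 results = steps, seed = plan$seed),
            class = "scaling_curve")
}

.step_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * k) %% .Machine$integer.max)
}

#' @export
print.scaling_curve <- function(x, digits = 4, ...) {
  cat("Sample-size scaling (", x$mode, " test on ", x$parameter,
      ", alpha = ", x$alpha, "); CI tracks ", x$ci_parameter,
      if (x$ci_parameter %in% c("sss", "rv")) paste0("[", x$ci_element, "]"),
      "\n", sep = "")
  print(format(x$steps, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.scaling_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$steps
  graphics::plot(s$step, s$p_value, type = "b", xlab = "size step (x1.2 each)",
                 ylab = "p-value", main = paste("Test on", x$parameter))
  graphics::abline(h = x$alpha, lty = 2)
  graphics::plot(s$step, s$power, type = "b", xlab = "size step",
                 ylab = "power", ylim = c(0, 1))
  graphics::plot(s$step, s$ci_upper, type = "l", col = "red",
                 ylim = range(s$ci_lower, s$ci_upper),
                 xlab = "size step", ylab = "95% CI")
  graphics::lines(s$step, s$ci_lower, col = "blue")
  invisible(x)
}
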