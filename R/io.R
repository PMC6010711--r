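#' Convert a history table to raw-data records
#'
#' One row per individual: `individual_id`, `population_id`,
#' `initial_stage`, `final_stage` (`"DEAD"` for deaths), and `recruits`
#' encoded as `stage:count` pairs separated by `;` (empty when none).
#'
#' @param table a [history_table].
#' @return Data frame in the raw-data layout.
#' @export
as_raw_data <- function(table) {
  stopifnot(inherits(table, "history_table"))
  n <- n_individuals(table)
  rec_txt <- rep("", n)
  if (!is.null(table$recruits)) {
    nz <- which(rowSums(table$recruits) > 0)
    for (k in nz) {
      j <- which(table$recruits[k, ] > 0)
      rec_txt[k] <- paste(paste0(table$stage_names[j], ":",
                                 table$recruits[k, j]), collapse = ";")
    }
  }
  data.frame(individual_id = paste0(table$population_id, "_", seq_len(n)),
             population_id = table$population_id,
             initial_stage = table$stage_names[table$initial],
             final_stage = ifelse(table$fate == 0L, "DEAD",
                                  table$stage_names[pmax(table$fate, 1L)]),
             recruits = rec_txt,
             stringsAsFactors = FALSE)
}

#' Write raw demographic data with a metadata sidecar
#'
#' Writes the raw-data CSV and a YAML (or JSON, by extension) sidecar with
#' `stages`, `reproduction_type`, `census`, `sampling` and, for `"anon1"`,
#' `reproductive_stages` and per-population `recruit_totals`.
#'
#' @param tables a [history_table] or list of them.
#' @param csv_path path of the CSV to write.
#' @param meta_path path of the sidecar (`.yaml`/`.yml` or `.json`).
#' @return Invisibly, the paths written.
#' @export
write_raw_data <- function(tables, csv_path, meta_path) {
  tables <- .as_table_list(tables)
  raw <- do.call(rbind, lapply(tables, as_raw_data))
  utils::write.csv(raw, csv_path, row.names = FALSE, quote = FALSE)
  t1 <- tables[[1]]
  meta <- list(stages = t1$stage_names,
               reproduction_type = t1$reproduction_type,
               census = t1$census, sampling = t1$sampling)
  if (identical(t1$reproduction_type, "anon1")) {
    meta$reproductive_stages <- t1$stage_names[t1$reproductive_stages]
    meta$recruit_totals <- lapply(tables, `[[`, "recruit_totals")
    names(meta$recruit_totals) <- vapply(tables, `[[`, character(1),
                                         "population_id")
  }
  .write_meta(meta, meta_path)
  invisible(c(csv_path, meta_path))
}

.write_meta <- function(meta, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(meta, path)
  }
}

.read_meta <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read raw demographic data with its metadata sidecar
#'
#' @param csv_path raw-data CSV (see [as_raw_data] for the layout).
#' @param meta_path YAML or JSON sidecar declaring `stages`,
#'   `reproduction_type`, `census`, `sampling`, and (for `"anon1"`)
#'   `reproductive_stages` and per-population `recruit_totals`.
#' @return Named list of [history_table]s, one per population.
#' @export
read_raw_data <- function(csv_path, meta_path) {
  meta <- .read_meta(meta_path)
  need <- c("stages", "reproduction_type", "census", "sampling")
  if (!all(need %in% names(meta))) {
    stop("metadata sidecar must declare ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  rt <- if (!is.null(meta$recruit_totals)) {
    lapply(meta$recruit_totals, function(v) {
      x <- as.numeric(v)
      if (length(x) != length(meta$stages)) {
        stop("recruit_totals must have one entry per stage", call. = FALSE)
      }
      x
    })
  }
  histories_from_raw(raw, stages = meta$stages,
                     reproduction_type = meta$reproduction_type,
                     census = meta$census, sampling = meta$sampling,
                     recruit_totals = rt,
                     reproductive_stages = meta$reproductive_stages)
}

#' Read projection-matrix input
#'
#' JSON with one object per population: `population_id`, `stages`, `F` and
#' `U` (row-major), `n_per_stage`, `census`, `sampling`. The individual
#' counts are mandatory: it is not possible to compare populations from
#' their projection matrices if the numbers of individuals used for their
#' construction are not available.
#'
#' @param path JSON file (a single object or an array of them).
#' @return Named list of [projection_model]s.
#' @export
read_matrix_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$stages)) x <- list(x)            # single population
  out <- lapply(x, function(p) {
    if (is.null(p$n_per_stage)) {
      stop("matrix input lacks 'n_per_stage': it is not possible to compare ",
           "populations using their projection matrices if the numbers of ",
           "individuals used for their construction are not available",
           call. = FALSE)
    }
    stages <- unlist(p$stages)
    m <- length(stages)
    as_m <- function(v) matrix(as.numeric(unlist(v)), m, m, byrow = TRUE)
    projection_model(F = as_m(p$F), U = as_m(p$U),
                     n_per_stage = as.integer(unlist(p$n_per_stage)),
                     stage_names = stages,
                     census = if (is.null(p$census)) "prebreeding" else p$census,
                     sampling = if (is.null(p$sampling)) "random" else p$sampling,
                     population_id = if (is.null(p$population_id)) "pop"
                                     else p$population_id)
  })
  names(out) <- vapply(out, `[[`, character(1), "population_id")
  stages_n <- vapply(out, function(p) length(p$stage_names), integer(1))
  if (length(unique(stages_n)) > 1L) {
    stop("populations must have the same number of stages", call. = FALSE)
  }
  out
}

#' Descriptive report for one or more populations
#'
#' For each population: the observed demographic parameters (\eqn{\lambda},
#' \eqn{R_0}, T, stable stage structure, reproductive value), sensitivity
#' and elasticity matrices, the composition of distinct individual
#' histories, bootstrap 90% and 95% confidence intervals with simulated
#' medians for every parameter except the history composition, and — under
#' random sampling — the Keyfitz distance of the observed stage structure to
#' the SSS with its randomization p-value. Under a fixed-per-stage design
#' the SSS-distance block is replaced by an explanation of its omission.
#'
#' @param tables a [history_table] or list of them.
#' @param plan a [resampling_plan] for the bootstrap intervals and the
#'   SSS-distance test.
#' @param parameters scalar/vector parameters to interval (default all).
#' @return An object of class `"describe_report"`; convert with
#'   [report_json].
#' @export
describe <- function(tables, plan = resampling_plan(),
                     parameters = c("lambda", "R0", "T", "sss", "rv")) {
  tables <- .as_table_list(tables)
  comp <- composition_vector(tables)
  pops <- lapply(seq_along(tables), function(k) {
    tab <- tables[[k]]
    model <- project_matrix(tab)
    summ <- demographic_summary(model)
    intervals <- lapply(parameters, function(p)
      bootstrap_ci(tab, p, plan = resampling_plan(plan$n_reps, plan$seed,
                                                  plan$stratify)))
    names(intervals) <- parameters
    sssd <- if (identical(tab$sampling, "random")) {
      d <- sss_distance_test(tab, plan = resampling_plan(plan$n_reps, plan$seed,
                                                         plan$stratify))
      list(delta = d$observed, p_value = d$p_value, n_reps = d$n_reps)
    } else {
      list(omitted = paste("distance to SSS not calculated: per-stage counts",
                           "are fixed by design, so the sampled stage",
                           "distribution does not estimate the population",
                           "structure"))
    }
    list(population_id = tab$population_id, n = n_individuals(tab),
         summary = summ, intervals = intervals,
         history_composition = comp[k, ], sss_distance = sssd)
  })
  structure(list(populations = pops, seed = plan$seed, n_reps = plan$n_reps,
                 stage_names = tables[[1]]$stage_names),
            class = "describe_report")
}

#' @export
print.describe_report <- function(x, digits = 4, ...) {
  for (p in x$populations) {
    cat("==== Population ", p$population_id, " (n = ", p$n, ") ====\n", sep = "")
    print(p$summary, digits = digits)
    for (nm in names(p$intervals)) print(p$intervals[[nm]], digits = digits)
    if (!is.null(p$sss_distance$omitted)) {
      cat("  ", p$sss_distance$omitted, "\n", sep = "")
    } else {
      cat("  distance to SSS: ", format(p$sss_distance$delta, digits = digits),
          " (p = ", format(p$sss_distance$p_value, digits = digits), ")\n",
          sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param x a `"describe_report"`, `"null_distribution"`, `"power_result"`,
#'   `"ltre_result"` or `"scaling_curve"`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @param replicates include replicate vectors (default `FALSE`, summaries
#'   only).
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL, replicates = FALSE) {
  payload <- .jsonable(x, replicates)
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
  }
}

.jsonable <- function(x, replicates = FALSE) {
  if (inherits(x, "null_distribution")) {
    out <- list(type = "randomization_test", statistic = x$statistic,
                parameter = x$parameter, mode = x$mode, observed = x$observed,
                p_value = x$p_value, n_reps = x$n_reps,
                n_skipped = x$n_skipped, unreliable = x$unreliable,
                seed = x$seed, stratified = x$stratified)
    if (replicates) out$replicates <- x$replicates
    return(out)
  }
  if (inherits(x, "power_result")) {
    out <- list(type = "power", statistic = x$statistic,
                parameter = x$parameter, mode = x$mode, alpha = x$alpha,
                critical = x$critical, power = x$power, n_reps = x$n_reps,
                n_skipped = x$n_skipped, seed = x$seed)
    if (replicates) {
      out$null_replicates <- x$null_replicates
      out$alt_replicates <- x$alt_replicates
    }
    return(out)
  }
  if (inherits(x, "ltre_result")) {
    return(if (identical(x$design, "fixed"))
      list(type = "ltre", design = "fixed", lambda_ref = x$lambda_ref,
           lambda = as.list(x$lambda),
           contributions = lapply(x$contributions, function(M)
             apply(M, 1L, as.numeric, simplify = FALSE)),
           residuals = as.list(x$residuals))
    else
      list(type = "ltre", design = "random", V_lambda = x$V_lambda,
           var_lambda = x$var_lambda,
           contributions = apply(x$contributions, 1L, as.numeric,
                                 simplify = FALSE)))
  }
  if (inherits(x, "scaling_curve")) {
    return(list(type = "scaling", parameter = x$parameter, mode = x$mode,
                alpha = x$alpha, steps = x$steps, seed = x$seed))
  }
  if (inherits(x, "describe_report")) {
    return(list(type = "describe", seed = x$seed, n_reps = x$n_reps,
                stages = x$stage_names,
                populations = lapply(x$populations, function(p) {
                  s <- p$summary
                  list(population_id = p$population_id, n = p$n,
                       lambda = s$lambda, R0 = s$R0,
                       T = if (is.na(s$T)) NULL else as.numeric(s$T),
                       T_undefined_reason = attr(s$T, "reason"),
                       sss = as.numeric(s$sss), rv = as.numeric(s$rv),
                       sensitivity = apply(s$sensitivity, 1L, as.numeric,
                                           simplify = FALSE),
                       elasticity = if (!is.null(s$elasticity))
                         apply(s$elasticity, 1L, as.numeric, simplify = FALSE),
                       history_composition = as.list(p$history_composition),
                       intervals = lapply(p$intervals, function(ci)
                         list(observed = as.numeric(ci$observed),
                              median = as.numeric(ci$median),
                              ci = ci$ci, n_reps = ci$n_reps,
                              n_undefined = ci$n_undefined)),
                       sss_distance = p$sss_distance)
                })))
  }
  stop("no JSON serialization for this object", call. = FALSE)
}
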