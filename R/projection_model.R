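#' Stage-structured projection model
#'
#' Bundles the fecundity matrix F (expected recruits to stage i per stage-j
#' individual per projection interval), the transition matrix U (survival and
#' stage-change probabilities; the deficit of each column sum from 1 is the
#' death probability), the implied projection matrix A = F + U, and the
#' sampling metadata required for inference: the number of individuals
#' observed per initial stage, the census type and the sampling design.
#'
#' Individual counts are mandatory: two matrices cannot be compared
#' statistically without knowing how many individuals each was built from —
#' any two non-identical matrices become "significantly different" if enough
#' individuals are assumed.
#'
#' @param F,U square nonnegative numeric matrices of equal dimension m;
#'   column sums of `U` must not exceed 1 (tolerance 1e-9).
#' @param n_per_stage nonnegative integer vector of length m: individuals
#'   observed starting in each stage.
#' @param stage_names optional character vector of stage labels.
#' @param census `"prebreeding"` or `"postbreeding"`: whether individuals are
#'   censused immediately before or after the reproductive season, which
#'   fixes what a recruit count in F means (newborns that survived to the
#'   next census vs newborns at breeding).
#' @param sampling `"random"` (stage proportions in the sample estimate the
#'   population stage structure) or `"fixed_per_stage"` (per-stage counts set
#'   by the experimenter).
#' @param population_id label used in reports.
#' @return An object of class `"projection_model"` with elements
#'   `stage_names`, `F`, `U`, `A`, `n_per_stage`, `census`, `sampling`,
#'   `population_id`.
#' @export
#' @examples
#' m <- projection_model(F = matrix(c(0, 0, 2, 0), 2, 2),
#'                       U = matrix(c(0, 0.5, 0, 0), 2, 2),
#'                       n_per_stage = c(40, 10))
#' dominant_eigenvalue(m$A)
projection_model <- function(F, U, n_per_stage,
                             stage_names = NULL,
                             census = c("prebreeding", "postbreeding"),
                             sampling = c("random", "fixed_per_stage"),
                             population_id = "pop") {
  census <- match.arg(census)
  sampling <- match.arg(sampling)
  .check_projection_matrix(F, "F")
  .check_projection_matrix(U, "U")
  m <- nrow(F)
  if (nrow(U) != m) stop("F and U must have the same dimension", call. = FALSE)
  cs <- colSums(U)
  if (any(cs > 1 + 1e-9)) {
    stop("column sum(s) of U exceed 1 (implies negative death probability): column(s) ",
         paste(which(cs > 1 + 1e-9), collapse = ", "), call. = FALSE)
  }
  if (is.null(stage_names)) stage_names <- paste0("stage", seq_len(m))
  if (length(stage_names) != m) stop("stage_names has wrong length", call. = FALSE)
  if (length(n_per_stage) != m || any(n_per_stage < 0) ||
      any(n_per_stage != round(n_per_stage))) {
    stop("n_per_stage must be a nonnegative integer vector of length m", call. = FALSE)
  }
  dimnames(F) <- dimnames(U) <- list(stage_names, stage_names)
  structure(list(stage_names = stage_names, F = F, U = U, A = F + U,
                 n_per_stage = as.integer(n_per_stage),
                 census = census, sampling = sampling,
                 population_id = population_id),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, digits = 4, ...) {
  cat("Projection model '", x$population_id, "': ", length(x$stage_names),
      " stages, ", sum(x$n_per_stage), " individuals (", x$census,
      " census, ", x$sampling, " sampling)\n", sep = "")
  cat("A = F + U:\n")
  print(round(x$A, digits))
  invisible(x)
}
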