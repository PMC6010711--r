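# Shared fixtures: a 3-stage life cycle (juvenile, subadult, adult) with
# adult reproduction, used across the simulation-based tests.  The vital
# rates are the study conditions for every calibration check; they are not
# per-test dials.

fixture_transitions <- function() {
  matrix(c(0.2, 0.3, 0,
           0,   0.4, 0.35,
           0,   0,   0.65), 3, 3)
}

fixture_fecundity <- function() {
  f <- matrix(0, 3, 3)
  f[1, 3] <- 2
  f
}

# n = 50 individuals by default (25/15/10), the group size used in the
# null-calibration studies
fixture_spec <- function(n_per_stage = c(25, 15, 10),
                         sampling = "random", recruit_dist = "poisson") {
  vital_rate_spec(fixture_transitions(), fixture_fecundity(), n_per_stage,
                  stage_names = c("juv", "sub", "adult"),
                  sampling = sampling, recruit_dist = recruit_dist)
}

# a clearly different population: stronger promotion and juvenile survival
fixture_spec_shifted <- function(n_per_stage = c(25, 15, 10)) {
  perturb_spec(perturb_spec(fixture_spec(n_per_stage), c(3, 2), 0.2),
               c(2, 1), 0.15)
}

fixture_pair <- function(seed, n_per_stage = c(25, 15, 10),
                         spec_b = fixture_spec(n_per_stage)) {
  list(simulate_history_table(fixture_spec(n_per_stage), seed = seed,
                              population_id = "A"),
       simulate_history_table(spec_b, seed = seed + 1L,
                              population_id = "B"))
}

# tiny deterministic two-stage model: half of stage 1 promotes, stage 2
# produces 2 recruits each and dies
fixture_model2 <- function(n = c(10, 10)) {
  projection_model(F = matrix(c(0, 0, 2, 0), 2, 2),
                   U = matrix(c(0, 0.5, 0, 0), 2, 2),
                   n_per_stage = n)
}

# random nonnegative matrix with a simple dominant eigenvalue
random_matrix <- function(m) {
  repeat {
    A <- matrix(stats::runif(m * m, 0, 2), m, m)
    ev <- eigen(A, only.values = TRUE)$values
    re <- Re(ev[abs(Im(ev)) < 1e-9])
    if (length(re) >= 1 && sum(abs(re - max(re)) < 1e-6) == 1) return(A)
  }
}

random_prob_vector <- function(m) {
  x <- stats::rexp(m)
  x / sum(x)
}

# a random projection model whose expected counts n_j * u_ij and n_j * f_ij
# are all integers, so the history reconstruction round-trips exactly
random_integer_model <- function(m = 2) {
  n <- sample(4:12, m, replace = TRUE) * 2L
  U <- matrix(0, m, m)
  Fm <- matrix(0, m, m)
  for (j in seq_len(m)) {
    fate_counts <- stats::rmultinom(1, n[j], rep(1, m + 1))[, 1]
    U[, j] <- fate_counts[seq_len(m)] / n[j]
    Fm[, j] <- sample(0:3, m, replace = TRUE) * n[j] / n[j]  # integer totals / n
  }
  projection_model(F = Fm, U = U, n_per_stage = n)
}
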