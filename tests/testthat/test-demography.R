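test_that("eigen-derived parameters match closed forms", {
  A <- matrix(c(1, 0.5, 1, 0), 2, 2)
  expect_equal(dominant_eigenvalue(A), (1 + sqrt(3)) / 2, tolerance = 1e-10)
  expect_equal(dominant_eigenvalue(diag(2)), 1)

  A2 <- matrix(c(0, 0.5, 2, 0), 2, 2)   # lambda^2 = 1, dominant root +1
  expect_equal(dominant_eigenvalue(A2), 1, tolerance = 1e-10)
  expect_equal(stable_stage_structure(A2), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(reproductive_value(A2), c(1 / 3, 2 / 3), tolerance = 1e-10)
  expect_equal(sensitivity_matrix(A2),
               matrix(c(0.5, 1, 0.25, 0.5), 2, 2), tolerance = 1e-10)
  expect_equal(elasticity_matrix(A2),
               matrix(c(0, 0.5, 0.5, 0), 2, 2), tolerance = 1e-10)

  expect_equal(stable_stage_structure(diag(c(2, 1))), c(1, 0))
  expect_equal(reproductive_value(diag(c(2, 1))), c(1, 0))
  expect_equal(sensitivity_matrix(diag(c(2, 1))),
               matrix(c(1, 0, 0, 0), 2, 2), tolerance = 1e-10)
})

test_that("degenerate dominant eigenvalue is averaged with a warning", {
  expect_warning(w <- stable_stage_structure(diag(2)), "not simple")
  expect_equal(w, c(0.5, 0.5))
})

test_that("fundamental matrix, R0 and generation time match closed forms", {
  U <- matrix(c(0, 0.5, 0, 0), 2, 2)
  expect_equal(fundamental_matrix(U), matrix(c(1, 0.5, 0, 1), 2, 2))
  expect_equal(fundamental_matrix(matrix(0, 2, 2)), diag(2))
  expect_equal(fundamental_matrix(diag(c(0.5, 0))), diag(c(2, 1)))
  expect_error(fundamental_matrix(diag(c(1, 0))), "spectral radius")

  Fm <- matrix(c(0, 0, 2, 0), 2, 2)
  expect_equal(net_reproductive_rate(Fm, U), 1, tolerance = 1e-10)
  expect_equal(net_reproductive_rate(matrix(0, 2, 2), U), 0)
  expect_equal(net_reproductive_rate(2 * Fm, U), 2, tolerance = 1e-10)

  expect_equal(generation_time(2, 2), 1)
  expect_equal(generation_time(2, 4), 2)
  T1 <- generation_time(1, 1)
  expect_true(is.na(T1))
  expect_match(attr(T1, "reason"), "replacement")
})

test_that("keyfitz distance matches hand values and rejects bad input", {
  p <- c(0.5, 0.5)
  expect_equal(keyfitz_delta(p, p), 0)
  expect_equal(keyfitz_delta(c(1, 0), c(0, 1)), 1)
  expect_equal(keyfitz_delta(p, c(0.8, 0.2)), 0.3)
  expect_error(keyfitz_delta(c(1, 0), c(1, 0, 0)), "different lengths")
  expect_error(keyfitz_delta(c(0.7, 0.7), p), "summing to 1")
})

test_that("keyfitz distance is a metric on probability vectors", {
  set.seed(42)
  for (k in 1:200) {
    m <- sample(2:6, 1)
    p <- random_prob_vector(m); q <- random_prob_vector(m)
    r <- random_prob_vector(m)
    expect_equal(keyfitz_delta(p, q), keyfitz_delta(q, p))
    expect_equal(keyfitz_delta(p, p), 0)
    expect_gte(keyfitz_delta(p, q) + keyfitz_delta(q, r) -
                 keyfitz_delta(p, r), -1e-12)
    if (keyfitz_delta(p, q) < 1e-12) expect_equal(p, q)
  }
})

test_that("elasticities sum to 1 and vanish where entries vanish", {
  set.seed(7)
  for (k in 1:1000) {
    A <- random_matrix(sample(2:5, 1))
    A[1, 1] <- 0
    E <- suppressWarnings(elasticity_matrix(A))
    expect_equal(sum(E), 1, tolerance = 1e-8)
    expect_equal(E[1, 1], 0)
  }
})

test_that("dominant eigenpairs satisfy the eigen equations after normalization", {
  set.seed(8)
  for (k in 1:200) {
    A <- random_matrix(sample(2:5, 1))
    lam <- dominant_eigenvalue(A)
    w <- stable_stage_structure(A)
    v <- reproductive_value(A)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(w >= 0) && all(v >= 0))
    expect_lt(max(abs(A %*% w - lam * w)), 1e-8)
    expect_lt(max(abs(t(A) %*% v - lam * v)), 1e-8)
  }
})

test_that("sensitivities agree with central finite differences", {
  set.seed(9)
  eps <- 1e-6
  for (k in 1:40) {
    m <- sample(2:5, 1)
    A <- random_matrix(m)
    S <- sensitivity_matrix(A)
    for (rep in 1:3) {
      i <- sample(m, 1); j <- sample(m, 1)
      Ap <- A; Ap[i, j] <- A[i, j] + eps
      Am <- A; Am[i, j] <- A[i, j] - eps
      fd <- (dominant_eigenvalue(Ap) - dominant_eigenvalue(Am)) / (2 * eps)
      expect_equal(S[i, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("generation time satisfies lambda^T = R0 whenever defined", {
  set.seed(10)
  for (k in 1:100) {
    m <- sample(2:4, 1)
    U <- matrix(stats::runif(m * m, 0, 0.3), m, m)
    U <- sweep(U, 2, pmax(colSums(U) / 0.9, 1), "/")  # column sums <= 0.9
    Fm <- matrix(0, m, m)
    Fm[1, m] <- stats::runif(1, 0.5, 4)
    lam <- dominant_eigenvalue(U + Fm)
    R0 <- net_reproductive_rate(Fm, U)
    Tg <- generation_time(lam, R0)
    if (!is.na(Tg)) expect_equal(lam^Tg, R0, tolerance = 1e-8)
  }
})

test_that("demographic summary reports SSS distance only under random sampling", {
  M <- fixture_model2()
  s <- demographic_summary(M)
  expect_equal(s$lambda, 1, tolerance = 1e-10)
  expect_equal(s$R0, 1, tolerance = 1e-10)
  expect_true(is.na(s$T))
  expect_equal(unname(s$sss), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(s$keyfitz_to_sss,
               keyfitz_delta(c(0.5, 0.5), c(2 / 3, 1 / 3)), tolerance = 1e-10)

  Mf <- projection_model(M$F, M$U, c(10, 10), sampling = "fixed_per_stage")
  expect_null(demographic_summary(Mf)$keyfitz_to_sss)
})

test_that("malformed matrices are rejected", {
  expect_error(dominant_eigenvalue(matrix(1, 2, 3)), "square")
  expect_error(dominant_eigenvalue(matrix(c(1, -1, 0, 1), 2, 2)), "nonnegative")
  expect_error(projection_model(matrix(0, 2, 2),
                                matrix(c(0.6, 0.6, 0, 0), 2, 2), c(5, 5)),
               "exceed 1")
})
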