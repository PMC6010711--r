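stages2 <- c("s1", "s2")

test_that("raw records become history tables", {
  raw <- data.frame(
    individual_id = paste0("i", 1:4),
    population_id = "P",
    initial_stage = "s1",
    final_stage = c("s2", "s2", "DEAD", "DEAD"),
    recruits = ""
  )
  tabs <- histories_from_raw(raw, stages2)
  expect_length(tabs, 1)
  tab <- tabs$P
  expect_equal(n_individuals(tab), 4)
  expect_equal(tab$fate, c(2L, 2L, 0L, 0L))
  expect_equal(ncol(composition_vector(tab)), 2)  # two distinct patterns

  expect_error(histories_from_raw(raw[0, ], stages2), "empty|zero")
  raw_bad <- raw; raw_bad$initial_stage[1] <- "s9"
  expect_error(histories_from_raw(raw_bad, stages2), "unknown stage")
})

test_that("anon1 stores population recruit totals, not per-history recruits", {
  raw <- data.frame(
    individual_id = paste0("i", 1:4), population_id = "P",
    initial_stage = c("s2", "s2", "s1", "s1"),
    final_stage = c("s2", "DEAD", "s2", "s1"), recruits = ""
  )
  tabs <- histories_from_raw(raw, stages2, reproduction_type = "anon1",
                             recruit_totals = list(P = c(20, 0)),
                             reproductive_stages = "s2")
  tab <- tabs$P
  expect_null(tab$recruits)
  expect_equal(tab$recruit_totals, c(20, 0))
  # f = total / all reproductive individuals, equal across reproductive columns
  M <- project_matrix(tab)
  expect_equal(M$F[1, 2], 20 / 2)
  expect_equal(M$F[1, 1], 0)

  raw$recruits <- c("s1:2", "", "", "")
  expect_error(histories_from_raw(raw, stages2, reproduction_type = "anon1",
                                  recruit_totals = list(P = c(20, 0)),
                                  reproductive_stages = "s2"),
               "anon1")
})

test_that("project_matrix computes observed frequencies", {
  # 4 stage-1 individuals, 2 promote; 10 stage-2 individuals produce 20 recruits
  tab <- history_table(
    initial = c(rep(1, 4), rep(2, 10)),
    fate = c(2, 2, 0, 0, rep(0, 10)),
    recruits = rbind(matrix(0L, 4, 2),
                     cbind(rep(2L, 10), rep(0L, 10))),
    stage_names = stages2
  )
  M <- project_matrix(tab)
  expect_equal(M$U[2, 1], 0.5)
  expect_equal(M$F[1, 2], 2.0)
  expect_equal(M$n_per_stage, c(4L, 10L))

  dead <- history_table(initial = c(1, 1, 2), fate = c(0, 0, 0),
                        stage_names = stages2)
  Md <- project_matrix(dead)
  expect_equal(Md$U, matrix(0, 2, 2, dimnames = list(stages2, stages2)))
  expect_equal(dominant_eigenvalue(Md$A), 0)
})

test_that("project_matrix matches the loop-tabulation oracle on random data", {
  set.seed(11)
  for (k in 1:20) {
    m <- sample(2:4, 1)
    n <- 30
    initial <- sample(m, n, replace = TRUE)
    fate <- sample(0:m, n, replace = TRUE)
    recruits <- matrix(rpois(n * m, 0.5), n, m)
    tab <- history_table(initial, fate, recruits, paste0("s", 1:m))
    M <- project_matrix(tab)
    o <- oracle_matrices(initial, fate, recruits, m)
    expect_equal(unname(M$U), o$U)
    expect_equal(unname(M$F), o$F)
  }
})

test_that("histories_from_matrix reconstructs exact multiples and breaks ties to survival", {
  M <- fixture_model2()                      # n = (10, 10)
  tab <- histories_from_matrix(M)
  expect_equal(sum(tab$initial == 1 & tab$fate == 2), 5)
  expect_equal(sum(tab$initial == 1 & tab$fate == 0), 5)
  expect_equal(sum(tab$initial == 2 & tab$fate == 0), 10)
  expect_equal(sum(tab$recruits[tab$initial == 2, 1]), 20)

  M3 <- projection_model(matrix(0, 2, 2), matrix(c(0, 0.5, 0, 0), 2, 2),
                         c(3, 0))
  t3 <- histories_from_matrix(M3)
  expect_equal(sort(t3$fate), c(0L, 2L, 2L))  # 2 promote, 1 dies

  expect_error(histories_from_matrix(fixture_model2(c(0, 10))),
               "zero individuals")
})

test_that("matrix -> histories -> matrix round-trips on integer-consistent models", {
  set.seed(12)
  for (k in 1:25) {
    M <- random_integer_model(sample(2:4, 1))
    tab <- histories_from_matrix(M)
    M2 <- project_matrix(tab)
    expect_equal(M2$U, M$U, tolerance = 1e-12)
    expect_equal(M2$F, M$F, tolerance = 1e-12)
    expect_equal(M2$n_per_stage, M$n_per_stage)
    # transition frequencies + death frequencies account for everyone
    m <- length(M$stage_names)
    deaths <- vapply(seq_len(m), function(j)
      sum(tab$initial == j & tab$fate == 0L), numeric(1))
    expect_equal(unname(colSums(M2$U)) + deaths / pmax(M$n_per_stage, 1),
                 rep(1, m))
  }
})

test_that("largest remainder apportionment is exact and deterministic", {
  expect_equal(largest_remainder(c(12, 6)), c(12L, 6L))
  expect_equal(largest_remainder(c(1.5, 1.5), total = 3), c(2L, 1L))
  expect_equal(largest_remainder(c(1.5, 1.5), total = 3, tie_order = c(2, 1)),
               c(1L, 2L))
  set.seed(13)
  for (k in 1:50) {
    x <- stats::runif(sample(2:8, 1), 0, 10)
    tot <- round(sum(x))
    out <- largest_remainder(x, total = tot)
    expect_equal(sum(out), tot)
    expect_true(all(abs(out - x) < 1))
  }
})

test_that("history composition vectors are aligned, normalized and order-invariant", {
  tab <- history_table(initial = c(1, 1, 1), fate = c(2, 2, 0),
                       stage_names = stages2, population_id = "X")
  P <- composition_vector(tab)
  expect_equal(sort(as.numeric(P)), c(1 / 3, 2 / 3))
  expect_equal(sum(P), 1)

  shuffled <- tab
  shuffled$initial <- tab$initial[c(3, 1, 2)]
  shuffled$fate <- tab$fate[c(3, 1, 2)]
  shuffled$recruits <- tab$recruits[c(3, 1, 2), ]
  expect_equal(composition_vector(shuffled), P)

  # disjoint history sets -> Dw = 1; identical tables -> Dw = 0
  ta <- history_table(initial = c(1, 1), fate = c(2, 2), stage_names = stages2,
                      population_id = "A")
  tb <- history_table(initial = c(2, 2), fate = c(0, 0), stage_names = stages2,
                      population_id = "B")
  Pab <- composition_vector(list(ta, tb))
  expect_equal(stat_vector_pairwise(Pab[1, ], Pab[2, ]), 1)
  Paa <- composition_vector(list(ta, ta))
  expect_equal(stat_vector_pairwise(Paa[1, ], Paa[2, ]), 0)
})
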