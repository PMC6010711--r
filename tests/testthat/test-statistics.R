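test_that("scalar and vector statistics match their formulas", {
  expect_equal(stat_scalar_pairwise(1.2, 1.0), 0.2)
  expect_equal(stat_scalar_pairwise(3, 3), 0)
  expect_equal(stat_scalar_pairwise(1, 2), stat_scalar_pairwise(2, 1))
  expect_equal(stat_scalar_global(c(1, 2, 3)), 2)
  expect_equal(stat_scalar_global(c(5, 5, 5)), 0)
  expect_equal(stat_vector_pairwise(c(0.5, 0.5), c(0.8, 0.2)), 0.3)
  expect_equal(stat_vector_global(rbind(c(1, 0), c(0, 1), c(0.5, 0.5))), 0.5)
  expect_equal(stat_vector_global(rbind(c(0.3, 0.7), c(0.3, 0.7))), 0)
})

test_that("two-population identities: Dg = Dw and dg = dw^2 / 2", {
  set.seed(31)
  for (k in 1:200) {
    m <- sample(2:8, 1)
    p1 <- random_prob_vector(m); p2 <- random_prob_vector(m)
    expect_equal(stat_vector_global(rbind(p1, p2)),
                 stat_vector_pairwise(p1, p2), tolerance = 1e-12)
    x <- stats::rnorm(2)
    expect_equal(stat_scalar_global(x),
                 stat_scalar_pairwise(x[1], x[2])^2 / 2, tolerance = 1e-12)
  }
})

test_that("statistics stay in their ranges on random compositions", {
  set.seed(32)
  for (k in 1:100) {
    n <- sample(2:5, 1); m <- sample(2:6, 1)
    P <- t(replicate(n, random_prob_vector(m)))
    dg <- stat_vector_global(P)
    expect_gte(dg, 0); expect_lte(dg, 1)
    expect_gte(stat_scalar_global(stats::rnorm(n)), 0)
  }
})

test_that("the two-vs-two disjoint case reproduces the exhaustive 6-split null", {
  ta <- history_table(initial = c(1, 1), fate = c(2, 2),
                      stage_names = c("a", "b"), population_id = "A")
  tb <- history_table(initial = c(1, 1), fate = c(0, 0),
                      stage_names = c("a", "b"), population_id = "B")
  r <- suppressWarnings(
    randomization_test(list(ta, tb), "histories", mode = "pairwise",
                       plan = resampling_plan(600, seed = 1)))
  # exhaustive null over the 6 unordered splits is {1, 1, 0, 0, 0, 0}:
  # only the original split and its mirror give Dw = 1
  expect_equal(r$observed, 1)
  expect_equal(r$p_value, 0)
  expect_equal(sort(unique(r$replicates)), c(0, 1))
  expect_equal(mean(r$replicates == 1), 1 / 3, tolerance = 0.07)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration (lambda)", {
  set.seed(33)
  m <- 2
  tab_a <- history_table(initial = c(1, 1, 2, 2, 1),
                         fate = c(2, 0, 2, 0, 1),
                         recruits = matrix(c(0L, 0L, 3L, 1L, 0L,
                                             rep(0L, 5)), 5, 2),
                         stage_names = c("a", "b"), population_id = "A")
  tab_b <- history_table(initial = c(1, 2, 2, 1, 1),
                         fate = c(2, 2, 2, 1, 0),
                         recruits = matrix(c(0L, 4L, 2L, 0L, 0L,
                                             rep(0L, 5)), 5, 2),
                         stage_names = c("a", "b"), population_id = "B")
  pooled_init <- c(tab_a$initial, tab_b$initial)
  pooled_fate <- c(tab_a$fate, tab_b$fate)
  pooled_rec <- rbind(tab_a$recruits, tab_b$recruits)
  ex <- oracle_exhaustive_test(pooled_init, pooled_fate, pooled_rec, m, n1 = 5)

  mc <- randomization_test(list(tab_a, tab_b), "lambda", mode = "pairwise",
                           plan = resampling_plan(10000, seed = 2))
  expect_equal(mc$observed, ex$observed, tolerance = 1e-10)
  se <- sqrt(ex$p * (1 - ex$p) / 10000)
  expect_lt(abs(mc$p_value - ex$p), max(3 * se, 1e-3))
})

test_that("the global statistic's observed value is invariant to table order", {
  tabs <- c(fixture_pair(seed = 34),
            list(simulate_history_table(fixture_spec(), seed = 40,
                                        population_id = "C")))
  r1 <- randomization_test(tabs, "lambda", mode = "global",
                           plan = resampling_plan(999, seed = 1))
  r2 <- randomization_test(rev(tabs), "lambda", mode = "global",
                           plan = resampling_plan(999, seed = 1))
  expect_equal(r1$observed, r2$observed, tolerance = 1e-12)
})

test_that("identical populations give roughly uniform p-values for lambda", {
  set.seed(35)
  pvals <- vapply(1:60, function(s) {
    tabs <- fixture_pair(seed = 600 + 2 * s)
    suppressWarnings(
      randomization_test(tabs, "lambda", mode = "pairwise",
                         plan = resampling_plan(499, seed = s)))$p_value
  }, numeric(1))
  # rejection rate near nominal at two levels
  expect_lt(abs(mean(pvals < 0.2) - 0.2), 0.17)
  expect_lt(mean(pvals < 0.05), 0.18)
})

test_that("generation-time replicates at replacement are skipped and counted", {
  # all individuals survive-and-cycle: many permuted groups sit at lambda = 1
  ta <- history_table(initial = c(1, 1, 2, 2), fate = c(2, 2, 0, 0),
                      recruits = matrix(c(0L, 0L, 2L, 2L, rep(0L, 4)), 4, 2),
                      stage_names = c("a", "b"), population_id = "A")
  tb <- history_table(initial = c(1, 1, 2, 2), fate = c(2, 0, 0, 0),
                      recruits = matrix(c(0L, 0L, 1L, 2L, rep(0L, 4)), 4, 2),
                      stage_names = c("a", "b"), population_id = "B")
  r <- suppressWarnings(randomization_test(list(ta, tb), "T",
                                           mode = "pairwise",
                                           plan = resampling_plan(500, seed = 3)))
  expect_equal(length(r$replicates) + r$n_skipped, 500)
  expect_true(r$n_skipped > 0)       # lambda = 1 splits occur
  expect_true(is.logical(r$unreliable))
})

test_that("planned comparisons pool individuals without averaging", {
  tabs <- c(fixture_pair(seed = 36),
            list(simulate_history_table(fixture_spec_shifted(), seed = 41,
                                        population_id = "C")))
  res <- planned_comparison(tabs, list(list(c("A", "B"), "C")),
                            parameter = "lambda",
                            plan = resampling_plan(999, seed = 4))
  expect_length(res, 1)
  expect_false(attr(res, "nonorthogonal"))
  expect_equal(attr(res, "n_tests"), 1)

  # oracle: identical to a pairwise test on the concatenated table
  direct <- randomization_test(
    list(pool_tables(tabs[1:2], population_id = "A+B"), tabs[[3]]),
    parameter = "lambda", mode = "pairwise",
    plan = resampling_plan(999, seed = 4))
  expect_identical(res[[1]]$observed, direct$observed)
  expect_identical(res[[1]]$p_value, direct$p_value)

  expect_error(planned_comparison(tabs, list(list(c("A", "B"), "B")),
                                  plan = resampling_plan(999, seed = 1)),
               "more than one group")
  res2 <- planned_comparison(tabs, list(list("A", "C"), list(c("A", "B"), "C")),
                             parameter = "lambda",
                             plan = resampling_plan(999, seed = 5))
  expect_true(attr(res2, "nonorthogonal"))
})

test_that("pooled group size equals the sum of its populations", {
  tabs <- fixture_pair(seed = 37)
  pooled <- pool_tables(tabs)
  expect_equal(n_individuals(pooled),
               sum(vapply(tabs, n_individuals, integer(1))))
})

test_that("SSS-distance test refuses fixed designs and accepts exact-SSS data", {
  tab_fixed <- simulate_history_table(fixture_spec(sampling = "fixed_per_stage"),
                                      seed = 38)
  expect_error(sss_distance_test(tab_fixed), "fixed-per-stage")

  # population built exactly at the SSS (2/3, 1/3) of its fitted matrix
  M <- fixture_model2(n = c(20, 10))
  tab <- histories_from_matrix(M)
  tab$sampling <- "random"
  r <- sss_distance_test(tab, plan = resampling_plan(999, seed = 6))
  expect_equal(r$observed, 0, tolerance = 1e-12)
  expect_gt(r$p_value, 0.9)
})

test_that("SSS distance is invariant under consistent stage relabeling", {
  tab <- simulate_history_table(fixture_spec(), seed = 39)
  perm <- c(3, 1, 2)
  relabeled <- tab
  relabeled$initial <- match(tab$initial, perm)
  relabeled$fate <- ifelse(tab$fate == 0L, 0L, match(tab$fate, perm))
  relabeled$recruits <- tab$recruits[, perm]
  relabeled$stage_names <- tab$stage_names[perm]
  r1 <- suppressWarnings(
    sss_distance_test(tab, plan = resampling_plan(499, seed = 7)))
  r2 <- suppressWarnings(
    sss_distance_test(relabeled, plan = resampling_plan(499, seed = 7)))
  expect_equal(r1$observed, r2$observed, tolerance = 1e-10)
})

test_that("SSS-distance test does not spuriously reject populations at their own SSS", {
  # draw initial stages at the implied model's SSS so the null holds; the
  # bootstrap null adds resampling noise on top of the observed discrepancy,
  # so replicate distances tend to exceed the observed one: p-values sit
  # high and the test is conservative, never anti-conservative
  base <- fixture_spec()
  sss <- stable_stage_structure(implied_model(base)$A)
  spec <- vital_rate_spec(fixture_transitions(), fixture_fecundity(),
                          n_per_stage = round(120 * sss),
                          stage_names = c("juv", "sub", "adult"))
  pvals <- vapply(1:100, function(s) {
    tab <- simulate_history_table(spec, seed = 9000 + s)
    suppressWarnings(
      sss_distance_test(tab, plan = resampling_plan(299, seed = s)))$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.05)
  expect_gt(mean(pvals), 0.5)
})

test_that("tests demand comparable populations", {
  tabs <- fixture_pair(seed = 42)
  tabs[[2]]$sampling <- "fixed_per_stage"
  expect_error(randomization_test(tabs, "lambda"), "sampling")
  tabs <- fixture_pair(seed = 43)
  tabs[[2]]$census <- "postbreeding"
  expect_error(randomization_test(tabs, "lambda"), "census")
})
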