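test_that("quantile ranks follow the average-tie r/n convention", {
  m <- matrix(c(5.2, 1.1, 3.3, 7.8), 4, 1,
              dimnames = list(letters[1:4], "s"))
  expect_equal(unname(quantile_ranks(m)[, 1]), c(0.75, 0.25, 0.50, 1.00))

  tied <- matrix(c(2, 2, 5, 5), 4, 1, dimnames = list(letters[1:4], "s"))
  expect_equal(unname(quantile_ranks(tied)[, 1]),
               c(0.375, 0.375, 0.875, 0.875))

  # monotone invariance
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(paste0("g", 1:30), "s"))
  expect_identical(quantile_ranks(x), quantile_ranks(exp(x)))

  expect_error(quantile_ranks(matrix(1, 1, 1, dimnames = list("g", "s"))),
               "at least 2")
})

test_that("worked scoring example reproduces A, B and the consensus call", {
  r <- icms_scores(worked_example_ranks(), tiny_sets())
  expect_equal(r$Mq2U, 0.95)
  expect_equal(r$Mq2D, 0.15)
  expect_equal(r$Mq3U, 0.45)
  expect_equal(r$Mq3D, 0.65)
  expect_equal(r$score_A, 0.95 / 0.15 - 0.45 / 0.65, tolerance = 1e-12)
  expect_equal(r$score_A, 5.641026, tolerance = 1e-6)
  expect_equal(r$score_B, 2.0)
  expect_identical(r$consensus, "iCMS2")
})

test_that("swapping iCMS2 and iCMS3 class assignments negates score B", {
  q <- worked_example_ranks()
  swapped <- tiny_sets()
  swapped[c("iCMS2_up", "iCMS3_up")] <- swapped[c("iCMS3_up", "iCMS2_up")]
  swapped[c("iCMS2_down", "iCMS3_down")] <-
    swapped[c("iCMS3_down", "iCMS2_down")]
  r1 <- icms_scores(q, tiny_sets())
  r2 <- icms_scores(q, swapped)
  expect_equal(r2$score_B, -r1$score_B)
  expect_identical(r2$consensus, "iCMS3")
})

test_that("all-tied ranks give zero scores and a flagged discordant call", {
  q <- matrix(rep(0.5, 8), 8, 1, dimnames = list(letters[1:8], "s"))
  r <- icms_scores(q, tiny_sets())
  expect_equal(r$score_A, 0)
  expect_equal(r$score_B, 0)
  expect_identical(r$consensus, "discordant")
  expect_true(r$zero_score)
})

test_that("Sq equals Mq times gene count and coverage drops absent genes", {
  set.seed(21)
  sim <- simulate_cohort(n_genes = 120, class_size = c(9, 7, 5, 11),
                         n_per_label = 4, seed = 21)
  q <- quantile_ranks(sim$matrix)
  r <- icms_scores(q, sim$sets)
  for (cl in c("2U", "2D", "3U", "3D")) {
    expect_equal(r[[paste0("Sq", cl)]],
                 r[[paste0("Mq", cl)]] * r[[paste0("n_", cl)]],
                 tolerance = 1e-9)
  }
  # remove half of one class from the matrix: scored over the remainder
  drop <- sim$sets$iCMS3_up[1:2]
  m2 <- expression_matrix(
    unclass(sim$matrix)[setdiff(rownames(sim$matrix), drop), ], "gene")
  r2 <- score_cohort(m2, sim$sets)
  expect_identical(unique(r2$n_3U), 3L)
  expect_equal(unname(attr(r2, "coverage")["3U"]), 3 / 5)
  # fully absent class is an error naming the class
  m3 <- expression_matrix(
    unclass(sim$matrix)[setdiff(rownames(sim$matrix), sim$sets$iCMS3_up), ],
    "gene")
  expect_error(score_cohort(m3, sim$sets), "iCMS3_up")
})

test_that("scores match the brute-force oracle on random matrices", {
  set.seed(99)
  sets <- list(iCMS2_up = sprintf("g%02d", 1:8),
               iCMS2_down = sprintf("g%02d", 9:16),
               iCMS3_up = sprintf("g%02d", 17:24),
               iCMS3_down = sprintf("g%02d", 25:32))
  for (i in 1:100) {
    m <- matrix(round(rnorm(500, 8, 2), 2), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("s%02d", 1:10)))
    mine <- score_cohort(expression_matrix(m, "gene"), sets)
    ref <- oracle_scores(m, sets)
    expect_equal(mine$score_A, ref$score_A, tolerance = 1e-12)
    expect_equal(mine$score_B, ref$score_B, tolerance = 1e-12)
  }
})

test_that("scores and calls are rank-invariant under monotone transforms", {
  set.seed(5)
  sim <- simulate_cohort(n_genes = 80, class_size = 8, n_per_label = 5,
                         seed = 5)
  base <- score_cohort(sim$matrix, sim$sets)
  transforms <- list(function(x) 2 * x + 1, exp, function(x) x^3,
                     function(x) atan(x / 10), function(x) 10^(x / 4))
  for (f in transforms) {
    m2 <- expression_matrix(f(unclass(sim$matrix)), "gene")
    r2 <- score_cohort(m2, sim$sets)
    expect_identical(r2$score_A, base$score_A)
    expect_identical(r2$score_B, base$score_B)
    expect_identical(r2$consensus, base$consensus)
  }
})

test_that("cohort scoring is columnwise: duplicates and singletons agree", {
  set.seed(31)
  sim <- simulate_cohort(n_genes = 60, class_size = 6, n_per_label = 3,
                         seed = 31)
  m <- unclass(sim$matrix)
  all_r <- score_cohort(sim$matrix, sim$sets)
  one <- expression_matrix(m[, 2, drop = FALSE], "gene")
  r1 <- score_cohort(one, sim$sets)
  expect_equal(r1$score_A, all_r$score_A[2])
  expect_equal(r1$score_B, all_r$score_B[2])

  dup <- cbind(m, m[, 1, drop = FALSE])
  colnames(dup)[ncol(dup)] <- "copy"
  rd <- score_cohort(expression_matrix(dup, "gene"), sim$sets)
  expect_equal(rd$score_A[ncol(dup)], rd$score_A[1])
  expect_equal(rd$score_B[ncol(dup)], rd$score_B[1])
})

test_that("normalized score B equalizes unequal class sizes", {
  q <- matrix(c(0.9, 1.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8), ncol = 1,
              dimnames = list(letters[1:10], "s"))
  sets <- list(iCMS2_up = c("a", "b"), iCMS2_down = c("c", "d"),
               iCMS3_up = c("e", "f", "g"), iCMS3_down = c("h", "i", "j"))
  r <- icms_scores(q, sets, normalize_b = TRUE)
  expect_equal(r$score_B,
               (0.95 - 0.15) - (mean(c(0.3, 0.4, 0.5)) - mean(c(0.6, 0.7, 0.8))))
})
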