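sphere <- function(x) sum(x^2)

test_that("leader assignment follows 1 + (i mod NL)", {
  expect_equal(assign_leader(0, 3), 1L)
  expect_equal(assign_leader(3, 3), 1L)
  expect_equal(assign_leader(5, 3), 3L)
  expect_equal(vapply(0:7, assign_leader, integer(1), NL = 4),
               c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L))
})

test_that("parameters are validated", {
  expect_error(coa_params(n_coots = 5, n_leaders = 5))
  expect_error(coa_params(lower = 1, upper = 1))
  expect_error(coa_params(iter_max = -1))
})

test_that("initial populations are uniform over the box", {
  p <- coa_params(n_coots = 2000, n_leaders = 10, lower = -2, upper = 6,
                  seed = 17)
  st <- coa_init(function(x) sum(x^2), p, dim = 5)
  draws <- rbind(st$followers, st$leaders)
  expect_equal(dim(draws), c(2000L, 5L))
  expect_true(all(draws >= -2 & draws <= 6))
  se <- (8 / sqrt(12)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("zero iterations return the best of the initial population", {
  p <- coa_params(n_coots = 12, iter_max = 0, lower = -3, upper = 3,
                  seed = 4)
  fit <- coa_minimize(sphere, p, dim = 3)
  st <- coa_init(sphere, p, dim = 3)
  expect_equal(fit$gBest_fitness,
               min(c(st$follower_fit, st$leader_fit)))
  expect_length(fit$history, 0L)
})

test_that("runs are deterministic under a fixed seed", {
  p <- coa_params(n_coots = 15, iter_max = 30, lower = -5, upper = 5,
                  seed = 9)
  a <- coa_minimize(sphere, p, dim = 4)
  b <- coa_minimize(sphere, p, dim = 4)
  expect_identical(a$gBest, b$gBest)
  expect_identical(a$history, b$history)
})

test_that("every evaluated candidate stays inside the box", {
  worst <- 0
  watched <- function(x) {
    worst <<- max(worst, max(x - 2), max(-1 - x), 0)
    sum(x^2)
  }
  p <- coa_params(n_coots = 20, iter_max = 40, lower = -1, upper = 2,
                  seed = 21)
  fit <- coa_minimize(watched, p, dim = 6)
  expect_equal(worst, 0)
  expect_true(all(fit$gBest >= -1 & fit$gBest <= 2))
})

test_that("the best-so-far history is non-increasing (elitism)", {
  for (s in 1:5) {
    fit <- coa_minimize(sphere,
                        coa_params(n_coots = 20, iter_max = 60,
                                   lower = -10, upper = 10, seed = s),
                        dim = 5)
    expect_true(all(diff(fit$history) <= 0))
  }
})

test_that("the 1D convex quadratic is solved to 1e-3 in most seeds", {
  hits <- 0
  for (s in 1:10) {
    fit <- coa_minimize(function(x) (x - 0.7)^2,
                        coa_params(n_coots = 20, iter_max = 100,
                                   lower = -5, upper = 5, seed = s),
                        dim = 1)
    if (abs(fit$gBest - 0.7) < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("non-finite fitness values are treated as +Inf", {
  f <- function(x) if (x[1] > 0) NaN else sum(x^2)
  fit <- coa_minimize(f, coa_params(n_coots = 10, iter_max = 20,
                                    lower = -1, upper = 1, seed = 2),
                      dim = 2)
  expect_true(is.finite(fit$gBest_fitness))
  expect_lte(fit$gBest[1], 0)
})

test_that("tidy and glance expose the optimizer trace", {
  fit <- coa_minimize(sphere, coa_params(iter_max = 10, seed = 1), dim = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10L)
  expect_equal(td$best_fitness, fit$history)
  gl <- glance(fit)
  expect_equal(gl$best_fitness, fit$gBest_fitness)
  expect_equal(gl$dim, 2L)
})
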