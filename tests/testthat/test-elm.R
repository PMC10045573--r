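test_that("hidden layer output matches the direct definition", {
  m <- list(W = matrix(0, 4, 3), b = rep(0, 4), activation = "sigmoid")
  H <- hidden_output(m, matrix(rnorm(6), 2, 3))
  expect_true(all(H == 0.5))

  m1 <- list(W = matrix(1, 1, 1), b = 0, activation = "sigmoid")
  expect_equal(hidden_output(m1, matrix(0, 1, 1)), matrix(0.5, 1, 1))

  set.seed(10)
  W <- matrix(rnorm(15), 5, 3)
  b <- rnorm(5)
  X <- matrix(rnorm(12), 4, 3)
  mt <- list(W = W, b = b, activation = "tanh")
  H <- hidden_output(mt, X)
  for (j in 1:4) for (i in 1:5) {
    expect_equal(H[j, i], tanh(sum(W[i, ] * X[j, ]) + b[i]),
                 tolerance = 1e-12)
  }
  expect_error(hidden_output(mt, matrix(0, 2, 2)), "input size")
})

test_that("the exact pseudoinverse interpolates when L equals N", {
  for (s in 1:10) {
    set.seed(1000 + s)
    X <- matrix(rnorm(20 * 3), 20)
    T <- matrix(rnorm(20 * 2), 20)
    m <- elm_train(X, T, L = 20, seed = s, ridge = 0)
    resid <- norm(hidden_output(m, X) %*% m$beta - T, "F")
    expect_lt(resid, 1e-6)
  }
})

test_that("beta satisfies the normal equations and minimizes the cost", {
  set.seed(11)
  X <- matrix(rnorm(40 * 4), 40)
  T <- matrix(rnorm(40), 40)
  m <- elm_train(X, T, L = 15, seed = 2, ridge = 0)
  H <- hidden_output(m, X)
  lhs <- crossprod(H) %*% m$beta
  rhs <- crossprod(H, T)
  expect_lt(norm(lhs - rhs, "F") / max(norm(rhs, "F"), 1e-12), 1e-8)

  cost <- sum((H %*% m$beta - T)^2)
  for (k in 1:100) {
    other <- m$beta + matrix(rnorm(length(m$beta), sd = 0.1), nrow(m$beta))
    expect_lte(cost, sum((H %*% other - T)^2) + 1e-10)
  }
})

test_that("a single sample and unit reduce to scalar division", {
  x <- matrix(0.3, 1, 1)
  t <- matrix(2, 1, 1)
  m <- elm_train(x, t, L = 1, seed = 5, ridge = 0)
  g <- 1 / (1 + exp(-(m$W[1, 1] * 0.3 + m$b[1])))
  expect_equal(m$beta[1, 1], 2 / g, tolerance = 1e-8)
})

test_that("ELM separates XOR with enough hidden units", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  m <- elm_train(X, y, L = 10, seed = 2, ridge = 0)
  expect_equal(elm_predict(m, X), y)
})

test_that("prediction rules: 0.5 tie labels 1, rows map independently", {
  m <- structure(list(W = matrix(0, 2, 2), b = c(0, 0), activation = "relu",
                      beta = matrix(c(0.25, 0.25), 2, 1), L = 2L),
                 class = "elm_model")
  # H = 0 (relu of 0), outputs 0 -> label 0; then force 0.5 via bias
  expect_equal(elm_predict(m, matrix(0, 1, 2)), 0L)
  m$b <- c(1, 1)  # H = 1, output = 0.5 exactly
  expect_equal(elm_predict(m, matrix(0, 1, 2)), 1L)

  set.seed(12)
  mm <- elm_train(matrix(rnorm(30), 15, 2), rbinom(15, 1, 0.5), L = 8,
                  seed = 3)
  X <- matrix(rnorm(10), 5, 2)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(elm_predict(mm, X)[perm], elm_predict(mm, X[perm, ]))

  mm$beta <- NULL
  expect_error(elm_predict(mm, X), "output weights")
})

test_that("models serialize to JSON and back", {
  set.seed(13)
  m <- elm_train(matrix(rnorm(20), 10, 2), rbinom(10, 1, 0.5), L = 4,
                 seed = 1)
  p <- tempfile(fileext = ".json")
  elm_save(m, p)
  m2 <- elm_load(p)
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(elm_raw_output <- hidden_output(m, X) %*% m$beta,
               hidden_output(m2, X) %*% m2$beta, tolerance = 1e-12)
  gl <- glance(m2)
  expect_equal(gl$hidden_units, 4L)
  expect_false(gl$coa_selected)
  expect_equal(nrow(tidy(m2)), 4L)
})

test_that("the stratified validation split honours the fraction", {
  y <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1)
  val <- geoclick:::stratified_split(y, 0.2, seed = 3)
  expect_length(val, 2L)
  expect_equal(sort(as.numeric(y[val])), c(0, 1))
})

test_that("COA-selected weights are at least as fit as the initial best", {
  set.seed(14)
  d <- two_gaussians_set(80, 3, separation = 2, seed = 5)
  coa <- coa_params(n_coots = 8, n_leaders = 2, iter_max = 6, seed = 6)
  m <- coa_elm_train(d$X, d$y, L = 10, coa = coa, seed = 6)
  fit <- attr(m, "coa")
  expect_s3_class(fit, "coa_fit")
  expect_true(all(diff(fit$history) <= 0))
  expect_true(glance(m)$coa_selected)
  # deterministic end to end
  m2 <- coa_elm_train(d$X, d$y, L = 10, coa = coa, seed = 6)
  expect_identical(m$beta, m2$beta)
})
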