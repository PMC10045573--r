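test_that("refinement cue maps follow the softmax of click distances", {
  # 1x3 image [0,1,3]: fg click at column 1, bg click at column 3 gives the
  # middle pixel Df = 1, Db = 2
  img <- matrix(c(0, 1, 3), 1)
  clicks <- click_set(fg = matrix(c(1, 1), 1), bg = matrix(c(1, 3), 1))
  maps <- refinement_cue_maps(img, clicks, connectivity = 4)
  Ef_expected <- exp(-1) / (exp(-1) + exp(-2))
  expect_equal(maps$Ef[1, 2], Ef_expected, tolerance = 1e-9)
  expect_equal(maps$alpha[1, 2], exp(-1), tolerance = 1e-9)
  # at the fg click: alpha = 1 and Ef = 1/(1 + e^-Db) > 0.5
  expect_equal(maps$alpha[1, 1], 1)
  expect_equal(maps$Ef[1, 1], 1 / (1 + exp(-3)), tolerance = 1e-9)
  expect_gt(maps$Ef[1, 1], 0.5)
  expect_equal(maps$Ef + maps$Eb, array(1, c(1, 3)))
  expect_false(maps$no_clicks)
})

test_that("empty click sets give neutral, flagged fusion maps", {
  img <- matrix(runif(25), 5)
  maps <- refinement_cue_maps(img, click_set())
  expect_true(maps$no_clicks)
  expect_true(all(maps$Ef == 0.5))
  expect_true(all(maps$alpha < 1e-300))

  only_bg <- refinement_cue_maps(img, click_set(bg = matrix(c(2, 2), 1)))
  expect_true(all(only_bg$Ef < 0.5))  # e^-Df vanishes for the empty fg side
})

test_that("fusion is the pixelwise convex combination of P and E", {
  set.seed(21)
  d <- c(4, 4)
  P <- probability_pair(array(runif(16), d))
  mk <- function(alpha, Ef) {
    structure(list(Ef = array(Ef, d), Eb = array(1 - Ef, d),
                   alpha = array(alpha, d), no_clicks = FALSE),
              class = "fusion_maps")
  }
  expect_equal(fuse_probabilities(P, mk(0, 0.9))$Pf, P$Pf)
  expect_equal(fuse_probabilities(P, mk(1, 0.9))$Pf, array(0.9, d))

  a <- exp(-1)
  Ef <- exp(-1) / (exp(-1) + exp(-2))
  R <- fuse_probabilities(probability_pair(array(0.5, d)), mk(a, Ef))
  expect_equal(R$Pf[1, 1], (1 - a) * 0.5 + a * Ef, tolerance = 1e-12)
  expect_equal(R$Pf[1, 1], 0.5850017, tolerance = 1e-6)

  Rr <- fuse_probabilities(P, mk(0.3, 0.8))
  expect_equal(Rr$Pf + Rr$Pb, array(1, d), tolerance = 1e-12)
})

test_that("CRF energy reproduces hand-computed cases", {
  # uniform probabilities, no pairwise: N log 2 for any labeling
  d <- c(3, 3)
  R <- probability_pair(array(0.5, d))
  img <- matrix(0, 3, 3)
  p0 <- crf_params(lam = 0)
  expect_equal(crf_energy(binary_mask(array(0L, d)), R, img, params = p0),
               9 * log(2))
  expect_equal(crf_energy(binary_mask(array(1L, d)), R, img, params = p0),
               9 * log(2))

  # uniform image, constant labeling: pairwise sum is zero
  p1 <- crf_params(lam = 3, sigma = 1)
  expect_equal(crf_energy(binary_mask(array(1L, d)), R, img, params = p1),
               9 * log(2))

  # 2x1 image, I = [0,0], r = [0.9, 0.1], lambda = 1, sigma = 1
  R2 <- probability_pair(array(c(0.9, 0.1), c(2, 1)))
  e <- crf_energy(binary_mask(array(c(1L, 0L), c(2, 1))), R2,
                  matrix(0, 2, 1), params = crf_params(lam = 1, sigma = 1))
  expect_equal(e, -log(0.9) - log(0.9) + 1, tolerance = 1e-12)

  # labels violating a click are rejected
  expect_error(
    crf_energy(binary_mask(array(0L, d)), R, img,
               click_set(fg = matrix(c(2, 2), 1)), p0),
    "violates"
  )
})

test_that("graph cut reduces to thresholding when the pairwise term is off", {
  set.seed(33)
  Pf <- array(runif(36, 0.02, 0.98), c(6, 6))
  R <- probability_pair(Pf)
  cut <- graph_cut_refine(R, matrix(0, 6, 6), params = crf_params(lam = 0))
  expect_equal(unclass(geoclick:::mask_values(cut)),
               array(as.integer(Pf >= 0.5), c(6, 6)))
})

test_that("clicked pixels are hard-constrained in the cut", {
  Pf <- array(0.9, c(5, 5))
  R <- probability_pair(Pf)
  img <- matrix(0, 5, 5)
  clicks <- click_set(bg = matrix(c(3, 3), 1))
  for (lam in c(0, 2)) {
    cut <- graph_cut_refine(R, img, clicks, crf_params(lam = lam))
    expect_equal(cut[3, 3][[1]], 0L)
  }
  expect_error(
    graph_cut_refine(R, img, structure(list(fg = matrix(c(2, 2), 1),
                                            bg = matrix(c(2, 2), 1)),
                                       class = "click_set")),
    "contradictory"
  )
})

test_that("graph cut attains the exhaustive minimum on random instances", {
  set.seed(44)
  for (k in 1:20) {
    img <- matrix(runif(9, 0, 10), 3, 3)
    R <- probability_pair(array(runif(9, 0.02, 0.98), c(3, 3)))
    lam <- c(0, 0.5, 2)[(k %% 3) + 1]
    params <- crf_params(lam = lam, sigma = 2, connectivity = 8)
    clicks <- if (k %% 4 == 0) {
      click_set(fg = matrix(c(1, 1), 1), bg = matrix(c(3, 3), 1))
    } else click_set()
    cut <- graph_cut_refine(R, img, clicks, params)
    e_cut <- crf_energy(cut, R, img, clicks, params)
    e_min <- oracle_crf_minimum(R, img, clicks, params)
    expect_equal(e_cut, e_min, tolerance = 1e-9)
  }
})

test_that("cut energy never exceeds simple candidate labelings", {
  set.seed(55)
  for (k in 1:5) {
    img <- matrix(runif(48, 0, 5), 6, 8)
    R <- probability_pair(array(runif(48, 0.05, 0.95), c(6, 8)))
    params <- crf_params(lam = 1.5, sigma = 1)
    cut <- graph_cut_refine(R, img, params = params)
    e_cut <- crf_energy(cut, R, img, params = params)
    for (cand in list(binary_mask(R$Pf >= 0.5),
                      binary_mask(array(1L, c(6, 8))),
                      binary_mask(array(0L, c(6, 8))))) {
      expect_lte(e_cut, crf_energy(cand, R, img, params = params) + 1e-9)
    }
  }
})

test_that("a new foreground click flips its pixel and sticks", {
  set.seed(66)
  Pf <- array(0.2, c(7, 7))
  R <- probability_pair(Pf)
  img <- matrix(rnorm(49), 7)
  params <- crf_params(lam = 1)
  base <- graph_cut_refine(R, img, params = params)
  expect_equal(base[4, 4][[1]], 0L)
  clicked <- graph_cut_refine(R, img, click_set(fg = matrix(c(4, 4), 1)),
                              params)
  expect_equal(clicked[4, 4][[1]], 1L)
})
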