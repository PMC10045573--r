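test_that("click sets validate coordinates and serialize to JSON", {
  cs <- click_set(fg = rbind(c(3, 4), c(5, 6)), bg = rbind(c(1, 1)))
  expect_equal(nrow(cs$fg), 2L)
  expect_error(click_set(fg = rbind(c(2, 2)), bg = rbind(c(2, 2))),
               "foreground and background")
  js <- clicks_to_json(cs)
  back <- clicks_from_json(js)
  expect_equal(back$fg, cs$fg)
  expect_equal(back$bg, cs$bg)
  # 0-based on the wire
  expect_match(as.character(js), "[[2,3]", fixed = TRUE)
})

test_that("inner-margin simulation covers the axis extremes of a square", {
  m <- array(0L, c(20, 20))
  m[4:17, 6:15] <- 1L
  mask <- binary_mask(m)
  cs <- simulate_inner_margin_points(mask, n_extra = 0, seed = 2)
  pts <- cs$fg
  expect_lte(nrow(pts), 4L)
  expect_true(all(m[pts] == 1L))
  # every click within the inward shift range (<= 3 px) of the boundary
  bd <- geoclick:::inner_boundary(m)
  for (i in seq_len(nrow(pts))) {
    dmin <- min(sqrt((bd[, 1] - pts[i, 1])^2 + (bd[, 2] - pts[i, 2])^2))
    expect_lte(dmin, 3 * sqrt(2))
  }
  # the expanded bbox of the clicks covers the whole mask
  box <- relaxed_bbox(cs, expand = 5, image_shape = c(20, 20))
  idx <- which(m == 1L, arr.ind = TRUE)
  expect_true(all(idx[, 1] >= box$lo[1] & idx[, 1] <= box$hi[1] &
                  idx[, 2] >= box$lo[2] & idx[, 2] <= box$hi[2]))
})

test_that("degenerate masks still produce valid clicks", {
  m <- array(0L, c(9, 9))
  m[5, 5] <- 1L
  cs <- simulate_inner_margin_points(binary_mask(m), n_extra = 3, seed = 1)
  expect_true(all(cs$fg[, 1] == 5L & cs$fg[, 2] == 5L))
  expect_error(simulate_inner_margin_points(binary_mask(array(0L, c(4, 4)))),
               "no foreground")
})

test_that("simulated clicks stay inside random blobs and cover them", {
  for (s in 1:50) {
    mask <- random_blob_mask(seed = s)
    cs <- simulate_inner_margin_points(mask, n_extra = 5, seed = s)
    m <- geoclick:::mask_values(mask)
    expect_true(all(m[cs$fg] == 1L))
    box <- relaxed_bbox(cs, expand = 5, image_shape = dim(m))
    idx <- which(m == 1L, arr.ind = TRUE)
    expect_true(all(idx[, 1] >= box$lo[1] & idx[, 1] <= box$hi[1] &
                    idx[, 2] >= box$lo[2] & idx[, 2] <= box$hi[2]))
  }
  a <- simulate_inner_margin_points(random_blob_mask(seed = 3), seed = 11)
  b <- simulate_inner_margin_points(random_blob_mask(seed = 3), seed = 11)
  expect_identical(a$fg, b$fg)
})

test_that("more extra clicks never shrink the tight bounding box", {
  for (s in 1:10) {
    mask <- random_blob_mask(seed = 100 + s)
    shp <- dim(geoclick:::mask_values(mask))
    b0 <- relaxed_bbox(simulate_inner_margin_points(mask, n_extra = 0,
                                                    seed = s), 0, shp)
    b8 <- relaxed_bbox(simulate_inner_margin_points(mask, n_extra = 8,
                                                    seed = s), 0, shp)
    expect_true(all(b8$lo <= b0$lo) && all(b8$hi >= b0$hi))
  }
})

test_that("relaxed bounding boxes expand, clip and crop correctly", {
  cs <- click_set(fg = rbind(c(5, 5), c(10, 8)))
  box <- relaxed_bbox(cs, expand = 2, image_shape = c(64, 64))
  expect_equal(box$lo, c(3L, 3L))
  expect_equal(box$hi, c(12L, 10L))
  tight <- relaxed_bbox(cs, expand = 0, image_shape = c(64, 64))
  expect_equal(tight$lo, c(5L, 5L))
  expect_equal(tight$hi, c(10L, 8L))
  corner <- relaxed_bbox(click_set(fg = rbind(c(1, 2))), 5, c(64, 64))
  expect_equal(corner$lo, c(1L, 1L))
  expect_error(relaxed_bbox(click_set(), 2, c(8, 8)), "empty")
})

test_that("crop and paste round-trip preserves untouched pixels", {
  img <- intensity_image(matrix(rnorm(400), 20))
  full_box <- structure(list(lo = c(1L, 1L), hi = c(20L, 20L)),
                        class = "bounding_box")
  expect_equal(crop(img, full_box)$values, img$values)
  single <- structure(list(lo = c(3L, 7L), hi = c(3L, 7L)),
                      class = "bounding_box")
  expect_equal(as.numeric(crop(img, single)$values), img$values[3, 7])

  box <- structure(list(lo = c(5L, 8L), hi = c(11L, 14L)),
                   class = "bounding_box")
  sub <- crop(img, box)
  expect_equal(attr(sub, "offset"), c(5L, 8L))
  modified <- sub$values * 0 + 99
  pasted <- paste_into(img, modified, box)
  expect_equal(dim(pasted$values), dim(img$values))
  expect_true(all(pasted$values[5:11, 8:14] == 99))
  untouched <- pasted$values
  untouched[5:11, 8:14] <- img$values[5:11, 8:14]
  expect_equal(untouched, img$values)

  out_box <- structure(list(lo = c(0L, 1L), hi = c(5L, 5L)),
                       class = "bounding_box")
  expect_error(crop(img, out_box), "outside")
})
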