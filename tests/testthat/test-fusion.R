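test_that("pixel-wise fusion gates and argmaxes single pixels correctly", {
  mk <- function(p) prob_maps(lapply(p, function(v) matrix(v, 1, 1)), 1:3)
  expect_equal(fuse_pixelwise(mk(c(0.3, 0.2, 0.1)))[1, 1], 0L)
  expect_equal(fuse_pixelwise(mk(c(0.9, 0.6, 0.1)))[1, 1], 1L)
  # a confidence of exactly 0.5 counts as positive
  expect_equal(fuse_pixelwise(mk(c(0.5, 0.1, 0.1)))[1, 1], 1L)
  expect_equal(fuse_pixelwise(mk(c(0.49999, 0.1, 0.1)))[1, 1], 0L)
  # argmax ties resolve to the lowest class id
  expect_equal(fuse_pixelwise(mk(c(0.7, 0.7, 0.7)))[1, 1], 1L)
  expect_equal(fuse_pixelwise(mk(c(0.2, 0.7, 0.7)))[1, 1], 2L)
})

test_that("weighted gate can demote a confident class", {
  p1 <- matrix(0.9, 1, 1)
  p2 <- matrix(0.6, 1, 1)
  pm <- prob_maps(list(p1, p2), 1:2)
  # w1 * 0.9 = 0.45 falls below the gate, so class 2 wins
  expect_equal(fuse_pixelwise_weighted(pm, c(0.5, 1))[1, 1], 2L)
  expect_equal(fuse_pixelwise(pm)[1, 1], 1L)
})

test_that("probability map validation rejects malformed inputs", {
  good <- matrix(0.5, 4, 4)
  expect_error(prob_maps(list(good, matrix(0.5, 4, 5)), 1:2), "class 2")
  expect_error(prob_maps(list(good, matrix(1.2, 4, 4)), 1:2), "\\[0, 1\\]")
  expect_error(prob_maps(list(good), 0L), "background")
  expect_error(prob_maps(list(good, good), c(2, 2)), "distinct")
  expect_error(validate_weights(c(1, 1), prob_maps(list(good), 1L)),
               "1 class map")
  expect_error(validate_weights(0, prob_maps(list(good), 1L)), "positive")
  expect_error(validate_weights(1.5, prob_maps(list(good), 1L)), "gate")
})

test_that("all four operators agree with literal brute-force evaluation", {
  w <- c(0.8, 0.9, 0.7)
  for (seed in 1:5) {
    m <- rand_maps(48, 48, seed = seed)
    pm <- prob_maps(m, 1:3)
    expect_identical(fuse_pixelwise(pm), oracle_fuse_pixel(m, 1:3))
    expect_identical(fuse_pixelwise_weighted(pm, w),
                     oracle_fuse_pixel(m, 1:3, w))
    expect_identical(fuse_regionwise(pm), oracle_fuse_region(m, 1:3))
    expect_identical(fuse_regionwise_weighted(pm, w),
                     oracle_fuse_region(m, 1:3, w))
  }
})

test_that("unit weights reproduce the unweighted operators bit-exactly", {
  for (seed in 6:10) {
    pm <- prob_maps(rand_maps(32, 32, seed = seed), 1:3)
    expect_identical(fuse_pixelwise_weighted(pm, c(1, 1, 1)),
                     fuse_pixelwise(pm))
    expect_identical(fuse_regionwise_weighted(pm, c(1, 1, 1)),
                     fuse_regionwise(pm))
  }
})

test_that("foreground regions match hand-enumerable component structure", {
  empty <- matrix(0L, 5, 5)
  expect_length(extract_foreground_regions(empty), 0L)

  two_squares <- matrix(0L, 5, 7)
  two_squares[2:4, 1:3] <- 1L
  two_squares[2:4, 5:7] <- 2L
  regs <- extract_foreground_regions(two_squares)
  expect_length(regs, 2L)
  expect_setequal(lengths(regs), c(9L, 9L))
  expect_length(Reduce(intersect, regs), 0L)
  expect_setequal(unlist(regs), which(two_squares != 0L))

  # diagonal touch: one region under 8-connectivity, two under 4
  diag2 <- matrix(0L, 3, 3)
  diag2[1, 1] <- 1L
  diag2[2, 2] <- 2L
  expect_length(extract_foreground_regions(diag2, connectivity = 8), 1L)
  expect_length(extract_foreground_regions(diag2, connectivity = 4), 2L)
})

test_that("majority relabeling follows counts with lowest-id tie break", {
  lm <- matrix(c(1L, 1L, 2L, 0L), 1, 4)
  expect_equal(region_majority_label(1:3, lm), 1L)
  lm2 <- matrix(c(2L, 2L, 2L), 1, 3)
  expect_equal(region_majority_label(1:3, lm2), 2L)
  lm3 <- matrix(c(1L, 2L), 1, 2)
  expect_equal(region_majority_label(1:2, lm3), 1L)   # tie -> lowest id
  expect_error(region_majority_label(integer(0), lm), "empty")
  expect_error(region_majority_label(4L, lm), "background")
})

test_that("region fusion homogenizes mixed components and preserves support", {
  # one 4-pixel component labeled 1,1,1,2 by the pixel stage
  p1 <- matrix(0, 2, 2)
  p2 <- matrix(0, 2, 2)
  p1[] <- c(0.9, 0.9, 0.9, 0.4)
  p2[] <- c(0.1, 0.1, 0.1, 0.8)
  pm <- prob_maps(list(p1, p2, matrix(0, 2, 2)), 1:3)
  expect_identical(fuse_regionwise(pm), matrix(1L, 2, 2))

  for (seed in 11:16) {
    pm <- prob_maps(rand_maps(40, 40, seed = seed), 1:3)
    px <- fuse_pixelwise(pm)
    rg <- fuse_regionwise(pm)
    expect_identical(px != 0L, rg != 0L)             # support preserved
    for (reg in extract_foreground_regions(rg)) {
      expect_length(unique(rg[reg]), 1L)             # homogeneous regions
    }
    # already-homogeneous maps are a fixed point
    expect_identical(fuse_regionwise(prob_maps(lapply(1:3, function(i)
      (rg == i) * 1), 1:3)), rg)
  }
})

test_that("lowering one weight never adds foreground pixels", {
  for (seed in 17:22) {
    pm <- prob_maps(rand_maps(32, 32, seed = seed), 1:3)
    w <- runif(3, 0.5, 1)
    fg_full <- fuse_pixelwise_weighted(pm, w) != 0L
    for (i in 1:3) {
      w2 <- w
      w2[i] <- w[i] * runif(1, 0.3, 0.9)
      fg_low <- fuse_pixelwise_weighted(pm, w2) != 0L
      expect_true(all(fg_full | !fg_low))
    }
  }
})

test_that("class-relabeled inputs permute outputs when no ties occur", {
  set.seed(23)
  # continuous random confidences: argmax/majority ties have measure zero
  m <- rand_maps(32, 32)
  pm_a <- prob_maps(m, 1:3)
  pm_b <- prob_maps(list(m[[2]], m[[3]], m[[1]]), 1:3)
  px_a <- fuse_pixelwise(pm_a)
  px_b <- fuse_pixelwise(pm_b)
  relabel <- c(0L, 3L, 1L, 2L)[px_a + 1L]  # old 1->3, 2->1, 3->2
  dim(relabel) <- dim(px_a)
  expect_identical(px_b, relabel)
})

test_that("single surviving class reduces to its thresholded mask", {
  set.seed(24)
  strong <- matrix(runif(900), 30, 30)
  weak1 <- matrix(runif(900, 0, 0.45), 30, 30)
  weak2 <- matrix(runif(900, 0, 0.45), 30, 30)
  pm <- prob_maps(list(weak1, strong, weak2), 1:3)
  expected <- (strong >= 0.5) * 2L
  expect_identical(fuse_pixelwise(pm), expected)
  expect_identical(fuse_regionwise(pm), expected)
  expect_identical(fuse_pixelwise_weighted(pm, c(1, 1, 1)), expected)
  expect_identical(fuse_regionwise_weighted(pm, c(1, 1, 1)), expected)
})
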