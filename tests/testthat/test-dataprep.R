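test_that("polygon rasterization fills pixel centers under even-odd rule", {
  # axis-aligned rectangle (1,1)-(4,3): centers x in 1..4, y in 1..3
  rect <- cbind(c(1, 4, 4, 1), c(1, 1, 3, 3))
  m <- rasterize_boundary(rect, 6, 5)
  expect_equal(sum(m), 12L)
  expect_equal(unname(m[2:4, 2:5]), matrix(1L, 3, 4))

  # small triangle enclosing exactly the center (2, 2)
  tri <- cbind(c(1.6, 2.4, 2.0), c(1.7, 1.7, 2.4))
  mt <- rasterize_boundary(tri, 5, 5)
  expect_equal(sum(mt), 1L)
  expect_equal(mt[3, 3], 1L)

  # orientation invariance
  expect_identical(rasterize_boundary(rect[4:1, ], 6, 5), m)
  expect_identical(rasterize_boundary(tri[3:1, ], 5, 5), mt)

  expect_error(rasterize_boundary(rect[1:2, ], 6, 5), "3")
  expect_error(rasterize_boundary(cbind(c(1, 2, 3), c(1, 1, 1)), 6, 5),
               "zero area")
  expect_error(rasterize_boundary(cbind(c(1, 9, 9), c(1, 1, 3)), 6, 5),
               "bounds")
})

test_that("mask merging applies lowest-id precedence and reports overlap", {
  a <- matrix(0L, 3, 3)
  a[1, 1:2] <- 1L
  b <- matrix(0L, 3, 3)
  b[1, 2] <- 1L
  b[3, 3] <- 1L
  merged <- merge_class_masks(list(a, b), c(1L, 2L))
  expect_equal(merged[1, 1], 1L)
  expect_equal(merged[1, 2], 1L)   # overlap pixel: class 1 wins
  expect_equal(merged[3, 3], 2L)
  expect_equal(attr(merged, "overlap_pixels"), 1L)

  zeros <- merge_class_masks(list(matrix(0L, 2, 2), matrix(0L, 2, 2)))
  expect_true(all(zeros == 0L))
  expect_equal(attr(zeros, "overlap_pixels"), 0L)
  expect_error(merge_class_masks(list(a, matrix(0L, 2, 2)), 1:2),
               "class 2")
})

test_that("binarization is a one-vs-all partition of the foreground", {
  lm <- matrix(c(0L, 1L, 2L, 1L), 1, 4)
  expect_equal(as.vector(binarize_mask(lm, 1)), c(0L, 1L, 0L, 1L))
  expect_true(all(binarize_mask(lm, 3) == 0L))
  total <- Reduce(`+`, lapply(1:3, function(cc) binarize_mask(lm, cc)))
  expect_identical(total, (lm != 0L) * 1L)
  expect_error(binarize_mask(lm, 5), "unknown class")
})

test_that("rasterize / merge / binarize round-trip for disjoint polygons", {
  p1 <- cbind(c(2, 8, 8, 2), c(2, 2, 6, 6))
  p2 <- cbind(c(12, 17, 17, 12), c(10, 10, 14, 14))
  m1 <- rasterize_boundary(p1, 20, 16)
  m2 <- rasterize_boundary(p2, 20, 16)
  merged <- merge_class_masks(list(m1, m2), 1:2)
  expect_identical(binarize_mask(merged, 1, 1:2), m1)
  expect_identical(binarize_mask(merged, 2, 1:2), m2)
})

test_that("crop slicing honours count, bounds and the fraction constraint", {
  h <- 60
  w <- 100
  labels <- matrix(0L, h, w)
  labels[25:40, 55:75] <- 1L
  image <- array(runif(h * w * 3), dim = c(h, w, 3))
  crops <- slice_crops(image, labels, n = 10, side = 30,
                       min_fraction = 1 / 3, seed = 5)
  expect_length(crops, 10L)
  total_fg <- sum(labels != 0L)
  for (cr in crops) {
    win <- cr$window
    expect_true(win$x >= 0 && win$y >= 0 &&
                  win$x + win$side <= w && win$y + win$side <= h)
    expect_identical(dim(cr$labels), c(30L, 30L))
    expect_identical(dim(cr$image), c(30L, 30L, 3L))
    # independent recount of the retained labeled fraction
    frac <- sum(cr$labels != 0L) / total_fg
    expect_true(frac >= 1 / 3)
    expect_equal(win$fraction, frac)
    expect_identical(cr$labels,
                     labels[(win$y + 1):(win$y + 30),
                            (win$x + 1):(win$x + 30)])
  }
  # identical seed reproduces identical windows
  again <- slice_crops(image, labels, n = 10, side = 30,
                       min_fraction = 1 / 3, seed = 5)
  expect_identical(lapply(crops, `[[`, "window"),
                   lapply(again, `[[`, "window"))
})

test_that("side-sized images yield the unique full-frame crop", {
  labels <- matrix(0L, 16, 16)
  labels[4:8, 4:8] <- 2L
  image <- matrix(runif(256), 16, 16)
  crops <- slice_crops(image, labels, n = 6, side = 16, seed = 1)
  for (cr in crops) {
    expect_equal(cr$window$x, 0L)
    expect_equal(cr$window$y, 0L)
    expect_equal(cr$window$fraction, 1.0)
  }
})

test_that("crop slicing rejects unsatisfiable or invalid inputs", {
  labels <- matrix(0L, 40, 40)
  image <- matrix(0.5, 40, 40)
  expect_error(slice_crops(image, labels, side = 20),
               "entirely background")
  expect_error(slice_crops(image, matrix(0L, 40, 41), side = 20), "differ")
  labels[1, 1] <- 1L
  expect_error(slice_crops(image, labels, side = 50), "smaller")
  # two far-apart blobs: no 20-window can hold 90% of the labels
  labels2 <- matrix(0L, 40, 40)
  labels2[2:6, 2:6] <- 1L
  labels2[35:39, 35:39] <- 2L
  expect_error(
    slice_crops(image, labels2, side = 20, min_fraction = 0.9),
    "best achievable"
  )
})

test_that("grouped splitting keeps videos whole and balances folds", {
  # 10 equal-sized videos over 5 folds -> exactly 2 videos per fold
  index <- data.frame(
    image_id = sprintf("img%02d", 1:30),
    video_id = rep(sprintf("v%02d", 1:10), each = 3)
  )
  out <- group_split(index, k = 5, seed = 3)
  per_video <- tapply(out$split, out$video_id, function(s) length(unique(s)))
  expect_true(all(per_video == 1L))
  fold_sizes <- table(out$split)
  expect_equal(length(fold_sizes), 5L)
  expect_true(all(fold_sizes == 6L))

  # uneven videos with test hold-out: partition + balance bound
  set.seed(9)
  sizes <- sample(1:8, 12, replace = TRUE)
  index2 <- data.frame(
    image_id = sprintf("i%03d", seq_len(sum(sizes))),
    video_id = rep(sprintf("v%02d", 1:12), times = sizes)
  )
  out2 <- group_split(index2, k = 3, test_videos = c("v01", "v02"), seed = 4)
  expect_true(all(out2$split[out2$video_id %in% c("v01", "v02")] == "test"))
  expect_false(any(out2$split[!out2$video_id %in% c("v01", "v02")] == "test"))
  expect_equal(nrow(out2), sum(sizes))
  per_video2 <- tapply(out2$split, out2$video_id,
                       function(s) length(unique(s)))
  expect_true(all(per_video2 == 1L))
  fold_sizes2 <- table(out2$split[out2$split != "test"])
  expect_true(max(fold_sizes2) - min(fold_sizes2) <= max(sizes))

  expect_error(group_split(index, k = 11), "folds")
  expect_error(group_split(index, k = 5, test_videos = "nope"), "unknown")
})

test_that("a 38-video index with 4 test videos splits 34 videos over 5 folds", {
  set.seed(11)
  sizes <- sample(5:25, 38, replace = TRUE)
  index <- data.frame(
    image_id = sprintf("i%04d", seq_len(sum(sizes))),
    video_id = rep(sprintf("v%02d", 1:38), times = sizes)
  )
  test_v <- c("v05", "v17", "v23", "v31")
  out <- group_split(index, k = 5, test_videos = test_v, seed = 2)
  expect_true(all(tapply(out$split, out$video_id,
                         function(s) length(unique(s))) == 1L))
  folded <- unique(out$video_id[out$split != "test"])
  expect_length(folded, 34L)
  expect_length(unique(out$split[out$split != "test"]), 5L)
})
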