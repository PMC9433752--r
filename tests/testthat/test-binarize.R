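test_that("ceiling partition reproduces printed block counts and the closed form", {
  expect_equal(partition_blocks(2788, 2238, 50)$n_blocks, 2520L)
  expect_equal(partition_blocks(2788, 2238, 500)$n_blocks, 30L)

  g <- partition_blocks(100, 100, 100)
  expect_equal(g$n_blocks, 1L)
  expect_equal(g$boxes[[1]], c(0, 100, 0, 100))

  set.seed(21)
  for (i in 1:200) {
    w <- sample(1:400, 1); h <- sample(1:400, 1); b <- sample(1:120, 1)
    g <- partition_blocks(w, h, b)
    expect_equal(g$n_blocks, ceiling(w / b) * ceiling(h / b))
    expect_equal(length(g$boxes), g$n_blocks)
    # blocks tile the frame exactly and disjointly
    areas <- vapply(g$boxes, function(bx) (bx[2] - bx[1]) * (bx[4] - bx[3]), numeric(1))
    expect_equal(sum(areas), w * h)
  }
  expect_error(partition_blocks(10, 10, 0), "must be >= 1")
})

test_that("block SD is the population standard deviation", {
  img <- matrix(7, 20, 20)
  expect_equal(block_sd(img, c(0, 20, 0, 20)), 0)

  half <- matrix(rep(c(0, 255), each = 200), 20, 20)
  expect_equal(block_sd(half, c(0, 20, 0, 20)), 127.5)

  set.seed(4)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  v <- as.numeric(img)
  oracle <- sqrt(sum((v - mean(v))^2) / length(v))  # two-pass population SD
  expect_equal(block_sd(img, c(0, 20, 0, 20)), oracle, tolerance = 1e-9)

  expect_error(block_sd(img, c(5, 5, 0, 10)), "empty block")
  expect_error(block_sd(img, c(0, 30, 0, 10)), "outside image")
})

test_that("Otsu threshold maximizes between-class variance (exhaustive oracle)", {
  two_spikes <- rep(0, 256); two_spikes[51] <- 40; two_spikes[201] <- 60
  t <- otsu_threshold(two_spikes)
  expect_true(t >= 50 && t < 200)

  single <- rep(0, 256); single[129] <- 10
  expect_no_error(otsu_threshold(single))

  expect_error(otsu_threshold(rep(0, 256)), "empty")

  set.seed(11)
  for (i in 1:250) {
    h <- rpois(256, lambda = runif(1, 0.5, 8))
    if (sum(h) == 0) h[sample(256, 1)] <- 1
    expect_identical(otsu_threshold(h), as.integer(otsu_exhaustive(h)))
  }
})

test_that("simple thresholding follows its definition and is stable on two-level input", {
  img <- matrix(rep(c(40, 220), 50), 10, 10)
  m <- binarize_simple(img, 175)
  expect_true(all(m[img == 40] == 255))
  expect_true(all(m[img == 220] == 0))

  expect_true(all(binarize_simple(img, 0) == 0))
  expect_error(binarize_simple(img, 256), "\\[0, 255\\]")

  # dark-is-foreground polarity swaps the two levels of a {0,255} mask, so
  # a second application returns the original: the map is period-2
  expect_identical(binarize_simple(binarize_simple(m, 175), 175), m)
})

test_that("adaptive thresholding matches a sliding-window oracle", {
  const <- matrix(128, 12, 12)
  expect_true(all(binarize_adaptive(const, "mean", 7, c = 1) == 0))
  expect_error(binarize_adaptive(const, "mean", 6), "odd")

  sc <- generate_scene(scene_params(width = 128, height = 96), seed = 2)
  g <- to_grayscale(sc$image)
  m <- binarize_adaptive(g, "gaussian", 7)
  expect_equal(dim(m), dim(g))

  set.seed(9)
  img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  w <- 5L; r <- 2L
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    ri <- pmin(pmax((i - r):(i + r), 1), 16)
    ci <- pmin(pmax((j - r):(j + r), 1), 16)
    oracle[i, j] <- if (img[i, j] < mean(img[ri, ci])) 255 else 0
  }
  expect_identical(binarize_adaptive(img, "mean", w), oracle)
})

test_that("block-threshold binarization gates low-SD blocks and recovers the strand", {
  const <- matrix(100, 60, 60)
  expect_true(all(binarize_block_threshold(const, 20, 1) == 0))

  sc <- generate_scene(scene_params(), seed = 1)
  g <- to_grayscale(sc$image)
  m <- binarize_block_threshold(g, 125, 6)
  comps <- extract_components(m, 8L)
  truth_px <- which(sc$mask != 0)
  cover <- length(intersect(comps[[1]]$pixels, truth_px)) / length(truth_px)
  expect_gte(cover, 0.95)

  # the foreground is confined to blocks that passed the SD gate
  grid <- partition_blocks(ncol(g), nrow(g), 125)
  for (box in grid$boxes) {
    sub <- m[(box[3] + 1):box[4], (box[1] + 1):box[2]]
    if (block_sd(g, box) < 6) expect_true(all(sub == 0))
  }

  # with the gate disabled every block is Otsu-binarized: on a noisy image
  # no block is all-background
  noisy <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  m0 <- binarize_block_threshold(noisy, 25, 0)
  grid <- partition_blocks(100, 100, 25)
  for (box in grid$boxes) {
    sub <- m0[(box[3] + 1):box[4], (box[1] + 1):box[2]]
    expect_true(any(sub == 255))
  }
})
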