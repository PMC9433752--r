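test_that("pooled block-SD sample has the closed-form size", {
  flat <- matrix(50, 2238, 2788)
  sds <- collect_block_sds(list(flat, flat), 500)
  expect_length(sds, 60L)  # 2 frames x 30 blocks
  expect_true(all(sds == 0))

  one <- matrix(c(0, 255, 0, 255), 2, 2)
  sds <- collect_block_sds(list(one), 10)
  expect_length(sds, 1L)
  expect_equal(sds, block_sd(one, c(0, 2, 0, 2)))

  expect_error(collect_block_sds(list(), 10), "nonempty")
})

test_that("density estimate is normalized and finds the right mode", {
  set.seed(3)
  s <- rnorm(10000, 10, 1)
  d <- estimate_density(s)
  expect_s3_class(d, "sd_density")
  expect_length(d$x, 512L)
  mode <- d$x[which.max(d$y)]
  expect_lt(abs(mode - 10), 0.2)
  integral <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_gte(integral, 0.99)
  expect_lte(integral, 1.01)

  # two-point sample: two symmetric kernel bumps of equal height
  d2 <- estimate_density(c(3, 7))
  y3 <- d2$y[which.min(abs(d2$x - 3))]
  y7 <- d2$y[which.min(abs(d2$x - 7))]
  expect_equal(y3, y7, tolerance = 0.02)

  expect_error(estimate_density(rep(2, 10)), "degenerate")
  expect_error(estimate_density(5), "at least 2")
})

test_that("first-trough detection floors the trough abscissa and rejects monotone curves", {
  # handcrafted curve: peak at 3, trough exactly at 7.0, second rise
  x <- seq(0, 14, by = 0.25)
  y <- ifelse(x <= 3, 0.1 + 0.3 * x / 3,
              ifelse(x <= 7, 0.4 - 0.35 * (x - 3) / 4,
                     0.05 + 0.2 * (x - 7) / 7))
  expect_identical(first_trough_threshold(list(x = x, y = y)), 7L)

  decreasing <- list(x = seq(0, 10, length.out = 100), y = exp(-seq(0, 10, length.out = 100)))
  expect_error(first_trough_threshold(decreasing), "no trough")

  # a noise wiggle below the prominence gate is skipped in favor of the
  # genuine trough
  y2 <- y
  dip <- which(x == 5)
  y2[dip] <- y2[dip] - 1e-4
  expect_identical(first_trough_threshold(list(x = x, y = y2)), 7L)
})

test_that("calibration recovers the floor of a known density trough (n = 50,000)", {
  f <- function(z) 0.8 * dnorm(z, 3, 1) + 0.2 * dnorm(z, 14, 4)
  t_star <- optimize(f, c(5, 12))$minimum  # analytic trough of the mixture
  expect_equal(floor(t_star), 6)
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    comp <- runif(50000) < 0.8
    s <- abs(ifelse(comp, rnorm(50000, 3, 1), rnorm(50000, 14, 4)))
    thr <- first_trough_threshold(estimate_density(s))
    expect_identical(thr, as.integer(floor(t_star)))
  }
})

test_that("corpus calibration separates background from strand blocks and is deterministic", {
  grays <- suite_grays()
  scenes <- scene_suite()
  thr <- calibrate_sd_threshold(grays, 125)
  expect_identical(as.integer(thr), as.integer(calibrate_sd_threshold(grays, 125)))

  # "pure background" excludes residue-speck blocks: residues are expected
  # to raise background-block SD above the gate and are removed later by
  # contour screening, which is why the *first* trough is the right gate
  bg_sds <- c(); strand_sds <- c()
  for (i in seq_along(scenes)) {
    g <- grays[[i]]
    rmask <- matrix(FALSE, nrow(g), ncol(g))
    rmask[scenes[[i]]$residue_px] <- TRUE
    grid <- partition_blocks(ncol(g), nrow(g), 125)
    for (box in grid$boxes) {
      rows <- (box[3] + 1):box[4]; cols <- (box[1] + 1):box[2]
      s <- block_sd(g, box)
      if (any(scenes[[i]]$mask[rows, cols] != 0)) strand_sds <- c(strand_sds, s)
      else if (!any(rmask[rows, cols])) bg_sds <- c(bg_sds, s)
    }
  }
  expect_gte(mean(bg_sds < thr), 0.99)
  expect_gt(median(strand_sds), thr)

  expect_error(calibrate_sd_threshold(list(matrix(5, 50, 50)), 25), "degenerate")
})

test_that("calibrated threshold is invariant to duplicating the corpus", {
  grays <- suite_grays()[1:30]
  t1 <- calibrate_sd_threshold(grays, 125)
  t2 <- calibrate_sd_threshold(c(grays, grays), 125)
  expect_identical(as.integer(t1), as.integer(t2))
})
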