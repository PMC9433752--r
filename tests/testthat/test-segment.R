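test_that("component extraction matches a flood-fill oracle and respects connectivity", {
  expect_length(extract_components(matrix(0, 10, 10)), 0L)

  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 255
  m[8:10, 7:9] <- 255
  comps <- extract_components(m, 8L)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, `[[`, numeric(1), "area"), c(9, 9))

  # diagonal contact joins under 8-connectivity, separates under 4
  d <- matrix(0, 4, 4)
  d[1, 1] <- 255; d[2, 2] <- 255
  expect_length(extract_components(d, 8L), 1L)
  expect_length(extract_components(d, 4L), 2L)

  set.seed(14)
  for (i in 1:10) {
    rnd <- matrix(ifelse(runif(48 * 64) < 0.35, 255, 0), 48, 64)
    for (conn in c(4L, 8L)) {
      mine <- extract_components(rnd, conn)
      oracle <- flood_fill_components(rnd, conn)
      expect_equal(length(mine), length(oracle$areas))
      expect_equal(sort(vapply(mine, `[[`, numeric(1), "area"), decreasing = TRUE),
                   oracle$areas)
    }
  }
})

test_that("contour screening keeps the largest component and flags residues", {
  m <- matrix(0, 40, 60)
  m[5:29, 5:24] <- 255          # area 500
  m[35:36, 50:51] <- 255        # area 4
  m[2, 55:56] <- 255            # area 2
  scr <- screen_contours(extract_components(m, 8L))
  expect_equal(scr$main$area, 500)
  expect_length(scr$residues, 2L)
  expect_length(scr$retained, 0L)

  single <- extract_components(matrix(c(0, 255, 255, 0), 2, 2), 8L)
  scr1 <- screen_contours(single)
  expect_length(scr1$residues, 0L)

  # area tie: the component with the smaller (row, col) bbox origin wins
  tie <- matrix(0, 20, 20)
  tie[12:14, 12:14] <- 255
  tie[2:4, 2:4] <- 255
  scr2 <- screen_contours(extract_components(tie, 8L))
  expect_equal(scr2$main$bbox, c(1L, 4L, 1L, 4L))

  expect_error(screen_contours(list()), "no foreground")
})

test_that("square ROI expands about the bbox center with edge clamping", {
  expect_equal(square_roi(c(10, 60, 10, 40), 1000, 1000), c(10L, 60L, 0L, 50L))

  # needed upward growth at the top edge: square shifts down to row 0
  roi <- square_roi(c(100, 160, 0, 20), 1000, 1000)
  expect_equal(roi[3], 0L)
  expect_equal(roi[4], 60L)

  expect_error(square_roi(c(5, 5, 0, 10), 100, 100), "degenerate")

  set.seed(31)
  for (i in 1:1000) {
    w <- sample(50:300, 1); h <- sample(50:300, 1)
    x0 <- sample(0:(w - 2), 1); x1 <- sample((x0 + 1):w, 1)
    y0 <- sample(0:(h - 2), 1); y1 <- sample((y0 + 1):h, 1)
    margin <- sample(0:3, 1)
    roi <- square_roi(c(x0, x1, y0, y1), w, h, margin)
    expect_equal(roi[2] - roi[1], roi[4] - roi[3])
    # the square contains the original bbox
    expect_true(roi[1] <= x0 && roi[2] >= x1 && roi[3] <= y0 && roi[4] >= y1)
  }
})

test_that("cropping pads out-of-frame regions with white and is always square", {
  img <- random_color_image(50, 70, seed = 6)
  sub <- crop_roi(img, c(10L, 30L, 5L, 25L))
  expect_identical(sub, img[6:25, 11:30, , drop = FALSE] + 0)

  over <- crop_roi(img, c(60L, 80L, 0L, 20L))
  expect_true(all(over[, 11:20, ] == 255))  # columns past the right edge
  expect_true(all(over[, 1:10, ] == img[1:20, 61:70, ]))

  set.seed(8)
  for (i in 1:200) {
    side <- sample(5:40, 1)
    x0 <- sample(-20:80, 1); y0 <- sample(-20:60, 1)
    out <- crop_roi(img, c(x0, x0 + side, y0, y0 + side))
    expect_equal(dim(out), c(side, side, 3L))
  }
})

test_that("completeness requires one covering, unbroken component", {
  truth <- matrix(0, 30, 30)
  truth[10:20, 5:25] <- 255
  expect_true(is_complete(truth, truth))

  broken <- truth
  broken[, 14:16] <- 0  # strand split into two large pieces
  expect_false(is_complete(broken, truth))

  eroded <- truth
  idx <- which(truth != 0)
  eroded[idx[seq_len(ceiling(0.1 * length(idx)))]] <- 0  # only ~90% coverage
  expect_false(is_complete(eroded, truth, cover = 0.95))

  expect_error(is_complete(truth, matrix(0, 10, 10)), "dimensions differ")
})
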