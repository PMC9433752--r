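# Block-threshold binarization: ceiling partition of the frame into b x b
# neighborhood blocks, a per-block standard-deviation gate that zeroes
# background blocks, and per-block Otsu thresholding inside the remaining
# ones. Shreds are dark on a bright background, so the darker Otsu class is
# foreground (255).

#' Ceiling partition of a frame into neighborhood blocks
#'
#' Divides a width x height frame into b x b blocks; partial blocks at the
#' right and bottom edges are retained at their actual size, so the block
#' count is ceiling(width/b) * ceiling(height/b). A 2788 x 2238 frame gives
#' 2,520 blocks at b = 50 and 30 blocks at b = 500.
#'
#' @param width,height Frame dimensions in pixels.
#' @param b Block side length in pixels.
#' @return An object of class `block_grid`: list with `n_cols`, `n_rows`,
#'   `n_blocks` and `boxes`, a list of 0-based half-open pixel boxes
#'   `c(x0, x1, y0, y1)`.
#' @export
partition_blocks <- function(width, height, b) {
  if (length(b) != 1L || is.na(b) || b < 1) stop_sv("block size b must be >= 1")
  if (width < 1 || height < 1) stop_sv("frame dimensions must be >= 1")
  b <- as.integer(b)
  n_cols <- as.integer(ceiling(width / b))
  n_rows <- as.integer(ceiling(height / b))
  x0 <- (seq_len(n_cols) - 1L) * b
  y0 <- (seq_len(n_rows) - 1L) * b
  boxes <- vector("list", n_cols * n_rows)
  i <- 0L
  for (cx in seq_len(n_cols)) {
    for (cy in seq_len(n_rows)) {
      i <- i + 1L
      boxes[[i]] <- c(x0[cx], min(x0[cx] + b, width), y0[cy], min(y0[cy] + b, height))
    }
  }
  structure(list(n_cols = n_cols, n_rows = n_rows,
                 n_blocks = n_cols * n_rows, boxes = boxes,
                 width = as.integer(width), height = as.integer(height), b = b),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("block_grid: %d x %d frame, b = %d -> %d x %d = %d blocks\n",
              x$width, x$height, x$b, x$n_cols, x$n_rows, x$n_blocks))
  invisible(x)
}

# Extract a block's pixels as a vector; box is 0-based half-open.
block_pixels <- function(img, box) {
  if (box[2] <= box[1] || box[4] <= box[3]) stop_sv("empty block")
  if (box[1] < 0 || box[3] < 0 || box[2] > ncol(img) || box[4] > nrow(img))
    stop_sv("block outside image bounds")
  img[(box[3] + 1L):box[4], (box[1] + 1L):box[2]]
}

#' Population standard deviation of a block's intensities
#'
#' Uses the population (divide-by-n) form, so a constant block has SD
#' exactly 0.
#'
#' @param img Gray matrix.
#' @param box 0-based half-open pixel box `c(x0, x1, y0, y1)`.
#' @return Nonnegative scalar in intensity units.
#' @export
block_sd <- function(img, box) {
  v <- as.numeric(block_pixels(img, box))
  sqrt(mean(v * v) - mean(v)^2)
}

#' Otsu's threshold from a 256-bin intensity histogram
#'
#' Finds the integer threshold t in 0..255 splitting intensities into the
#' classes \code{[0, t]} and \code{[t+1, 255]} that maximizes the
#' between-class variance; ties are broken toward the smaller threshold.
#'
#' @param hist Numeric vector of 256 nonnegative counts for intensities
#'   0..255.
#' @return Integer threshold in 0..255.
#' @export
otsu_threshold <- function(hist) {
  if (length(hist) != 256L || any(hist < 0)) stop_sv("hist must be 256 nonnegative counts")
  total <- sum(hist)
  if (total == 0) stop_sv("histogram is empty")
  p <- hist / total
  levels <- 0:255
  w0 <- cumsum(p)                    # weight of class [0, t]
  mu0 <- cumsum(p * levels)          # unnormalized class-0 mean
  mu_t <- mu0[256L]
  w1 <- 1 - w0
  # between-class variance; 0 where a class is empty
  num <- (mu_t * w0 - mu0)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, 0)
  as.integer(which.max(sigma_b) - 1L)  # which.max takes the first (smallest) argmax
}

hist256 <- function(v) tabulate(as.integer(v) + 1L, nbins = 256L)

#' Block-threshold binarization
#'
#' The core preprocessing step: partition the gray image into b x b blocks;
#' any block whose pixel SD falls below `sd_thresh` is zeroed as background;
#' the remaining blocks are binarized with per-block Otsu thresholds, with
#' the darker class mapped to foreground (255).
#'
#' @param img Gray matrix with intensities in 0..255.
#' @param b Block side length in pixels (125 works well at the native frame
#'   scale used here).
#' @param sd_thresh Nonnegative SD gate; see [calibrate_sd_threshold()] for
#'   the data-driven choice. `sd_thresh = 0` disables the gate.
#' @return Binary mask matrix (0 background / 255 foreground) of the same
#'   dimensions as `img`.
#' @seealso [binarize_simple()], [binarize_adaptive()], [binarize_otsu()]
#' @export
binarize_block_threshold <- function(img, b, sd_thresh) {
  assert_gray_image(img)
  if (sd_thresh < 0) stop_sv("sd_thresh must be >= 0")
  grid <- partition_blocks(ncol(img), nrow(img), b)
  mask <- matrix(0, nrow(img), ncol(img))
  for (box in grid$boxes) {
    px <- block_pixels(img, box)
    v <- as.numeric(px)
    sdv <- sqrt(mean(v * v) - mean(v)^2)
    if (sdv < sd_thresh) next
    t <- otsu_threshold(hist256(v))
    mask[(box[3] + 1L):box[4], (box[1] + 1L):box[2]] <- ifelse(px <= t, 255, 0)
  }
  mask
}

#' Fixed-threshold binarization
#'
#' Pixels strictly darker than `t` become foreground (255).
#'
#' @param img Gray matrix.
#' @param t Integer threshold in 0..255.
#' @return Binary mask matrix.
#' @export
binarize_simple <- function(img, t) {
  assert_gray_image(img)
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255) stop_sv("threshold t must be in [0, 255]")
  ifelse(img < t, 255, 0)
}

#' Global Otsu binarization
#'
#' Whole-image Otsu threshold; the darker class is foreground.
#'
#' @param img Gray matrix.
#' @return Binary mask matrix.
#' @export
binarize_otsu <- function(img) {
  assert_gray_image(img)
  t <- otsu_threshold(hist256(img))
  ifelse(img <= t, 255, 0)
}

# Replicate-pad a matrix by r rows/cols on each side.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# w x w box-filter local mean via integral image, replicate padding.
local_mean <- function(img, w) {
  r <- (w - 1L) %/% 2L
  p <- pad_replicate(img, r)
  s <- rbind(0, apply(p, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  h <- nrow(img); wd <- ncol(img)
  # sum over window [i, i+w) x [j, j+w) of padded image
  (s[(seq_len(h) + w), (seq_len(wd) + w)] - s[(seq_len(h) + w), seq_len(wd)] -
     s[seq_len(h), (seq_len(wd) + w)] + s[seq_len(h), seq_len(wd)]) / (w * w)
}

# Separable Gaussian-weighted local mean; sigma follows the common
# 0.3*((w-1)/2 - 1) + 0.8 convention for a w-tap kernel.
local_gaussian <- function(img, w) {
  r <- (w - 1L) %/% 2L
  sigma <- 0.3 * ((w - 1) * 0.5 - 1) + 0.8
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(img, r)
  h <- nrow(img); wd <- ncol(img)
  tmp <- matrix(0, h, ncol(p))
  for (o in seq_len(w)) tmp <- tmp + k[o] * p[(o - 1L) + seq_len(h), , drop = FALSE]
  out <- matrix(0, h, wd)
  for (o in seq_len(w)) out <- out + k[o] * tmp[, (o - 1L) + seq_len(wd), drop = FALSE]
  out
}

#' Adaptive (local-mean) binarization
#'
#' Each pixel is compared against the mean or Gaussian-weighted mean of its
#' w x w neighborhood minus an offset `c`; strictly darker pixels become
#' foreground.
#'
#' @param img Gray matrix.
#' @param method `"mean"` or `"gaussian"`.
#' @param w Odd window size >= 3 (7 is a good default for fine strands).
#' @param c Offset subtracted from the local mean (default 0).
#' @return Binary mask matrix.
#' @export
binarize_adaptive <- function(img, method = c("mean", "gaussian"), w = 7L, c = 0) {
  assert_gray_image(img)
  method <- match.arg(method)
  if (w < 3L || w %% 2L == 0L) stop_sv("window size w must be odd and >= 3")
  loc <- if (method == "mean") local_mean(img, as.integer(w)) else local_gaussian(img, as.integer(w))
  ifelse(img < loc - c, 255, 0)
}
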