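# Calibration of the SD gate: pool the per-block standard deviations of a
# corpus, estimate their density, and take the floor of the first trough
# after the first peak. The trough separates the tall, narrow cluster of
# background blocks from the diffuse cluster of blocks containing shred.

#' Pool per-block standard deviations across a corpus
#'
#' @param corpus Nonempty list of gray matrices.
#' @param b Block side length in pixels.
#' @return Numeric vector of per-block population SDs; its length is the
#'   summed block count over the corpus.
#' @export
collect_block_sds <- function(corpus, b) {
  if (!is.list(corpus) || length(corpus) == 0L) stop_sv("corpus must be a nonempty list of gray images")
  unlist(lapply(corpus, function(img) {
    assert_gray_image(img)
    grid <- partition_blocks(ncol(img), nrow(img), b)
    vapply(grid$boxes, function(box) block_sd(img, box), numeric(1))
  }), use.names = FALSE)
}

#' Kernel-density estimate of a pooled SD sample
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' 512-point grid spanning `[0, max(s)]`.
#'
#' @param s Numeric vector of block SDs (length >= 2, nonzero variance).
#' @return Object of class `sd_density`: list with `x`, `y`, `bw`, `n`.
#' @export
estimate_density <- function(s) {
  if (length(s) < 2L) stop_sv("need at least 2 SD values")
  if (stats::sd(s) == 0) stop_sv("degenerate sample: all block SDs identical")
  d <- stats::density(s, bw = "nrd0", kernel = "gaussian", n = 512L,
                      from = 0, to = max(s))
  structure(list(x = d$x, y = d$y, bw = d$bw, n = length(s)), class = "sd_density")
}

#' @export
print.sd_density <- function(x, ...) {
  cat(sprintf("sd_density: n = %d, bandwidth = %.4g, grid [0, %.4g] (512 points)\n",
              x$n, x$bw, max(x$x)))
  invisible(x)
}

#' First-trough threshold of a density curve
#'
#' Scans past the first local maximum of the curve for the first point where
#' the density stops decreasing (the left edge of any flat stretch counts),
#' and accepts it as the trough only if its prominence — the height above it
#' of the tallest point reached before the curve next drops below the trough
#' level — is at least `prominence` times the first peak's height. This
#' rejects noise wiggles on the downslope, whose escape barrier is tiny even
#' when the curve rises again much later. Returns the floor of the accepted
#' abscissa.
#'
#' @param curve `sd_density` object (or list with `x`, `y`).
#' @param prominence Required subsequent rise, as a fraction of the first
#'   peak height (default 0.01).
#' @return Integer threshold: floor of the trough abscissa.
#' @export
first_trough_threshold <- function(curve, prominence = 0.01) {
  x <- curve$x; y <- curve$y
  n <- length(y)
  dy <- diff(y)
  # first index where the curve turns down AND the height is substantial:
  # numerical noise near zero density must not count as the first peak
  turns <- which(dy < 0)
  turns <- turns[y[turns] >= 0.01 * max(y)]
  peak <- turns[1]
  if (is.na(peak) || peak >= n - 1L) stop_sv("no trough: density curve has no interior first peak")
  i <- peak + 1L
  while (i <= n) {
    # advance to where the strict decrease stops
    while (i < n && y[i + 1L] < y[i]) i <- i + 1L
    if (i >= n) break
    # escape barrier: tallest point after i before the curve first falls
    # below the candidate trough level
    later <- y[(i + 1L):n]
    below <- which(later < y[i])
    j_end <- if (length(below)) below[1L] else length(later)
    barrier <- if (j_end >= 1L) max(later[seq_len(j_end)]) - y[i] else 0
    if (barrier >= prominence * y[peak]) return(as.integer(floor(x[i])))
    # climb past the non-qualifying wiggle and keep scanning
    while (i < n && y[i + 1L] >= y[i]) i <- i + 1L
    i <- i + 1L
  }
  stop_sv("no trough: density curve has no qualifying local minimum after its first peak")
}

#' Calibrate the SD gate from a corpus
#'
#' Composition of [collect_block_sds()], [estimate_density()] and
#' [first_trough_threshold()]. Deterministic given the corpus.
#'
#' @param corpus Nonempty list of gray matrices.
#' @param b Block side length in pixels.
#' @param prominence Passed to [first_trough_threshold()].
#' @param verbose Print the sample size, bandwidth and peak/trough abscissas.
#' @return Integer SD threshold, with attributes `n_blocks`, `bandwidth` and
#'   `peak` (abscissa of the first density peak).
#' @export
calibrate_sd_threshold <- function(corpus, b, prominence = 0.01, verbose = FALSE) {
  s <- collect_block_sds(corpus, b)
  d <- estimate_density(s)
  thr <- first_trough_threshold(d, prominence)
  peak_i <- which(diff(d$y) < 0)[1]
  if (verbose)
    message(sprintf("calibrated SD gate: %d blocks, bw %.4g, first peak at %.3g, threshold %d",
                    d$n, d$bw, d$x[peak_i], thr))
  structure(thr, n_blocks = d$n, bandwidth = d$bw, peak = d$x[peak_i])
}
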