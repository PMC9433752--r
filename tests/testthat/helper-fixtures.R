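# Shared fixtures, memoised so expensive corpora are generated once per run.

.fixtures <- new.env(parent = emptyenv())

# Fixed-seed 100-scene suite at default (quarter-scale) frame size, used by
# the calibration, generator-contract and binarizer-benchmark tests.
scene_suite <- function(n = 100L, seed = 7L) {
  key <- sprintf("suite_%d_%d", n, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_corpus(n, seed = seed)
  .fixtures[[key]]
}

suite_grays <- function(n = 100L, seed = 7L) {
  key <- sprintf("grays_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- lapply(scene_suite(n, seed), function(s) to_grayscale(s$image))
    # downstream suite users only need masks/residues/grays; dropping the
    # color frames keeps the cached fixtures small
    skey <- sprintf("suite_%d_%d", n, seed)
    .fixtures[[skey]] <- lapply(.fixtures[[skey]], function(s) { s$image <- NULL; s })
  }
  .fixtures[[key]]
}

# Independent scalar flood-fill labeling oracle (stack-based), for checking
# the vectorised component extraction.
flood_fill_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0
  lab <- matrix(0L, h, w)
  if (connectivity == 4L) {
    nb <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  }
  comps <- list()
  k <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    stack <- list(c(i, j))
    lab[i, j] <- k
    area <- 0L
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (q in seq_len(nrow(nb))) {
        ni <- p[1] + nb[q, 1]; nj <- p[2] + nb[q, 2]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            fg[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- k
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
    comps[[k]] <- area
  }
  list(labels = lab, areas = sort(unlist(comps), decreasing = TRUE))
}

# Exhaustive Otsu oracle: evaluate the between-class variance for every
# candidate threshold 0..255 and return the first argmax.
otsu_exhaustive <- function(hist) {
  total <- sum(hist)
  levels <- 0:255
  best <- -Inf; best_t <- 0L
  for (t in 0:255) {
    w0 <- sum(hist[1:(t + 1)]) / total
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) { s <- 0 } else {
      mu0 <- sum(hist[1:(t + 1)] * levels[1:(t + 1)]) / (w0 * total)
      mu1 <- sum(hist[(t + 2):256] * levels[(t + 2):256]) / (w1 * total)
      s <- w0 * w1 * (mu0 - mu1)^2
    }
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# Random small color image with integer intensities.
random_color_image <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

random_prob_batch <- function(m, k) {
  z <- matrix(rnorm(m * k), m, k)
  e <- exp(z)
  e / rowSums(e)
}
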