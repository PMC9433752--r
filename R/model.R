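# The multi-scale residual network family. A network is four stages of
# bottleneck blocks (1x1 reduce, 3x3, 1x1 expand, each followed by batch
# norm) on top of a 7x7/stride-2 stem with 3x3/stride-2 max pooling. The
# first block of stages 2-4 downsamples with a projection shortcut (Conv
# block); the rest are identity blocks. The head global-average-pools the
# stage-3 (1024-channel) and stage-4 (2048-channel) outputs, concatenates
# them to a 3072-long feature and applies a single fully connected layer;
# without multi-scale fusion only the stage-4 pool feeds the classifier.

#' Network configuration
#'
#' The family is indexed by per-stage bottleneck block counts
#' `(b1, b2, b3, b4)`: the A configuration fixes `(b1, b2, b4) = (3, 4, 3)`
#' and the B configuration `(3, 3, 3)`, with the stage-3 count free. The
#' classic 50- and 101-layer networks are `(3, 4, 6, 3)` and `(3, 4, 23, 3)`.
#'
#' @param blocks Integer vector of 4 positive per-stage block counts.
#' @param multiscale Fuse pooled stage-3 and stage-4 features (default TRUE).
#' @param n_classes Number of output classes (default 4).
#' @param input_side Input image side in pixels (default 224; must be >= 32
#'   so stage 4 retains spatial extent).
#' @param width_mult Channel width multiplier (default 1). Values below 1
#'   give proportionally narrower networks for small-scale experiments.
#' @return Object of class `model_config`.
#' @export
model_config <- function(blocks = c(3L, 4L, 6L, 3L), multiscale = TRUE,
                         n_classes = 4L, input_side = 224L, width_mult = 1) {
  blocks <- as.integer(blocks)
  if (length(blocks) != 4L || any(is.na(blocks)) || any(blocks < 1L))
    stop_sv("blocks must be 4 positive integers")
  if (n_classes < 2L) stop_sv("need at least 2 classes")
  if (input_side < 32L) stop_sv("input_side must be >= 32")
  if (width_mult <= 0) stop_sv("width_mult must be positive")
  structure(list(blocks = blocks, multiscale = isTRUE(multiscale),
                 n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side),
                 width_mult = width_mult),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model_config: blocks (%s), depth index %d, %s, %d classes, input %dx%d, width x%g\n",
              paste(x$blocks, collapse = ","), depth_index(x$blocks),
              if (x$multiscale) "multi-scale head" else "single-scale head",
              x$n_classes, x$input_side, x$input_side, x$width_mult))
  invisible(x)
}

#' Depth index of a block configuration
#'
#' Counts weighted layers: three per bottleneck block, plus the stem
#' convolution and the final fully connected layer, i.e.
#' `3 * sum(blocks) + 2`. `(3, 4, 6, 3)` gives 50 and `(3, 4, 23, 3)`
#' gives 101; the B configuration `(3, 3, 16, 3)` gives 77.
#'
#' @param blocks Integer vector of 4 positive block counts, or a
#'   [model_config()].
#' @return Integer depth index.
#' @export
depth_index <- function(blocks) {
  if (inherits(blocks, "model_config")) blocks <- blocks$blocks
  if (length(blocks) != 4L || any(blocks < 1L))
    stop_sv("blocks must be 4 positive integers")
  as.integer(3L * sum(blocks) + 2L)
}

make_bottleneck <- function(c_in, c_mid, c_out, stride, zero_init_residual) {
  blk <- list(conv1 = kaiming_weight(1L, c_in, c_mid), bn1 = bn_init(c_mid),
              conv2 = kaiming_weight(3L, c_mid, c_mid), bn2 = bn_init(c_mid),
              conv3 = kaiming_weight(1L, c_mid, c_out), bn3 = bn_init(c_out),
              stride = stride)
  if (zero_init_residual) blk$bn3$gamma[] <- 0
  if (stride != 1L || c_in != c_out) {
    blk$proj <- kaiming_weight(1L, c_in, c_out)
    blk$bn_proj <- bn_init(c_out)
  }
  blk
}

#' Build an executable network from a configuration
#'
#' Parameters are initialized Kaiming-style for convolutions (seedable via
#' `seed`), unit scale/zero shift for batch norm — except the last batch
#' norm of each residual block, whose scale starts at zero so every block
#' begins as an identity mapping — and small Gaussian weights with zero
#' bias for the classifier layer.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for the parameter initialization.
#' @param zero_init_residual Zero the last batch-norm scale of each block
#'   (default TRUE).
#' @return Object of class `shred_network`.
#' @export
build_network <- function(cfg, seed = NULL, zero_init_residual = TRUE) {
  if (!inherits(cfg, "model_config")) stop_sv("cfg must be a model_config")
  if (!is.null(seed)) set.seed(seed)
  ch <- function(c) max(1L, as.integer(round(c * cfg$width_mult)))
  stem_ch <- ch(64)
  outs <- c(ch(256), ch(512), ch(1024), ch(2048))
  mids <- c(ch(64), ch(128), ch(256), ch(512))
  net <- list(cfg = cfg,
              stem_conv = kaiming_weight(7L, 3L, stem_ch),
              stem_bn = bn_init(stem_ch),
              stages = vector("list", 4L))
  c_in <- stem_ch
  for (s in 1:4) {
    stage <- vector("list", cfg$blocks[s])
    for (i in seq_len(cfg$blocks[s])) {
      stride <- if (i == 1L && s > 1L) 2L else 1L
      stage[[i]] <- make_bottleneck(c_in, mids[s], outs[s], stride, zero_init_residual)
      c_in <- outs[s]
    }
    net$stages[[s]] <- stage
  }
  feat_dim <- if (cfg$multiscale) outs[3] + outs[4] else outs[4]
  net$fc_W <- matrix(stats::rnorm(feat_dim * cfg$n_classes, sd = 0.01),
                     feat_dim, cfg$n_classes)
  net$fc_b <- rep(0, cfg$n_classes)
  net$channels <- list(stem = stem_ch, outs = outs, mids = mids, feat = feat_dim)
  class(net) <- "shred_network"
  net
}

#' @export
print.shred_network <- function(x, ...) {
  print(x$cfg)
  cat(sprintf("  stage channels %s; fused feature length %d\n",
              paste(x$channels$outs, collapse = "/"), x$channels$feat))
  invisible(x)
}

block_fwd <- function(X, blk, training, bn_momentum = 0.1,
                      keep_cache = training) {
  c1 <- conv_fwd(X, blk$conv1, 1L, 0L, keep_cache)
  b1 <- bn_fwd(c1$Y, blk$bn1, training, bn_momentum, keep_cache = keep_cache); blk$bn1 <- b1$bn
  r1 <- relu_fwd(b1$Y, keep_cache)
  c2 <- conv_fwd(r1$Y, blk$conv2, blk$stride, 1L, keep_cache)
  b2 <- bn_fwd(c2$Y, blk$bn2, training, bn_momentum, keep_cache = keep_cache); blk$bn2 <- b2$bn
  r2 <- relu_fwd(b2$Y, keep_cache)
  c3 <- conv_fwd(r2$Y, blk$conv3, 1L, 0L, keep_cache)
  b3 <- bn_fwd(c3$Y, blk$bn3, training, bn_momentum, keep_cache = keep_cache); blk$bn3 <- b3$bn
  if (!is.null(blk$proj)) {
    cp <- conv_fwd(X, blk$proj, blk$stride, 0L, keep_cache)
    bp <- bn_fwd(cp$Y, blk$bn_proj, training, bn_momentum, keep_cache = keep_cache); blk$bn_proj <- bp$bn
    shortcut <- bp$Y
  } else {
    cp <- NULL; bp <- NULL; shortcut <- X
  }
  r3 <- relu_fwd(b3$Y + shortcut, keep_cache)
  cache <- if (keep_cache)
    list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
         c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
         c3 = c3$cache, b3 = b3$cache,
         cp = if (!is.null(cp)) cp$cache, bp = if (!is.null(bp)) bp$cache,
         r3 = r3$cache)
  list(Y = r3$Y, blk = blk, cache = cache)
}

block_bwd <- function(dY, blk, cache) {
  g <- list()
  dS <- dY * cache$r3
  db3 <- bn_bwd(dS, blk$bn3, cache$b3)
  g$bn3 <- list(gamma = db3$gamma, beta = db3$beta)
  dc3 <- conv_bwd(db3$dX, blk$conv3, cache$c3)
  g$conv3 <- dc3$dW
  dr2 <- dc3$dX * cache$r2
  db2 <- bn_bwd(dr2, blk$bn2, cache$b2)
  g$bn2 <- list(gamma = db2$gamma, beta = db2$beta)
  dc2 <- conv_bwd(db2$dX, blk$conv2, cache$c2)
  g$conv2 <- dc2$dW
  dr1 <- dc2$dX * cache$r1
  db1 <- bn_bwd(dr1, blk$bn1, cache$b1)
  g$bn1 <- list(gamma = db1$gamma, beta = db1$beta)
  dc1 <- conv_bwd(db1$dX, blk$conv1, cache$c1)
  g$conv1 <- dc1$dW
  dX <- dc1$dX
  if (!is.null(blk$proj)) {
    dbp <- bn_bwd(dS, blk$bn_proj, cache$bp)
    g$bn_proj <- list(gamma = dbp$gamma, beta = dbp$beta)
    dcp <- conv_bwd(dbp$dX, blk$proj, cache$cp)
    g$proj <- dcp$dW
    dX <- dX + dcp$dX
  } else {
    dX <- dX + dS
  }
  list(dX = dX, g = g)
}

#' Forward pass with named stage outputs
#'
#' @param net `shred_network`.
#' @param X Batch array in (H, W, N, 3) layout with values standardized by
#'   [resize_normalize()].
#' @param training Use batch statistics and keep backward caches.
#' @param bn_momentum Momentum for the batch-norm running statistics
#'   (training mode only).
#' @return List with `logits` (N x n_classes), `stage3`, `stage4` (the
#'   stage activations), `net` (with updated running statistics when
#'   training) and `cache`.
#' @export
net_forward <- function(net, X, training = FALSE, bn_momentum = 0.1,
                        keep_cache = training) {
  d <- dim(X)
  if (length(d) != 4L || d[4] != 3L)
    stop_sv("input batch must be an (H, W, N, 3) array")
  if (d[1] != net$cfg$input_side || d[2] != net$cfg$input_side)
    stop_sv("input is %dx%d but the network expects %dx%d",
            d[2], d[1], net$cfg$input_side, net$cfg$input_side)
  sc <- conv_fwd(X, net$stem_conv, 2L, 3L, keep_cache)
  sb <- bn_fwd(sc$Y, net$stem_bn, training, bn_momentum, keep_cache = keep_cache); net$stem_bn <- sb$bn
  sr <- relu_fwd(sb$Y, keep_cache)
  mp <- maxpool_fwd(sr$Y, 3L, 2L, 1L, keep_cache)
  cur <- mp$Y
  stage_caches <- vector("list", 4L)
  stage3 <- NULL; stage4 <- NULL
  for (s in 1:4) {
    blocks <- net$stages[[s]]
    caches <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      r <- block_fwd(cur, blocks[[i]], training, bn_momentum, keep_cache)
      blocks[[i]] <- r$blk
      caches[[i]] <- r$cache
      cur <- r$Y
    }
    net$stages[[s]] <- blocks
    stage_caches[[s]] <- caches
    if (s == 3L) stage3 <- cur
    if (s == 4L) stage4 <- cur
  }
  feat <- if (net$cfg$multiscale) cbind(gap_fwd(stage3), gap_fwd(stage4)) else gap_fwd(stage4)
  logits <- sweep(feat %*% net$fc_W, 2, net$fc_b, `+`)
  cache <- if (keep_cache)
    list(sc = sc$cache, sb = sb$cache, sr = sr$cache, mp = mp$cache,
         stages = stage_caches, feat = feat,
         d3 = dim(stage3), d4 = dim(stage4))
  list(logits = logits, stage3 = stage3, stage4 = stage4,
       net = net, cache = cache)
}

# Backward pass: dlogits (N x n_classes) -> gradient tree mirroring the
# trainable parameters of `net`.
net_backward <- function(dlogits, net, cache) {
  g <- list()
  g$fc_W <- crossprod(cache$feat, dlogits)
  g$fc_b <- colSums(dlogits)
  dfeat <- tcrossprod(dlogits, net$fc_W)
  c3 <- cache$d3[4]
  if (net$cfg$multiscale) {
    d4 <- gap_bwd(dfeat[, (c3 + 1L):ncol(dfeat), drop = FALSE], cache$d4)
    d3_extra <- gap_bwd(dfeat[, seq_len(c3), drop = FALSE], cache$d3)
  } else {
    d4 <- gap_bwd(dfeat, cache$d4)
    d3_extra <- NULL
  }
  g$stages <- vector("list", 4L)
  dcur <- d4
  for (s in 4:1) {
    blocks <- net$stages[[s]]
    gs <- vector("list", length(blocks))
    for (i in rev(seq_along(blocks))) {
      r <- block_bwd(dcur, blocks[[i]], cache$stages[[s]][[i]])
      gs[[i]] <- r$g
      dcur <- r$dX
    }
    g$stages[[s]] <- gs
    if (s == 4L && !is.null(d3_extra)) dcur <- dcur + d3_extra
  }
  dmp <- maxpool_bwd(dcur, cache$mp)
  dsr <- dmp * cache$sr
  dsb <- bn_bwd(dsr, net$stem_bn, cache$sb)
  g$stem_bn <- list(gamma = dsb$gamma, beta = dsb$beta)
  dsc <- conv_bwd(dsb$dX, net$stem_conv, cache$sc)
  g$stem_conv <- dsc$dW
  g
}

#' Recompute batch-norm running statistics over a reference set
#'
#' Resets every batch-norm running mean/variance and replaces them with the
#' exact cumulative average of batch statistics over `X`, leaving weights
#' untouched. Evaluation-mode behavior then matches the activation
#' distribution of the reference data; after short training runs the
#' momentum-smoothed running statistics still lag the rapidly moving
#' activations, and this realignment removes that lag.
#'
#' @param net `shred_network`.
#' @param X (H, W, N, 3) batch array (typically the training set).
#' @param batch_size Batch size for the statistics passes.
#' @return The network with updated running statistics.
#' @export
recalibrate_bn <- function(net, X, batch_size = 32L) {
  reset <- function(bn) { bn$rmean[] <- 0; bn$rvar[] <- 1; bn }
  net$stem_bn <- reset(net$stem_bn)
  for (s in seq_along(net$stages)) for (b in seq_along(net$stages[[s]])) {
    for (nm in c("bn1", "bn2", "bn3", "bn_proj"))
      if (!is.null(net$stages[[s]][[b]][[nm]]))
        net$stages[[s]][[b]][[nm]] <- reset(net$stages[[s]][[b]][[nm]])
  }
  n <- dim(X)[3]
  starts <- seq(1L, n, by = batch_size)
  k <- 0L
  for (start in starts) {
    idx <- start:min(start + batch_size - 1L, n)
    if (length(idx) < 2L) next
    k <- k + 1L
    fw <- net_forward(net, X[, , idx, , drop = FALSE], training = TRUE,
                      bn_momentum = 1 / k, keep_cache = FALSE)
    net <- fw$net
  }
  net
}

# Stack a list of (side, side, 3) tensors into an (side, side, N, 3) batch.
stack_tensors <- function(tensors) {
  side <- dim(tensors[[1]])[1]
  a <- array(unlist(tensors, use.names = FALSE),
             c(side, side, 3L, length(tensors)))
  aperm(a, c(1L, 2L, 4L, 3L))
}

#' Class probabilities for a batch of inputs
#'
#' Runs the network in evaluation mode (running batch-norm statistics) and
#' applies a softmax, so each row sums to one.
#'
#' @param net `shred_network`.
#' @param batch (H, W, N, 3) array, a single (H, W, 3) tensor, or a list of
#'   tensors from [resize_normalize()].
#' @return N x n_classes matrix of class probabilities.
#' @export
classify <- function(net, batch) {
  if (is.list(batch)) batch <- stack_tensors(batch)
  d <- dim(batch)
  if (length(d) == 3L) dim(batch) <- c(d[1], d[2], 1L, d[3])
  softmax_rows(net_forward(net, batch, training = FALSE)$logits)
}
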