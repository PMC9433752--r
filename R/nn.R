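# Minimal CNN engine on base R + BLAS. Activations are numeric arrays in
# (H, W, N, C) layout: height fastest in memory, channels last, so im2col
# matricizes without transposes and batch-norm reduces over contiguous
# slabs. Convolution weights are matrices of shape (C_in * k * k, C_out)
# whose rows are ordered channel-fastest, then kernel row offset, then
# kernel column offset. All backward passes are verified against finite
# differences in the test suite.

kaiming_weight <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out)
}

im2col <- function(X, k, stride, pad) {
  d <- dim(X)
  if (pad > 0L) {
    Xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
    Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  } else Xp <- X
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  M <- array(0, c(ho, wo, d[3], d[4], k * k))
  o <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    o <- o + 1L
    M[, , , , o] <- Xp[seq.int(a, by = stride, length.out = ho),
                       seq.int(b, by = stride, length.out = wo), , , drop = FALSE]
  }
  dim(M) <- c(ho * wo * d[3], d[4] * k * k)
  list(M = M, ho = ho, wo = wo)
}

col2im <- function(dM, dim_x, k, stride, pad, ho, wo) {
  dim(dM) <- c(ho, wo, dim_x[3], dim_x[4], k * k)
  dXp <- array(0, c(dim_x[1] + 2L * pad, dim_x[2] + 2L * pad, dim_x[3], dim_x[4]))
  o <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    o <- o + 1L
    ri <- seq.int(a, by = stride, length.out = ho)
    ci <- seq.int(b, by = stride, length.out = wo)
    dXp[ri, ci, , ] <- dXp[ri, ci, , ] + dM[, , , , o]
  }
  if (pad > 0L)
    dXp[pad + seq_len(dim_x[1]), pad + seq_len(dim_x[2]), , , drop = FALSE]
  else dXp
}

conv_fwd <- function(X, W, stride = 1L, pad = 0L, training = FALSE) {
  d <- dim(X)
  k <- as.integer(round(sqrt(nrow(W) / d[4])))
  if (k == 1L && pad == 0L) {
    Xs <- if (stride > 1L)
      X[seq.int(1L, d[1], by = stride), seq.int(1L, d[2], by = stride), , , drop = FALSE]
    else X
    ds <- dim(Xs)
    ho <- ds[1]; wo <- ds[2]
    M <- Xs; dim(M) <- c(ho * wo * d[3], d[4])
  } else {
    cc <- im2col(X, k, stride, pad)
    M <- cc$M; ho <- cc$ho; wo <- cc$wo
  }
  Y <- M %*% W
  dim(Y) <- c(ho, wo, d[3], ncol(W))
  list(Y = Y,
       cache = if (training) list(M = M, dim_x = d, k = k, stride = stride,
                                  pad = pad, ho = ho, wo = wo))
}

conv_bwd <- function(dY, W, cache) {
  dYm <- dY; dim(dYm) <- c(cache$ho * cache$wo * cache$dim_x[3], ncol(W))
  dW <- crossprod(cache$M, dYm)
  dM <- tcrossprod(dYm, W)
  if (cache$k == 1L && cache$pad == 0L) {
    if (cache$stride == 1L) {
      dX <- dM; dim(dX) <- cache$dim_x
    } else {
      dX <- array(0, cache$dim_x)
      dim(dM) <- c(cache$ho, cache$wo, cache$dim_x[3], cache$dim_x[4])
      dX[seq.int(1L, cache$dim_x[1], by = cache$stride),
         seq.int(1L, cache$dim_x[2], by = cache$stride), , ] <- dM
    }
  } else {
    dX <- col2im(dM, cache$dim_x, cache$k, cache$stride, cache$pad, cache$ho, cache$wo)
  }
  list(dX = dX, dW = dW)
}

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       rmean = rep(0, c_out), rvar = rep(1, c_out))
}

bn_fwd <- function(X, bn, training, momentum = 0.1, eps = 1e-5,
                   keep_cache = training) {
  d <- dim(X); n <- prod(d[1:3])
  Xm <- X; dim(Xm) <- c(n, d[4])
  if (training) {
    mu <- colMeans(Xm)
    Xc <- sweep(Xm, 2, mu)
    v <- colMeans(Xc * Xc)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- bn$rmean; v <- bn$rvar
    Xc <- sweep(Xm, 2, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(Xc, 2, invstd, `*`)
  Y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  dim(Y) <- d
  list(Y = Y, bn = bn,
       cache = if (keep_cache) list(xhat = xhat, invstd = invstd, d = d))
}

bn_bwd <- function(dY, bn, cache) {
  d <- cache$d; n <- prod(d[1:3])
  dYm <- dY; dim(dYm) <- c(n, d[4])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  t1 <- sweep(dYm, 2, dbeta / n)
  t2 <- sweep(cache$xhat, 2, dgamma / n, `*`)
  dX <- sweep(t1 - t2, 2, bn$gamma * cache$invstd, `*`)
  dim(dX) <- d
  list(dX = dX, gamma = dgamma, beta = dbeta)
}

relu_fwd <- function(X, training = FALSE) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, cache = if (training) mask)
}

maxpool_fwd <- function(X, k = 3L, stride = 2L, pad = 1L, training = FALSE) {
  d <- dim(X)
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  Xp <- array(-Inf, c(hp, wp, d[3], d[4]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  Y <- array(-Inf, c(ho, wo, d[3], d[4]))
  A <- array(0L, c(ho, wo, d[3], d[4]))
  o <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    o <- o + 1L
    cur <- Xp[seq.int(a, by = stride, length.out = ho),
              seq.int(b, by = stride, length.out = wo), , , drop = FALSE]
    upd <- cur > Y
    Y[upd] <- cur[upd]
    A[upd] <- o
  }
  list(Y = Y,
       cache = if (training) list(A = A, d = d, k = k, stride = stride,
                                  pad = pad, ho = ho, wo = wo))
}

maxpool_bwd <- function(dY, cache) {
  d <- cache$d; pad <- cache$pad
  dXp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  o <- 0L
  for (b in seq_len(cache$k)) for (a in seq_len(cache$k)) {
    o <- o + 1L
    ri <- seq.int(a, by = cache$stride, length.out = cache$ho)
    ci <- seq.int(b, by = cache$stride, length.out = cache$wo)
    dXp[ri, ci, , ] <- dXp[ri, ci, , ] + dY * (cache$A == o)
  }
  dXp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
}

gap_fwd <- function(X) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(Xm), d[3], d[4])
}

gap_bwd <- function(dY, d) {
  array(rep(as.numeric(dY), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam with L2 weight decay applied to convolution and FC weight matrices
# only (not to batch-norm scales/shifts or biases). `state` holds the first
# and second moment trees; `t` is the 1-based step count for bias
# correction.
adam_update <- function(params, grads, state, lr, t, wd = 1e-4,
                        b1 = 0.9, b2 = 0.99, eps = 1e-8) {
  decay_names <- c("conv1", "conv2", "conv3", "proj", "stem_conv", "fc_W")
  walk <- function(p, g, m, v) {
    keys <- names(g)
    if (is.null(keys)) keys <- seq_along(g)
    if (is.null(m)) { m <- vector("list", length(g)); v <- m }
    out_m <- m; out_v <- v
    for (i in seq_along(keys)) {
      nm <- keys[[i]]
      gi <- g[[nm]]
      if (is.list(gi)) {
        r <- walk(p[[nm]], gi, m[[nm]], v[[nm]])
        p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      } else {
        pi <- p[[nm]]
        if (is.character(nm) && nm %in% decay_names) gi <- gi + wd * pi
        mi <- m[[nm]]; vi <- v[[nm]]
        if (is.null(mi)) { mi <- gi * 0; vi <- gi * 0 }
        mi <- b1 * mi + (1 - b1) * gi
        vi <- b2 * vi + (1 - b2) * gi * gi
        mh <- mi / (1 - b1^t)
        vh <- vi / (1 - b2^t)
        p[[nm]] <- pi - lr * mh / (sqrt(vh) + eps)
        out_m[[nm]] <- mi; out_v[[nm]] <- vi
      }
    }
    list(p = p, m = out_m, v = out_v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}
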