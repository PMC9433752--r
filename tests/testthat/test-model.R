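test_that("depth index follows the 3*sum(blocks) + 2 layer count", {
  expect_identical(depth_index(c(3, 4, 6, 3)), 50L)
  expect_identical(depth_index(c(3, 4, 23, 3)), 101L)
  expect_identical(depth_index(c(3, 3, 16, 3)), 77L)  # the B-77 variant
  expect_error(depth_index(c(3, 0, 6, 3)), "positive")

  # agrees with counting weighted layers (stem + 3 per bottleneck + FC) in
  # the constructed network; projection shortcuts are not counted, per the
  # naming convention
  count_weighted <- function(net) {
    n <- 1L + 1L  # stem conv + final FC
    for (st in net$stages) for (blk in st) n <- n + 3L
    n
  }
  set.seed(2)
  for (i in 1:5) {
    blocks <- sample(1:4, 4, replace = TRUE)
    net <- build_network(model_config(blocks, input_side = 32, width_mult = 1 / 32))
    expect_identical(count_weighted(net), depth_index(blocks))
  }
})

test_that("stage outputs have the documented spatial extents and channel widths", {
  # width-reduced build keeps the stride structure of the full network
  cfg <- model_config(c(2, 2, 2, 2), multiscale = TRUE, input_side = 64, width_mult = 1 / 8)
  net <- build_network(cfg, seed = 1)
  X <- array(rnorm(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  fw <- net_forward(net, X)
  expect_equal(dim(fw$stage3), c(4, 4, 2, 128))   # 64 / 16, 1024 / 8
  expect_equal(dim(fw$stage4), c(2, 2, 2, 256))   # 64 / 32, 2048 / 8
  expect_equal(nrow(net$fc_W), 128 + 256)         # fused feature length

  sngl <- build_network(model_config(c(2, 2, 2, 2), multiscale = FALSE,
                                     input_side = 64, width_mult = 1 / 8), seed = 1)
  expect_equal(nrow(sngl$fc_W), 256)

  expect_error(net_forward(net, array(0, c(32, 32, 1, 3))), "expects 64x64")
  expect_error(model_config(c(3, 4, 6)), "4 positive")
})

test_that("classification is a softmax: rows sum to one, deterministic, symmetric at init", {
  cfg <- model_config(c(1, 1, 1, 1), input_side = 32, width_mult = 1 / 16)
  net <- build_network(cfg, seed = 9)
  X <- array(rnorm(32 * 32 * 8 * 3), c(32, 32, 8, 3))
  p <- classify(net, X)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)

  net2 <- build_network(cfg, seed = 9)
  expect_identical(classify(net2, X), p)

  # near-uniform class probabilities for an untrained network
  set.seed(77)
  Xbig <- array(rnorm(32 * 32 * 300 * 3), c(32, 32, 300, 3))
  pm <- colMeans(classify(net, Xbig))
  expect_true(all(abs(pm - 0.25) < 0.05))
})

test_that("multiscale and single-scale variants share the same trunk", {
  cfg_ms <- model_config(c(1, 1, 1, 1), multiscale = TRUE, input_side = 32, width_mult = 1 / 16)
  cfg_ss <- model_config(c(1, 1, 1, 1), multiscale = FALSE, input_side = 32, width_mult = 1 / 16)
  ms <- build_network(cfg_ms, seed = 4)
  ss <- build_network(cfg_ss, seed = 99)
  ss$stem_conv <- ms$stem_conv; ss$stem_bn <- ms$stem_bn; ss$stages <- ms$stages
  X <- array(rnorm(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  expect_identical(net_forward(ss, X)$stage4, net_forward(ms, X)$stage4)
})

test_that("backpropagated gradients match finite differences on a tiny network", {
  cfg <- model_config(c(1, 1, 1, 1), multiscale = TRUE, n_classes = 3,
                      input_side = 32, width_mult = 1 / 16)
  net <- build_network(cfg, seed = 7, zero_init_residual = FALSE)
  set.seed(42)
  X <- array(rnorm(32 * 32 * 3 * 3, 0, 0.5), c(32, 32, 3, 3))
  y <- c(1L, 2L, 3L)
  gam <- 0.75
  loss_of <- function(n) {
    fw <- net_forward(n, X, training = TRUE)
    focal_loss(softmax_rows(fw$logits), y, gam)
  }
  fw <- net_forward(net, X, training = TRUE)
  prob <- softmax_rows(fw$logits)
  grads <- net_backward(loss_grad_logits(prob, y, gam), net, fw$cache)

  probes <- list(
    list(get = function(n) n$stem_conv,
         set = function(n, v) { n$stem_conv[] <- v; n },
         g = grads$stem_conv),
    list(get = function(n) n$stages[[2]][[1]]$conv2,
         set = function(n, v) { n$stages[[2]][[1]]$conv2[] <- v; n },
         g = grads$stages[[2]][[1]]$conv2),
    list(get = function(n) n$stages[[4]][[1]]$proj,
         set = function(n, v) { n$stages[[4]][[1]]$proj[] <- v; n },
         g = grads$stages[[4]][[1]]$proj),
    list(get = function(n) n$stages[[3]][[1]]$bn2$gamma,
         set = function(n, v) { n$stages[[3]][[1]]$bn2$gamma <- v; n },
         g = grads$stages[[3]][[1]]$bn2$gamma),
    list(get = function(n) n$fc_W,
         set = function(n, v) { n$fc_W[] <- v; n },
         g = grads$fc_W))
  h <- 1e-5
  set.seed(1)
  for (pr in probes) {
    p0 <- pr$get(net)
    for (i in sample(length(p0), 3)) {
      v <- p0; v[i] <- v[i] + h
      lp <- loss_of(pr$set(net, v))
      v <- p0; v[i] <- v[i] - h
      lm <- loss_of(pr$set(net, v))
      fd <- (lp - lm) / (2 * h)
      expect_equal(pr$g[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("identity blocks preserve dimensions and Conv blocks downsample", {
  # directly exercise a block pair at stage-2 geometry
  set.seed(5)
  conv_blk <- shredvision:::make_bottleneck(16L, 8L, 32L, 2L, FALSE)
  id_blk <- shredvision:::make_bottleneck(32L, 8L, 32L, 1L, FALSE)
  X <- array(rnorm(16 * 16 * 2 * 16), c(16, 16, 2, 16))
  down <- shredvision:::block_fwd(X, conv_blk, training = FALSE)$Y
  expect_equal(dim(down), c(8, 8, 2, 32))
  same <- shredvision:::block_fwd(down, id_blk, training = FALSE)$Y
  expect_equal(dim(same), dim(down))
})
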