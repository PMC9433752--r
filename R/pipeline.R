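# Orchestration: dataset split, end-to-end preprocessing (gray -> block
# binarize -> contour screen -> square ROI -> crop), the training loop
# (Adam, per-epoch shuffling and test evaluation, step learning-rate
# decay), and evaluation reports.

#' Random 7:3 dataset split
#'
#' Uniformly random partition under `seed`; the training share is
#' `floor(ratio * n)` (8,202 items at the default ratio give 5,741 and
#' 2,461), the test share the remainder; the two are disjoint and
#' exhaustive.
#'
#' @param n Number of items (>= 2).
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(n, ratio = 0.7, seed = 1L) {
  if (n < 2L) stop_sv("need at least 2 items to split")
  if (ratio <= 0 || ratio >= 1) stop_sv("ratio must be in (0, 1)")
  set.seed(seed)
  n_train <- floor(ratio * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Preprocess one image or scene to a square shred crop
#'
#' The four-step pipeline: grayscale conversion, block-threshold
#' binarization, contour screening, square-ROI cropping. When a
#' `shred_scene` with ground truth is supplied, the crop is additionally
#' scored for completeness.
#'
#' @param x H x W x 3 color array or a `shred_scene`.
#' @param b Block size in pixels (default 125).
#' @param sd_thresh SD gate (default 6); see [calibrate_sd_threshold()].
#' @param margin ROI margin in pixels before squaring (default 0).
#' @param min_area_frac Residue cut-off for [screen_contours()].
#' @return List with `crop` (square color array), `roi`, `bbox`,
#'   `n_residues`, `complete` (NA without ground truth) and `class`
#'   (NA for plain images).
#' @export
preprocess_scene <- function(x, b = 125L, sd_thresh = 6, margin = 0L,
                             min_area_frac = 0.05) {
  scene <- inherits(x, "shred_scene")
  img <- if (scene) x$image else x
  assert_color_image(img)
  gray <- to_grayscale(img)
  mask <- binarize_block_threshold(gray, b, sd_thresh)
  comps <- extract_components(mask, 8L)
  if (length(comps) == 0L) stop_sv("no foreground found during preprocessing")
  scr <- screen_contours(comps, min_area_frac)
  roi <- square_roi(scr$main$bbox, ncol(img), nrow(img), margin)
  list(crop = crop_roi(img, roi), roi = roi, bbox = scr$main$bbox,
       n_residues = length(scr$residues),
       complete = if (scene) is_complete(mask, x$mask) else NA,
       class = if (scene) x$class else NA_character_)
}

#' Preprocess a corpus of scenes or images
#'
#' Applies [preprocess_scene()] to each element; failures are recorded in
#' the manifest, not fatal.
#'
#' @param xs List of color images or `shred_scene` objects.
#' @inheritParams preprocess_scene
#' @return List with `crops` (list of square color crops, NULL where
#'   preprocessing failed) and `manifest` (data frame with one row per
#'   input: `index`, `class`, `complete`, `n_residues`, `roi_side`, `ok`,
#'   `note`).
#' @export
preprocess_corpus <- function(xs, b = 125L, sd_thresh = 6, margin = 0L,
                              min_area_frac = 0.05) {
  n <- length(xs)
  if (n == 0L) {
    warning("empty input corpus")
    return(list(crops = list(),
                manifest = data.frame(index = integer(), class = character(),
                                      complete = logical(), n_residues = integer(),
                                      roi_side = integer(), ok = logical(),
                                      note = character())))
  }
  crops <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(preprocess_scene(xs[[i]], b, sd_thresh, margin, min_area_frac),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(index = i, class = NA_character_, complete = NA,
                              n_residues = NA_integer_, roi_side = NA_integer_,
                              ok = FALSE, note = conditionMessage(res))
    } else {
      crops[[i]] <- res$crop
      rows[[i]] <- data.frame(index = i, class = res$class,
                              complete = res$complete,
                              n_residues = res$n_residues,
                              roi_side = res$roi[2] - res$roi[1],
                              ok = TRUE, note = "")
    }
  }
  list(crops = crops, manifest = do.call(rbind, rows))
}

#' Synthesize a preprocessed crop dataset, one scene at a time
#'
#' Streams scene generation through the preprocessing pipeline so that full
#' frames are never held in memory together: each scene is generated
#' (seeded `seed + i`, classes by largest-remainder apportionment as in
#' [generate_corpus()]), binarized, screened, cropped, resized to `side`
#' pixels and standardized.
#'
#' @param n Number of scenes/crops.
#' @param class_mix Class proportions (sum to 1).
#' @param params [scene_params()].
#' @param seed Base seed.
#' @param side Output tensor side in pixels.
#' @inheritParams preprocess_scene
#' @return List with `x` (a (side, side, n, 3) standardized tensor),
#'   `y` (factor of class labels) and `complete` (logical per scene).
#' @export
synthesize_crops <- function(n, class_mix = rep(0.25, 4), params = scene_params(),
                             seed = 1L, side = 64L, b = 125L, sd_thresh = 6,
                             margin = 0L, min_area_frac = 0.05) {
  counts <- apportion(n, class_mix)
  labels <- rep(params$classes$class, counts)
  X <- array(0, c(side, side, n, 3L))
  complete <- logical(n)
  for (i in seq_len(n)) {
    scene <- generate_scene(params, seed + i, labels[i])
    pp <- preprocess_scene(scene, b, sd_thresh, margin, min_area_frac)
    X[, , i, ] <- resize_normalize(pp$crop, side)
    complete[i] <- isTRUE(pp$complete)
  }
  list(x = X, y = factor(labels, levels = params$classes$class),
       complete = complete)
}

#' Training configuration
#'
#' Defaults: Adam with initial learning rate 1e-4 for cross-entropy and
#' 1e-3 for focal loss, weight decay 1e-4, beta1 0.9, beta2 0.99, epsilon
#' 1e-8; batch size 32; up to 50 epochs; step learning-rate decay by a
#' factor of 0.1 every 20 epochs.
#'
#' @param lr Initial learning rate; NULL picks the loss-specific default.
#' @param weight_decay,beta1,beta2,eps Adam hyperparameters.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param lr_decay_every,lr_decay_factor Step-decay schedule.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = NULL, weight_decay = 1e-4, beta1 = 0.9,
                         beta2 = 0.99, eps = 1e-8, batch_size = 32L,
                         epochs = 50L, lr_decay_every = 20L,
                         lr_decay_factor = 0.1) {
  structure(list(lr = lr, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, eps = eps, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor),
            class = "train_config")
}

# Random dihedral-group augmentation of a square (H, W, N, C) batch: each
# sample gets an independent flip / quarter-rotation. Label-preserving for
# shreds, which have no canonical orientation.
augment_batch <- function(Xb) {
  n <- dim(Xb)[3]
  for (i in seq_len(n)) {
    s <- Xb[, , i, ]
    k <- sample(0:3, 1)
    if (k == 1L) s <- aperm(s, c(2L, 1L, 3L))[dim(s)[2]:1, , , drop = FALSE]
    if (k == 2L) s <- s[dim(s)[1]:1, dim(s)[2]:1, , drop = FALSE]
    if (k == 3L) s <- aperm(s, c(2L, 1L, 3L))[, dim(s)[1]:1, , drop = FALSE]
    if (sample(c(TRUE, FALSE), 1)) s <- s[, dim(s)[2]:1, , drop = FALSE]
    Xb[, , i, ] <- s
  }
  Xb
}

prep_tensors <- function(x, side) {
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  stack_tensors(lapply(x, function(img) {
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    resize_normalize(img, side)
  }))
}

#' Train a shred classifier
#'
#' Fits a multi-scale residual network on square shred crops. Each crop is
#' bilinearly resized to the configured input side and standardized; the
#' training set is reshuffled every epoch; after each epoch the loss is
#' recorded and, if a test set is given, test accuracy is evaluated; all
#' per-epoch results are retained in the history.
#'
#' @param x List of color crops (or a prebuilt (H, W, N, 3) tensor).
#' @param y Class labels: factor or character vector.
#' @param config [model_config()] describing the network.
#' @param tc [train_config()] with optimizer settings.
#' @param loss `"focal"` (default) or `"ce"`.
#' @param gamma Focal modulation factor (default 0.75).
#' @param x_test,y_test Optional held-out set evaluated each epoch.
#' @param augment Apply random flips and quarter-rotations to each training
#'   batch (label-preserving for shreds, which have no canonical
#'   orientation; useful for small training sets). Default FALSE.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param verbose Print one line per epoch.
#' @return Object of class `shrednet`: list with `net`, `classes`,
#'   `history` (data frame: epoch, lr, train_loss, test_acc), `config`,
#'   `train_config`, `loss`, `gamma`.
#' @export
shred_train <- function(x, y, config = model_config(), tc = train_config(),
                        loss = c("focal", "ce"), gamma = 0.75,
                        x_test = NULL, y_test = NULL, augment = FALSE,
                        seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) != config$n_classes)
    stop_sv("config expects %d classes but labels have %d", config$n_classes, length(classes))
  labels <- as.integer(y)
  X <- prep_tensors(x, config$input_side)
  n <- dim(X)[3]
  if (n < 1L || length(labels) != n) stop_sv("x and y sizes differ or are empty")
  lr0 <- if (is.null(tc$lr)) { if (loss == "focal") 1e-3 else 1e-4 } else tc$lr
  gam <- if (loss == "focal") gamma else 0
  if (!is.null(x_test)) {
    Xt <- prep_tensors(x_test, config$input_side)
    lt <- as.integer(factor(as.character(y_test), levels = classes))
  }
  set.seed(seed)
  net <- build_network(config)
  state <- list(m = NULL, v = NULL)
  t_step <- 0L
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), test_acc = numeric())
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr0 * tc$lr_decay_factor^((epoch - 1L) %/% tc$lr_decay_every)
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      if (length(idx) < 2L) next  # batch norm needs at least 2 samples
      Xb <- X[, , idx, , drop = FALSE]
      if (augment) Xb <- augment_batch(Xb)
      yb <- labels[idx]
      fw <- net_forward(net, Xb, training = TRUE)
      net <- fw$net
      prob <- softmax_rows(fw$logits)
      batch_losses <- c(batch_losses,
                        if (gam == 0) cross_entropy(prob, yb) else focal_loss(prob, yb, gam))
      dlogits <- loss_grad_logits(prob, yb, gam)
      grads <- net_backward(dlogits, net, fw$cache)
      t_step <- t_step + 1L
      upd <- adam_update(net, grads, state, lr, t_step, tc$weight_decay,
                         tc$beta1, tc$beta2, tc$eps)
      class(upd$params) <- class(net)
      net <- upd$params
      state <- upd$state
    }
    test_acc <- NA_real_
    if (!is.null(x_test)) {
      # align evaluation-mode statistics with the training distribution
      # before scoring; the training trajectory itself is unaffected
      net_eval <- recalibrate_bn(net, X)
      pred <- predict_batched(net_eval, Xt)
      test_acc <- mean(pred == lt)
      if (epoch == tc$epochs) net <- net_eval
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = mean(batch_losses),
                                         test_acc = test_acc))
    if (verbose)
      message(sprintf("epoch %2d  lr %.2g  train loss %.4f  test acc %s",
                      epoch, lr, mean(batch_losses),
                      ifelse(is.na(test_acc), "-", sprintf("%.4f", test_acc))))
  }
  if (is.null(x_test)) net <- recalibrate_bn(net, X)
  structure(list(net = net, classes = classes, history = history,
                 config = config, train_config = tc, loss = loss,
                 gamma = gam, seed = seed),
            class = "shrednet")
}

# Evaluate in manageable chunks to bound memory.
predict_batched <- function(net, X, chunk = 32L) {
  n <- dim(X)[3]
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    prob <- classify(net, X[, , idx, , drop = FALSE])
    out[idx] <- max.col(prob, ties.method = "first")
  }
  out
}

#' @export
print.shrednet <- function(x, ...) {
  cat(sprintf("shrednet: %d classes (%s), %s loss%s, %d epochs\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$loss, if (x$loss == "focal") sprintf(" (gamma %g)", x$gamma) else "",
              nrow(x$history)))
  print(x$config)
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f%s\n", last$train_loss,
              if (!is.na(last$test_acc)) sprintf(", test accuracy %.4f", last$test_acc) else ""))
  invisible(x)
}

#' Predict classes or probabilities for new crops
#'
#' @param object `shrednet` fit.
#' @param newdata List of color crops or an (H, W, N, 3) tensor.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or an N x k probability matrix.
#' @export
predict.shrednet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- prep_tensors(newdata, object$config$input_side)
  if (type == "prob") {
    n <- dim(X)[3]
    out <- NULL
    for (start in seq(1L, n, by = 32L)) {
      idx <- start:min(start + 31L, n)
      out <- rbind(out, classify(object$net, X[, , idx, , drop = FALSE]))
    }
    colnames(out) <- object$classes
    return(out)
  }
  factor(object$classes[predict_batched(object$net, X)], levels = object$classes)
}

#' Training-history plot
#'
#' @param x `shrednet` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.shrednet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (any(!is.na(h$test_acc))) 2 else 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "train loss", main = "Training loss", ...)
  if (any(!is.na(h$test_acc)))
    graphics::plot(h$epoch, h$test_acc, type = "b", xlab = "epoch",
                   ylab = "test accuracy", main = "Test accuracy", ...)
  invisible(x)
}

#' Evaluate a fitted classifier on a test set
#'
#' @param fit `shrednet` fit.
#' @param x List of color crops or tensor.
#' @param y True labels.
#' @return [confusion_metrics()] report with per-class rows and the
#'   equally weighted average row.
#' @export
evaluate_network <- function(fit, x, y) {
  if (length(y) == 0L) stop_sv("empty test set")
  pred <- predict(fit, x)
  confusion_metrics(pred, factor(as.character(y), levels = fit$classes),
                    class_names = fit$classes)
}
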