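# Cross-entropy and focal loss with probability clamping, and the
# one-vs-rest evaluation metrics with equally weighted (macro) averaging.
# Probabilities entering a logarithm are clamped to [0.005, 0.995] so the
# loss stays finite for saturated predictions.

CLAMP_LO <- 0.005
CLAMP_HI <- 0.995

clamp_prob <- function(p) pmin(pmax(p, CLAMP_LO), CLAMP_HI)

check_pred_labels <- function(pred, labels) {
  if (!is.matrix(pred) || nrow(pred) == 0L) stop_sv("pred must be a nonempty m x k probability matrix")
  labels <- as.integer(labels)
  if (length(labels) != nrow(pred)) stop_sv("pred and labels lengths differ")
  if (any(labels < 1L) || any(labels > ncol(pred))) stop_sv("labels out of class range")
  labels
}

#' Cross-entropy loss of a predicted batch
#'
#' Mean over the batch of the negative log predicted probability of the
#' true class (the one-hot double sum reduces to this), with the predicted
#' probability clamped to \code{[0.005, 0.995]} before the logarithm.
#'
#' @param pred m x k matrix of predicted class distributions (rows sum
#'   to 1).
#' @param labels Integer vector of true classes in 1..k.
#' @return Nonnegative scalar loss (natural log).
#' @export
cross_entropy <- function(pred, labels) {
  labels <- check_pred_labels(pred, labels)
  p <- clamp_prob(pred[cbind(seq_along(labels), labels)])
  -mean(log(p))
}

#' Focal loss of a predicted batch
#'
#' Cross-entropy modulated by \eqn{(1 - p)^\gamma}, where p is the clamped
#' softmax probability of the true class, so confidently classified (easy)
#' samples contribute less and hard samples dominate the gradient. At
#' \eqn{\gamma = 0} it equals [cross_entropy()].
#'
#' @param pred m x k matrix of predicted class distributions.
#' @param labels Integer vector of true classes in 1..k.
#' @param gamma Nonnegative modulation factor (default 0.75).
#' @return Nonnegative scalar loss.
#' @export
focal_loss <- function(pred, labels, gamma = 0.75) {
  if (gamma < 0) stop_sv("gamma must be >= 0")
  labels <- check_pred_labels(pred, labels)
  p <- clamp_prob(pred[cbind(seq_along(labels), labels)])
  -mean((1 - p)^gamma * log(p))
}

# Gradient of the mean focal loss (gamma = 0 gives cross-entropy) with
# respect to the logits, given softmax probabilities. The clamp is treated
# exactly: a saturated true-class probability contributes zero gradient.
loss_grad_logits <- function(prob, labels, gamma) {
  m <- nrow(prob)
  p_true <- prob[cbind(seq_len(m), labels)]
  inside <- p_true > CLAMP_LO & p_true < CLAMP_HI
  pc <- clamp_prob(p_true)
  # dL_i/dp for L_i = -(1 - p)^gamma log(p)
  dldp <- if (gamma == 0) -1 / pc
          else gamma * (1 - pc)^(gamma - 1) * log(pc) - (1 - pc)^gamma / pc
  dldp[!inside] <- 0
  onehot <- matrix(0, m, ncol(prob))
  onehot[cbind(seq_len(m), labels)] <- 1
  (dldp * p_true / m) * (onehot - prob)
}

#' One-vs-rest confusion metrics with equally weighted averaging
#'
#' For each class builds the one-vs-rest 2x2 table (TP, TN, FP, FN) and
#' computes accuracy, precision, recall and F1 (harmonic mean of precision
#' and recall); the summary row is the unweighted mean over classes,
#' regardless of class frequency. Undefined ratios (empty denominator) are
#' reported as 0.
#'
#' @param pred Predicted classes: integers in 1..k or a factor.
#' @param truth True classes, same length and coding.
#' @param k Number of classes (default: inferred).
#' @param class_names Optional class labels for printing.
#' @return Object of class `class_metrics`: list with `confusion` (k x k
#'   matrix, rows = truth), `per_class` (data frame with TP/TN/FP/FN, ACC,
#'   P, R, F1), `average` (named vector of equally weighted means) and
#'   `accuracy` (overall fraction correct).
#' @export
confusion_metrics <- function(pred, truth, k = NULL, class_names = NULL) {
  if (is.factor(pred) || is.factor(truth)) {
    lev <- levels(as.factor(truth))
    if (is.null(class_names)) class_names <- lev
    pred <- as.integer(factor(pred, levels = lev))
    truth <- as.integer(factor(truth, levels = lev))
  }
  if (length(pred) != length(truth)) stop_sv("pred and truth lengths differ")
  if (is.null(k)) k <- max(pred, truth)
  if (any(pred < 1L | pred > k) || any(truth < 1L | truth > k))
    stop_sv("class indices outside 1..%d", k)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(k))
  n <- length(truth)
  confusion <- matrix(0L, k, k, dimnames = list(truth = class_names, pred = class_names))
  for (i in seq_len(n)) confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- (tp + tn) / n
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  f1 <- safe(2 * prec * rec, prec + rec)
  per_class <- data.frame(class = class_names, TP = tp, TN = tn, FP = fp, FN = fn,
                          ACC = acc, P = prec, R = rec, F1 = f1,
                          row.names = NULL)
  structure(list(confusion = confusion, per_class = per_class,
                 average = c(ACC = mean(acc), P = mean(prec),
                             R = mean(rec), F1 = mean(f1)),
                 accuracy = sum(tp) / n),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, digits = 4, ...) {
  cat("Per-class one-vs-rest metrics:\n")
  df <- x$per_class
  df[c("ACC", "P", "R", "F1")] <- round(df[c("ACC", "P", "R", "F1")], digits)
  print(df, row.names = FALSE)
  cat(sprintf("Equally weighted average: ACC %.4f  P %.4f  R %.4f  F1 %.4f\n",
              x$average["ACC"], x$average["P"], x$average["R"], x$average["F1"]))
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  invisible(x)
}
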