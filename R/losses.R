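# The three training losses of the stage-two ensemble, on the probability
# simplex: frequency-weighted cross entropy (WCE), multiclass soft Dice
# (DC), and Lovasz-softmax (LV). All operate on an n x 5 probability matrix
# over lung voxels only (the caller applies the lung restriction) with
# integer targets in 1..5, and all vanish on a perfect one-hot prediction.
# Analytic gradients with respect to the logits drive the network training;
# finite differences are the test oracle.

#' Inverse-frequency class weights
#'
#' Weights are proportional to the reciprocal pooled class fraction,
#' normalised so the finite weights have mean 1; a class with zero frequency
#' gets the cap, with a warning.
#'
#' @param freqs a [class_frequencies()] data.frame (or any data.frame with a
#'   `fraction` column of length 5).
#' @param cap weight assigned to zero-frequency classes.
#' @return Numeric length-5 weight vector.
#' @export
weights_from_frequencies <- function(freqs, cap = 100) {
  f <- freqs$fraction
  stopifnot(length(f) == 5L, all(f >= 0))
  w <- ifelse(f > 0, 1 / f, NA_real_)
  fin <- !is.na(w)
  w[fin] <- w[fin] / mean(w[fin])
  if (any(!fin)) {
    warning("class(es) with zero frequency assigned the weight cap (",
            cap, ")", call. = FALSE)
    w[!fin] <- cap
  }
  w
}

check_probs <- function(prob, target) {
  stopifnot(is.matrix(prob), ncol(prob) == 5L,
            length(target) == nrow(prob))
  if (!all(target %in% RILD_CLASSES))
    stop("targets must be classes 1..5", call. = FALSE)
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    stop("probabilities must sum to 1 per voxel", call. = FALSE)
  invisible(TRUE)
}

#' Weighted cross entropy
#'
#' Mean over voxels of `-w[y] * log p[y]`; reduces to plain cross entropy at
#' unit weights. Zero probabilities at the target are clamped at `eps`.
#'
#' @param prob n x 5 matrix of class probabilities (rows sum to 1).
#' @param target integer vector of true classes in 1..5.
#' @param weights length-5 positive class weights.
#' @param eps probability clamp.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(prob, target, weights = rep(1, 5),
                                   eps = 1e-7) {
  check_probs(prob, target)
  stopifnot(length(weights) == 5L, all(weights > 0))
  p_true <- pmax(prob[cbind(seq_along(target), target)], eps)
  mean(-weights[target] * log(p_true))
}

#' Multiclass soft Dice loss
#'
#' One minus the mean, over classes present in the target, of the smoothed
#' soft Dice ratio `(2 sum(p_c t_c) + s) / (sum(p_c) + sum(t_c) + s)`.
#'
#' @inheritParams weighted_cross_entropy
#' @param smooth additive smoothing applied to numerator and denominator.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(prob, target, smooth = 1) {
  check_probs(prob, target)
  present <- sort(unique(target))
  dices <- vapply(present, function(cls) {
    t_c <- as.numeric(target == cls)
    (2 * sum(prob[, cls] * t_c) + smooth) /
      (sum(prob[, cls]) + sum(t_c) + smooth)
  }, numeric(1))
  1 - mean(dices)
}

#' Gradient of the Lovasz extension of the Jaccard loss
#'
#' Given the 0/1 ground-truth membership vector sorted by decreasing
#' prediction error, returns the vector of discrete-gradient coefficients:
#' the inner product of sorted errors with this vector is the Lovasz
#' extension of `1 - IoU` at that error vector.
#'
#' @param gt_sorted 0/1 vector sorted by decreasing error.
#' @return Numeric coefficient vector of the same length.
#' @export
lovasz_grad <- function(gt_sorted) {
  p <- length(gt_sorted)
  gts <- sum(gt_sorted)
  intersection <- gts - cumsum(gt_sorted)
  union <- gts + cumsum(1 - gt_sorted)
  jaccard <- 1 - intersection / union
  if (p > 1) jaccard[2:p] <- jaccard[2:p] - jaccard[1:(p - 1)]
  jaccard
}

#' Lovasz-softmax loss
#'
#' Per class present in the target: errors are `1 - p_c` on that class's
#' voxels and `p_c` elsewhere; sorted in decreasing order their inner
#' product with [lovasz_grad()] gives the class surrogate, and the loss is
#' the mean over present classes. On hard 0/1 predictions it equals the
#' mean of `1 - IoU` over present classes.
#'
#' @inheritParams weighted_cross_entropy
#' @return Scalar loss in `[0, 1]`.
#' @export
lovasz_softmax <- function(prob, target) {
  check_probs(prob, target)
  present <- sort(unique(target))
  losses <- vapply(present, function(cls) {
    fg <- as.numeric(target == cls)
    errors <- abs(fg - prob[, cls])
    ord <- order(errors, decreasing = TRUE)
    sum(errors[ord] * lovasz_grad(fg[ord]))
  }, numeric(1))
  mean(losses)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# chain rule through row-wise softmax: g = dL/dp -> dL/dz
softmax_backprop <- function(p, g) {
  p * (g - rowSums(g * p))
}

# Loss value and gradient w.r.t. logits for the training loop.
# logits: n x 5 over lung voxels; target in 1..5.
loss_grad_logits <- function(kind, logits, target, weights = rep(1, 5),
                             smooth = 1, eps = 1e-7) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  if (kind == "WCE") {
    onehot <- matrix(0, n, 5)
    onehot[cbind(seq_len(n), target)] <- 1
    loss <- mean(-weights[target] * log(pmax(p[cbind(seq_len(n), target)],
                                             eps)))
    grad <- (weights[target] / n) * (p - onehot)
    return(list(loss = loss, grad = grad))
  }
  if (kind == "DC") {
    present <- sort(unique(target))
    gp <- matrix(0, n, 5)
    dices <- numeric(length(present))
    for (k in seq_along(present)) {
      cls <- present[k]
      t_c <- as.numeric(target == cls)
      num <- 2 * sum(p[, cls] * t_c) + smooth
      den <- sum(p[, cls]) + sum(t_c) + smooth
      dices[k] <- num / den
      # d(1 - mean dice)/dp_c = -(2 t_c den - num) / den^2 / |present|
      gp[, cls] <- -(2 * t_c * den - num) / den^2 / length(present)
    }
    return(list(loss = 1 - mean(dices), grad = softmax_backprop(p, gp)))
  }
  if (kind == "LV") {
    present <- sort(unique(target))
    gp <- matrix(0, n, 5)
    losses <- numeric(length(present))
    for (k in seq_along(present)) {
      cls <- present[k]
      fg <- as.numeric(target == cls)
      errors <- abs(fg - p[, cls])
      ord <- order(errors, decreasing = TRUE)
      g <- lovasz_grad(fg[ord])
      losses[k] <- sum(errors[ord] * g)
      coeff <- numeric(n)
      coeff[ord] <- g
      # d|fg - p|/dp = -1 on the class's voxels, +1 elsewhere
      gp[, cls] <- ifelse(fg == 1, -coeff, coeff) / length(present)
    }
    return(list(loss = mean(losses), grad = softmax_backprop(p, gp)))
  }
  stop("unknown loss kind: ", kind, call. = FALSE)
}
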