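# 2D encoder-decoder segmenters and their logit-sum ensembles.
#
# Architecture: canonical depth-4 U-Net. Encoder filter widths f, 2f, 4f,
# 8f with a 16f bottleneck; two 3x3 convolutions per level, each followed by
# instance normalisation and ReLU; 2x2 max-pool down, nearest-upsample +
# conv up with skip concatenation; a 1x1 convolution to 5 class channels
# (softmax head — the stored scores are the pre-softmax logits, which is
# what the ensemble sums).

#' Configure one segmentation network
#'
#' @param loss training loss: `"WCE"` (frequency-weighted cross entropy),
#'   `"DC"` (soft Dice) or `"LV"` (Lovasz-softmax).
#' @param base_filters filters at the first level; the study-scale presets
#'   use 32 or 64, smaller values give desk-scale networks.
#' @param in_channels odd number of input channels (adjacent axial slices;
#'   default 1, the windowed slice itself).
#' @param seed weight-initialisation seed.
#' @return A `net_config`.
#' @export
net_config <- function(loss = c("WCE", "DC", "LV"), base_filters = 32L,
                       in_channels = 1L, seed = 1L) {
  loss <- match.arg(loss)
  if (length(base_filters) != 1L || base_filters < 1 ||
      base_filters != round(base_filters))
    stop("base_filters must be a positive integer", call. = FALSE)
  if (in_channels %% 2L != 1L)
    stop("in_channels must be odd", call. = FALSE)
  structure(list(loss = loss, base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels), depth = 4L,
                 n_classes = 5L, seed = as.integer(seed)),
            class = "net_config")
}

#' Preset ensemble configurations
#'
#' Stage one is the 3-network draft-annotation ensemble (WCE at the smaller
#' width, Lovasz at both widths); stage two crosses all three losses with
#' both widths (6 networks).
#'
#' @param preset `"stage1"` or `"stage2"`.
#' @param base_filters the two filter widths, default `c(32, 64)`.
#' @param in_channels passed to every member.
#' @param seed base seed; member i uses `seed + i`.
#' @return List of `net_config` objects.
#' @export
ensemble_config <- function(preset = c("stage2", "stage1"),
                            base_filters = c(32L, 64L), in_channels = 1L,
                            seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(length(base_filters) == 2L)
  f1 <- base_filters[1]; f2 <- base_filters[2]
  members <- if (preset == "stage1") {
    list(c("WCE", f1), c("LV", f1), c("LV", f2))
  } else {
    list(c("WCE", f1), c("WCE", f2), c("DC", f1), c("DC", f2),
         c("LV", f1), c("LV", f2))
  }
  lapply(seq_along(members), function(i) {
    net_config(loss = members[[i]][1],
               base_filters = as.integer(members[[i]][2]),
               in_channels = in_channels, seed = seed + i)
  })
}

# (Cin, Cout, kernel, has instance norm) per unit, in the fixed order the
# C++ driver expects
unet_layout <- function(f, in_channels) {
  ch <- f * c(1, 2, 4, 8, 16)
  units <- list()
  cin <- in_channels
  for (l in 1:5) {                       # encoder levels + bottleneck
    units <- c(units, list(c(cin, ch[l]), c(ch[l], ch[l])))
    cin <- ch[l]
  }
  for (l in 4:1) {                       # decoder levels 3..0
    units <- c(units, list(c(ch[l + 1], ch[l]),       # up conv
                           c(2 * ch[l], ch[l]),       # after skip concat
                           c(ch[l], ch[l])))
  }
  units <- c(units, list(c(ch[1], 5L)))  # 1x1 head
  lapply(seq_along(units), function(i) {
    list(cin = units[[i]][1], cout = units[[i]][2],
         k = if (i == length(units)) 1L else 9L,
         has_in = i != length(units))
  })
}

#' Build a network from its configuration
#'
#' Initialises all weights deterministically from the config seed (He
#' initialisation for convolutions, unit scale / zero shift for instance
#' norm).
#'
#' @param config a [net_config()].
#' @return A `rild_net` (config + parameter list).
#' @export
build_net <- function(config) {
  stopifnot(inherits(config, "net_config"))
  layout <- unet_layout(config$base_filters, config$in_channels)
  params <- with_seed(config$seed, lapply(layout, function(u) {
    W <- matrix(stats::rnorm(u$k * u$cin * u$cout,
                             sd = sqrt(2 / (u$k * u$cin))),
                u$k * u$cin, u$cout)
    p <- list(W = W, b = numeric(u$cout))
    if (u$has_in) { p$g <- rep(1, u$cout); p$be <- numeric(u$cout) }
    p
  }))
  structure(list(config = config, params = params), class = "rild_net")
}

#' Number of trainable parameters
#' @param net a `rild_net`.
#' @export
parameter_count <- function(net) {
  sum(vapply(net$params, function(u)
    sum(vapply(u, length, integer(1))), numeric(1)))
}

#' @export
print.rild_net <- function(x, ...) {
  cat(sprintf("<rild_net> loss=%s f=%d in_channels=%d, %s parameters\n",
              x$config$loss, x$config$base_filters, x$config$in_channels,
              format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

sample_image_array <- function(sample) {
  img <- sample$image
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  img
}

check_input_shape <- function(net, img) {
  d <- dim(img)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input shape must be divisible by 16 (four reduction stages), got ",
         d[1], "x", d[2], call. = FALSE)
  if (d[3] != net$config$in_channels)
    stop("sample has ", d[3], " channels but the network expects ",
         net$config$in_channels, call. = FALSE)
  invisible(TRUE)
}

#' Forward pass: per-class logit scores for one sample
#'
#' Returns the pre-softmax class scores on the network grid. Softmax is
#' monotone per voxel, so `argmax` over these scores is the single-network
#' prediction; the ensemble sums these scores across members before the
#' argmax.
#'
#' @param net a trained (or freshly built) `rild_net`.
#' @param sample one element of [make_samples()].
#' @return `(H, W, 5)` score array.
#' @export
predict_scores <- function(net, sample) {
  img <- sample_image_array(sample)
  check_input_shape(net, img)
  cpp_unet_logits(net$params, img)
}

#' Train one network
#'
#' Plain stochastic training (batch size 1) with Adam. Deterministic given
#' `seed`: initial weights come from the config seed, shuffling from the
#' training seed. Optional early stopping on a validation set. Aborts with
#' a diagnostic if the loss diverges to NaN.
#'
#' @param net a `rild_net` from [build_net()].
#' @param samples training samples from [make_samples()] (lung-containing).
#' @param epochs passes over the training set.
#' @param lr Adam learning rate.
#' @param weights length-5 class weights (used by the WCE loss; see
#'   [weights_from_frequencies()]).
#' @param val_samples optional validation samples for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed shuffling seed.
#' @param verbose print per-epoch losses.
#' @return The trained `rild_net`, with a `history` data.frame attached
#'   (epoch, train_loss, val_loss).
#' @export
train_net <- function(net, samples, epochs = 10L, lr = 1e-3,
                      weights = rep(1, 5), val_samples = NULL,
                      patience = 3L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "rild_net"), length(samples) >= 1)
  kind <- net$config$loss
  params <- net$params
  adam_m <- rapply(params, function(x) x * 0, how = "replace")
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L
  history <- list()
  best_val <- Inf; best_params <- params; stale <- 0L

  sample_loss_grad <- function(sample) {
    lung_idx <- which(sample$lung == 1L)
    target <- sample$labels[lung_idx]
    function(logits) {
      d <- dim(logits)
      lmat <- matrix(logits, d[1] * d[2], d[3])[lung_idx, , drop = FALSE]
      lg <- loss_grad_logits(kind, lmat, target, weights)
      grad <- matrix(0, d[1] * d[2], d[3])
      grad[lung_idx, ] <- lg$grad
      list(loss = lg$loss, grad = array(grad, dim = d))
    }
  }

  eval_loss <- function(sample) {
    sc <- cpp_unet_logits(params, sample_image_array(sample))
    lung_idx <- which(sample$lung == 1L)
    d <- dim(sc)
    lmat <- matrix(sc, d[1] * d[2], d[3])[lung_idx, , drop = FALSE]
    loss_grad_logits(kind, lmat, sample$labels[lung_idx], weights)$loss
  }

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(samples))
      ep_losses <- numeric(0)
      for (si in ord) {
        sm <- samples[[si]]
        if (!any(sm$lung == 1L)) next
        img <- sample_image_array(sm)
        check_input_shape(net, img)
        step <- cpp_unet_step(params, img, sample_loss_grad(sm))
        if (!is.finite(step$loss))
          stop("training diverged (non-finite ", kind, " loss at epoch ",
               ep, ")", call. = FALSE)
        ep_losses <- c(ep_losses, step$loss)
        t_step <- t_step + 1L
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (ui in seq_along(params)) {
          for (fld in names(params[[ui]])) {
            g <- step$grads[[ui]][[fld]]
            adam_m[[ui]][[fld]] <- b1 * adam_m[[ui]][[fld]] + (1 - b1) * g
            adam_v[[ui]][[fld]] <- b2 * adam_v[[ui]][[fld]] + (1 - b2) * g^2
            params[[ui]][[fld]] <- params[[ui]][[fld]] -
              lr * (adam_m[[ui]][[fld]] / corr1) /
              (sqrt(adam_v[[ui]][[fld]] / corr2) + adam_eps)
          }
        }
      }
      val_loss <- NA_real_
      if (!is.null(val_samples)) {
        val_loss <- mean(vapply(val_samples, eval_loss, numeric(1)))
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss; best_params <- params; stale <- 0L
        } else stale <- stale + 1L
      }
      history[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                                  val_loss = val_loss)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %s", ep, mean(ep_losses),
                        ifelse(is.na(val_loss), "-", sprintf("%.4f",
                                                             val_loss))))
      if (!is.null(val_samples) && stale >= patience) break
    }
  })
  if (!is.null(val_samples)) params <- best_params
  out <- structure(list(config = net$config, params = params),
                   class = "rild_net")
  attr(out, "history") <- do.call(rbind, history)
  out
}

#' Train every member of an ensemble
#'
#' @param configs list of `net_config` (e.g. [ensemble_config()]).
#' @param samples,weights,epochs,lr,val_samples,patience,verbose passed to
#'   [train_net()].
#' @param seed base training seed; member i trains with `seed + 100 * i`.
#' @return List of trained `rild_net`s.
#' @export
train_ensemble <- function(configs, samples, weights = rep(1, 5),
                           epochs = 10L, lr = 1e-3, val_samples = NULL,
                           patience = 3L, seed = 1L, verbose = FALSE) {
  lapply(seq_along(configs), function(i) {
    train_net(build_net(configs[[i]]), samples, epochs = epochs, lr = lr,
              weights = weights, val_samples = val_samples,
              patience = patience, seed = seed + 100L * i,
              verbose = verbose)
  })
}

#' Logit-sum ensemble prediction for one slice
#'
#' Sums the members' pre-softmax scores channel-wise and only then takes the
#' per-voxel argmax; voxels outside the lung get the `OUTSIDE` sentinel. No
#' other postprocessing is applied.
#'
#' @param nets nonempty list of `rild_net`s sharing the input geometry.
#' @param sample one element of [make_samples()].
#' @param lung optional lung mask matrix on the network grid; defaults to
#'   `sample$lung`.
#' @return Integer label matrix on the network grid.
#' @export
ensemble_predict <- function(nets, sample, lung = NULL) {
  if (length(nets) == 0) stop("empty ensemble", call. = FALSE)
  if (is.null(lung)) lung <- sample$lung
  scores <- lapply(nets, predict_scores, sample = sample)
  fuse_scores(scores, lung)
}

# the fusion rule itself: channel-wise logit sum, then per-voxel argmax,
# then the lung mask
fuse_scores <- function(scores, lung) {
  total <- Reduce(`+`, scores)
  d <- dim(total)
  lab <- max.col(matrix(total, d[1] * d[2], d[3]), ties.method = "first")
  lab <- matrix(as.integer(lab), d[1], d[2])
  lab[lung == 0L] <- OUTSIDE
  lab
}

#' Predict a whole case on its original grid
#'
#' Runs the ensemble on every lung-containing slice (the pathology slice
#' filter applies to training only), maps each prediction back through the
#' crop geometry, and assembles a label map aligned to the case: every lung
#' voxel receives a class in 1..5, everything else `OUTSIDE`.
#'
#' @param nets nonempty list of `rild_net`s.
#' @param case a `rild_case`.
#' @param plan its [slice_plan()].
#' @return A `label_map` on the case grid.
#' @export
predict_case <- function(nets, case, plan) {
  if (length(nets) == 0) stop("empty ensemble", call. = FALSE)
  stopifnot(inherits(plan, "slice_plan"))
  dims <- dim(case$mask$voxels)
  out <- array(OUTSIDE, dim = dims)
  ch <- nets[[1]]$config$in_channels
  samples <- make_samples(case, plan, slices = plan$lung_slices,
                          channels = ch)
  for (sm in samples) {
    pred <- ensemble_predict(nets, sm)
    back <- map_back(pred, plan$crop)
    # lung voxels whose network pixel fell outside the mask (nearest-
    # neighbour edge effects at s < 1) still need a class: argmax unmasked
    if (any(back[case$mask$voxels[sm$slice, , ] == 1L] == OUTSIDE)) {
      unmasked <- ensemble_predict(nets, sm, lung = matrix(1L,
                                                           dim(pred)[1],
                                                           dim(pred)[2]))
      back_u <- map_back(unmasked, plan$crop)
      fillv <- back == OUTSIDE & case$mask$voxels[sm$slice, , ] == 1L
      back[fillv] <- back_u[fillv]
    }
    out[sm$slice, , ] <- back
  }
  out[case$mask$voxels == 0L] <- OUTSIDE
  label_map(out, case$labels$spacing)
}
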