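# Quantitative evaluation. The headline metric is the pooled "global" Dice:
# true/false positives and false negatives are pooled over every lung voxel
# of every scan in a set before the ratio is taken, giving one score per
# class instead of a per-scan mean. This keeps scans where a rare class has
# only a handful of voxels from distorting the summary.

pair_lung_labels <- function(pred, truth, mask) {
  check_aligned(pred, truth, "prediction", "ground truth")
  check_aligned(pred, mask, "prediction", "mask")
  inside <- mask$voxels == 1L
  list(pred = pred$voxels[inside], truth = truth$voxels[inside])
}

#' Pooled (global) Dice per class
#'
#' `DSC_c = 2 TP_c / (2 TP_c + FP_c + FN_c)` with the counts pooled over all
#' lung voxels of all scans in the set. A class absent from both predictions
#' and ground truth across the whole set is reported as `NA` (undefined),
#' deliberately distinct from 0.
#'
#' @param predictions,truths lists of aligned `label_map`s (same length).
#' @param masks list of aligned `lung_mask`s.
#' @param classes classes to report; default all five.
#' @return Named numeric vector of Dice values in `[0, 1]` (or `NA`).
#' @export
global_dice <- function(predictions, truths, masks, classes = RILD_CLASSES) {
  stopifnot(length(predictions) == length(truths),
            length(predictions) == length(masks),
            length(predictions) >= 1)
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(predictions)) {
    v <- pair_lung_labels(predictions[[i]], truths[[i]], masks[[i]])
    for (k in seq_along(classes)) {
      cls <- classes[k]
      tp[k] <- tp[k] + sum(v$pred == cls & v$truth == cls)
      fp[k] <- fp[k] + sum(v$pred == cls & v$truth != cls)
      fn[k] <- fn[k] + sum(v$pred != cls & v$truth == cls)
    }
  }
  denom <- 2 * tp + fp + fn
  ifelse(denom > 0, 2 * tp / denom, NA_real_)
}

#' Pooled confusion matrix over lung voxels
#'
#' Entry `(i, j)` counts lung voxels with true class `i` predicted as class
#' `j`, pooled over the scan set; the row-normalised variant divides each
#' nonempty row by its sum.
#'
#' @inheritParams global_dice
#' @param normalise return row-normalised proportions instead of counts.
#' @return 5 x 5 matrix (rows = truth, cols = prediction).
#' @export
confusion_matrix <- function(predictions, truths, masks, normalise = FALSE) {
  if (inherits(predictions, "label_map")) predictions <- list(predictions)
  if (inherits(truths, "label_map")) truths <- list(truths)
  if (inherits(masks, "lung_mask")) masks <- list(masks)
  M <- matrix(0, 5, 5, dimnames = list(truth = RILD_CLASSES,
                                       prediction = RILD_CLASSES))
  for (i in seq_along(predictions)) {
    v <- pair_lung_labels(predictions[[i]], truths[[i]], masks[[i]])
    M <- M + table(factor(v$truth, levels = RILD_CLASSES),
                   factor(v$pred, levels = RILD_CLASSES))
  }
  M <- unclass(M)
  if (normalise) {
    rs <- rowSums(M)
    M <- sweep(M, 1, ifelse(rs > 0, rs, 1), "/")
  }
  M
}

#' Recompute per-class Dice from a confusion matrix
#'
#' `2 M_cc / (2 M_cc + sum_off_row + sum_off_col)`; equals [global_dice()]
#' on the same scan set.
#'
#' @param M 5 x 5 confusion matrix of counts.
#' @export
dice_from_confusion <- function(M) {
  vapply(seq_len(nrow(M)), function(cls) {
    denom <- 2 * M[cls, cls] + sum(M[cls, -cls]) + sum(M[-cls, cls])
    if (denom > 0) 2 * M[cls, cls] / denom else NA_real_
  }, numeric(1))
}

#' Evaluate an ensemble on a set of cases
#'
#' @param nets list of trained `rild_net`s.
#' @param cases list of `rild_case`.
#' @param target,tau slice-plan parameters (must match training).
#' @return An `eval_report`: per-class global Dice, voxel counts, confusion
#'   matrices (counts and row-normalised) and the scan-set size.
#' @export
evaluate_cases <- function(nets, cases, target = c(288L, 384L), tau = 0.01) {
  stopifnot(length(cases) >= 1)
  preds <- lapply(cases, function(cs)
    predict_case(nets, cs, slice_plan(cs, target = target, tau = tau)))
  truths <- lapply(cases, `[[`, "labels")
  masks <- lapply(cases, `[[`, "mask")
  M <- confusion_matrix(preds, truths, masks)
  structure(list(
    dice = global_dice(preds, truths, masks),
    voxels = rowSums(M),
    confusion = M,
    confusion_normalised = sweep(M, 1, pmax(rowSums(M), 1), "/"),
    n_scans = length(cases)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d scan(s); global Dice per class:\n",
              x$n_scans))
  print(round(x$dice, 4))
  invisible(x)
}

#' Patient-level K-fold cross-validation
#'
#' Splits patients into K folds, trains the ensemble on K-1 folds and
#' evaluates pooled global Dice on the held-out fold; summarises per class
#' with mean, sd and the normal-approximation 95% interval
#' `mean +/- 1.96 sd / sqrt(K)` over the folds where the class is defined
#' (a class absent from a fold is excluded from that fold's summary, with a
#' warning).
#'
#' @param cases list of `rild_case` (>= K patients).
#' @param configs ensemble member configurations.
#' @param k number of folds.
#' @param seed split + training seed.
#' @param target,tau slice-plan parameters.
#' @param epochs,lr,weights training parameters (see [train_net()]).
#' @return List with `folds` (per-fold `eval_report` plus patient lists) and
#'   `summary` (per-class data.frame: mean, sd, ci95lo, ci95hi, n_folds).
#' @export
crossval_run <- function(cases, configs, k = 5L, seed = 1L,
                         target = c(288L, 384L), tau = 0.01,
                         epochs = 10L, lr = 1e-3, weights = rep(1, 5)) {
  patients <- unique(vapply(cases, `[[`, character(1), "patient"))
  split <- split_patients(patients, k = k, seed = seed)
  folds <- vector("list", k)
  for (fold in seq_len(k)) {
    val_pat <- names(split)[split == fold]
    train_cases <- Filter(function(cs) !(cs$patient %in% val_pat), cases)
    val_cases <- Filter(function(cs) cs$patient %in% val_pat, cases)
    samples <- unlist(lapply(train_cases, function(cs)
      make_samples(cs, slice_plan(cs, target = target, tau = tau))),
      recursive = FALSE)
    nets <- train_ensemble(configs, samples, weights = weights,
                           epochs = epochs, lr = lr,
                           seed = seed + 1000L * fold)
    report <- evaluate_cases(nets, val_cases, target = target, tau = tau)
    report$fold <- fold
    folds[[fold]] <- list(report = report, validation_patients = val_pat,
                          training_patients = setdiff(patients, val_pat))
  }
  dice_mat <- do.call(rbind, lapply(folds, function(f) f$report$dice))
  summarise_class <- function(cls) {
    vals <- dice_mat[, as.character(cls)]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    if (n < k)
      warning("class ", cls, " undefined in ", k - n,
              " fold(s); excluded from its summary", call. = FALSE)
    if (n == 0)
      return(data.frame(class = cls, mean = NA_real_, sd = NA_real_,
                        ci95lo = NA_real_, ci95hi = NA_real_, n_folds = 0L))
    m <- mean(vals); s <- if (n > 1) stats::sd(vals) else 0
    half <- 1.96 * s / sqrt(n)
    data.frame(class = cls, mean = m, sd = s, ci95lo = m - half,
               ci95hi = m + half, n_folds = n)
  }
  list(folds = folds,
       dice = dice_mat,
       summary = do.call(rbind, lapply(RILD_CLASSES, summarise_class)))
}

#' Voxel-wise disagreement between two segmentations
#'
#' Used by the two-stage annotation-refinement workflow to locate and grade
#' discrepancies between a manual draft and an automatic segmentation.
#'
#' @param seg_a,seg_b aligned `label_map`s.
#' @param mask aligned `lung_mask`; only lung voxels are compared.
#' @return List: `mask` (binary disagreement array), `fraction` of lung
#'   voxels disagreeing, and `histogram` of `|class_a - class_b|` among
#'   disagreements.
#' @export
disagreement_map <- function(seg_a, seg_b, mask) {
  check_aligned(seg_a, seg_b, "segmentation A", "segmentation B")
  check_aligned(seg_a, mask, "segmentation A", "mask")
  inside <- mask$voxels == 1L
  diff <- (seg_a$voxels != seg_b$voxels) & inside
  delta <- abs(seg_a$voxels[diff] - seg_b$voxels[diff])
  list(mask = array(as.integer(diff), dim = dim(diff)),
       fraction = sum(diff) / sum(inside),
       histogram = if (length(delta) > 0) table(delta) else
         table(integer(0)))
}

#' Summarise refinement choices
#'
#' For each subset, the fraction of scans whose manual (vs automatic)
#' segmentation was chosen as the closer draft for refinement.
#'
#' @param records data.frame with columns `scan_id`, `choice` (`"manual"` /
#'   `"automatic"`) and `subset`.
#' @return data.frame: subset, manual, automatic (fractions summing to 1).
#' @export
refinement_report <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(records$choice %in% c("manual", "automatic")))
  out <- do.call(rbind, lapply(split(records, records$subset), function(d) {
    data.frame(subset = d$subset[1],
               manual = mean(d$choice == "manual"),
               automatic = mean(d$choice == "automatic"))
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate ordinal qualitative scores
#'
#' Scores are per scan and class on the 3-point scale 1 acceptable, 2 minor
#' disagreement, 3 major disagreement. Returns per class the percentage of
#' scans at each score, plus an average row (mean over classes).
#'
#' @param scores complete scans x classes matrix (or data.frame) of scores
#'   in `{1, 2, 3}`; columns are the five classes.
#' @return data.frame with rows Class 1..5 and AVG, columns score1, score2,
#'   score3 (percentages summing to 100 per row).
#' @export
qualitative_summary <- function(scores) {
  m <- as.matrix(scores)
  if (ncol(m) != 5L) stop("scores must have five class columns",
                          call. = FALSE)
  if (any(is.na(m))) stop("score grid has missing cells", call. = FALSE)
  if (!all(m %in% 1:3)) stop("scores must be 1, 2 or 3", call. = FALSE)
  per_class <- t(vapply(seq_len(5), function(cls) {
    100 * vapply(1:3, function(s) mean(m[, cls] == s), numeric(1))
  }, numeric(3)))
  out <- rbind(per_class, colMeans(per_class))
  dimnames(out) <- list(c(paste("Class", 1:5), "AVG"),
                        c("score1", "score2", "score3"))
  as.data.frame(out)
}
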