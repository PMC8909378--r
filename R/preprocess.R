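# From 3D cases to network-ready 2D samples.
#
# The method is axial-slice-wise: slices are cropped to the lung bounding
# box, fitted to a fixed rectangular input (default 288 x 384) at original
# resolution where possible, and downscaled by a single isotropic factor
# only when the box does not fit. Training uses only slices where at least
# 1% of lung tissue carries pathology (classes 2-5); inference runs on every
# lung-containing slice.

#' Mask anatomy outside the lungs
#'
#' Voxels outside the lung mask are replaced by a fixed fill value (air,
#' -1000 HU, by default); lung voxels are untouched.
#'
#' @param volume a `ct_volume`.
#' @param mask an aligned `lung_mask`; must be nonempty.
#' @param fill replacement HU value.
#' @return A `ct_volume` with non-lung anatomy blanked.
#' @export
mask_lungs <- function(volume, mask, fill = -1000) {
  check_aligned(volume, mask, "volume", "mask")
  if (sum(mask$voxels) == 0)
    stop("lung mask is empty", call. = FALSE)
  v <- volume$voxels
  v[mask$voxels == 0L] <- fill
  ct_volume(v, volume$spacing, volume$origin)
}

#' Compute the crop-and-fit geometry for a case
#'
#' Takes the axial (row, column) bounding box of the lung mask, pooled over
#' all slices. If the box fits inside the target it is padded symmetrically
#' at original resolution (scale 1); otherwise one isotropic,
#' aspect-preserving scale `s = min(target / bbox) < 1` shrinks it to fit,
#' the minimum downscaling that does.
#'
#' @param mask a `lung_mask`; must be nonempty.
#' @param target `(rows, cols)` of the network input; default `c(288, 384)`.
#' @return A `crop_geometry` list: `bbox` (y0, y1, x0, x1, 1-based
#'   inclusive), `scale`, `pad` (top, left), `scaled` (rows, cols of the
#'   scaled box), `target`, `source_shape`.
#' @export
compute_crop <- function(mask, target = c(288L, 384L)) {
  m <- mask$voxels
  if (sum(m) == 0) stop("lung mask is empty", call. = FALSE)
  any_y <- apply(m, 2, sum) > 0
  any_x <- apply(m, 3, sum) > 0
  y0 <- which(any_y)[1]; y1 <- max(which(any_y))
  x0 <- which(any_x)[1]; x1 <- max(which(any_x))
  bh <- y1 - y0 + 1L; bw <- x1 - x0 + 1L
  s <- min(1, target[1] / bh, target[2] / bw)
  if (s == 1) {
    scaled <- c(bh, bw)
  } else {
    scaled <- c(min(floor(bh * s + 1e-9), target[1]),
                min(floor(bw * s + 1e-9), target[2]))
  }
  pad <- c(floor((target[1] - scaled[1]) / 2),
           floor((target[2] - scaled[2]) / 2))
  structure(list(bbox = c(y0 = y0, y1 = y1, x0 = x0, x1 = x1),
                 scale = s, pad = pad, scaled = scaled,
                 target = as.integer(target),
                 source_shape = dim(m)[2:3]),
            class = "crop_geometry")
}

#' Pathology-driven slice filter
#'
#' For each axial slice, the pathology fraction is the share of lung voxels
#' carrying classes 2-5. Slices are retained iff the fraction is at least
#' `tau` (ties at exactly `tau` retained); slices without lung voxels are
#' never retained.
#'
#' @param labels a `label_map`.
#' @param mask an aligned `lung_mask`.
#' @param tau retention threshold in `[0, 1]`; default 0.01.
#' @return List with `fraction` and `lung_voxels` per slice and the
#'   `retained` slice indices (1-based).
#' @export
filter_slices <- function(labels, mask, tau = 0.01) {
  if (tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]", call. = FALSE)
  check_aligned(labels, mask, "labels", "mask")
  nz <- dim(mask$voxels)[1]
  lung <- vapply(seq_len(nz),
                 function(z) sum(mask$voxels[z, , ]), numeric(1))
  path <- vapply(seq_len(nz), function(z) {
    sum(labels$voxels[z, , ] >= 2L & mask$voxels[z, , ] == 1L)
  }, numeric(1))
  frac <- ifelse(lung > 0, path / lung, 0)
  retained <- which(lung > 0 & frac >= tau)
  list(fraction = frac, lung_voxels = lung, retained = retained)
}

#' Build the slice plan for a case
#'
#' Bundles the crop geometry with the slice filter: the training-set
#' construction record for one volume.
#'
#' @param case a `rild_case`.
#' @param target network input `(rows, cols)`.
#' @param tau slice-filter threshold.
#' @return A `slice_plan` list: `crop`, `fraction`, `retained` (filtered
#'   training slices), `lung_slices` (all slices containing lung, used at
#'   inference), `tau`.
#' @export
slice_plan <- function(case, target = c(288L, 384L), tau = 0.01) {
  crop <- compute_crop(case$mask, target)
  filt <- filter_slices(case$labels, case$mask, tau)
  structure(list(crop = crop, fraction = filt$fraction,
                 retained = filt$retained,
                 lung_slices = which(filt$lung_voxels > 0),
                 tau = tau),
            class = "slice_plan")
}

# bilinear resize of a bbox crop onto the scaled target region
resize_bilinear <- function(img, out_shape) {
  sh <- dim(img); oh <- out_shape[1]; ow <- out_shape[2]
  if (all(sh == out_shape)) return(img)
  ys <- (seq_len(oh) - 0.5) * sh[1] / oh - 0.5
  xs <- (seq_len(ow) - 0.5) * sh[2] / ow - 0.5
  y0 <- pmin(pmax(floor(ys), 0), sh[1] - 1); y1 <- pmin(y0 + 1, sh[1] - 1)
  x0 <- pmin(pmax(floor(xs), 0), sh[2] - 1); x1 <- pmin(x0 + 1, sh[2] - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0 + 1, x0 + 1, drop = FALSE]; b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]; d <- img[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * (1 - rep(wx, each = oh)) + b * rep(wx, each = oh)
  bot <- c_ * (1 - rep(wx, each = oh)) + d * rep(wx, each = oh)
  top * (1 - wy) + bot * wy
}

resize_nearest <- function(img, out_shape) {
  sh <- dim(img)
  if (all(sh == out_shape)) return(img)
  ys <- pmin(pmax(ceiling((seq_len(out_shape[1]) - 0.5) * sh[1] /
                            out_shape[1]), 1), sh[1])
  xs <- pmin(pmax(ceiling((seq_len(out_shape[2]) - 0.5) * sh[2] /
                            out_shape[2]), 1), sh[2])
  img[ys, xs, drop = FALSE]
}

# place a scaled crop into the padded target canvas
place_in_target <- function(img, crop, fill) {
  out <- matrix(fill, crop$target[1], crop$target[2])
  out[crop$pad[1] + seq_len(crop$scaled[1]),
      crop$pad[2] + seq_len(crop$scaled[2])] <- img
  out
}

window_normalise <- function(hu, window = c(-1000, 100)) {
  pmin(pmax((hu - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Extract network-ready 2D samples from a case
#'
#' Each selected axial slice is lung-masked, cropped, scaled (bilinear for
#' intensities, nearest-neighbour for labels and mask), padded to the target
#' shape, and intensity-normalised by a fixed HU window onto `[0, 1]`.
#'
#' @param case a `rild_case`.
#' @param plan its [slice_plan()].
#' @param slices slice indices to extract; defaults to the plan's retained
#'   (training) slices. Use `plan$lung_slices` for inference.
#' @param window HU normalisation window, default `c(-1000, 100)`.
#' @param fill masked-region fill value in HU before windowing.
#' @param channels odd number of adjacent-slice input channels (default 1;
#'   3 stacks the slices above and below, clamped at volume edges).
#' @return List of samples: `image` (target matrix, or array with
#'   `channels` > 1), `labels`, `lung` (target-sized integer matrices),
#'   `case_id`, `slice`.
#' @export
make_samples <- function(case, plan, slices = NULL,
                         window = c(-1000, 100), fill = -1000,
                         channels = 1L) {
  stopifnot(inherits(plan, "slice_plan"))
  if (channels %% 2L != 1L)
    stop("channels must be odd (centre slice plus symmetric neighbours)",
         call. = FALSE)
  if (is.null(slices)) slices <- plan$retained
  crop <- plan$crop
  if (!identical(unname(crop$source_shape), unname(dim(case$mask$voxels)[2:3])))
    stop("slice plan geometry does not match the case grid", call. = FALSE)
  masked <- mask_lungs(case$volume, case$mask, fill = fill)
  bb <- crop$bbox
  nz <- dim(case$mask$voxels)[1]
  half <- (channels - 1L) %/% 2L
  cid <- sprintf("%s_T%s", case$patient, case$timepoint)

  one_channel <- function(z) {
    sl <- masked$voxels[z, bb["y0"]:bb["y1"], bb["x0"]:bb["x1"]]
    sl <- resize_bilinear(sl, crop$scaled)
    window_normalise(place_in_target(sl, crop, fill), window)
  }
  lapply(slices, function(z) {
    img <- if (channels == 1L) one_channel(z) else {
      zs <- pmin(pmax(z + (-half):half, 1L), nz)
      arr <- array(0, dim = c(crop$target, channels))
      for (k in seq_along(zs)) arr[, , k] <- one_channel(zs[k])
      arr
    }
    lab <- case$labels$voxels[z, bb["y0"]:bb["y1"], bb["x0"]:bb["x1"]]
    lab <- resize_nearest(lab, crop$scaled)
    lng <- case$mask$voxels[z, bb["y0"]:bb["y1"], bb["x0"]:bb["x1"]]
    lng <- resize_nearest(lng, crop$scaled)
    list(image = img,
         labels = place_in_target(lab, crop, OUTSIDE),
         lung = place_in_target(lng, crop, 0L),
         case_id = cid, slice = z)
  })
}

#' Map a network-grid label slice back onto the source grid
#'
#' Inverts the crop-and-fit geometry: every source voxel inside the bounding
#' box reads the target pixel it was mapped to, so each receives exactly one
#' label; at scale 1 this is the exact inverse translation. Voxels outside
#' the bounding box get `OUTSIDE`.
#'
#' @param pred label matrix on the network grid (`crop$target`).
#' @param crop a `crop_geometry`.
#' @return Label matrix on the source slice grid.
#' @export
map_back <- function(pred, crop) {
  stopifnot(inherits(crop, "crop_geometry"))
  if (!identical(dim(pred), as.integer(crop$target)))
    stop("prediction shape does not match the crop target", call. = FALSE)
  out <- matrix(OUTSIDE, crop$source_shape[1], crop$source_shape[2])
  bb <- crop$bbox
  ys <- bb["y0"]:bb["y1"]; xs <- bb["x0"]:bb["x1"]
  ty <- pmin(crop$pad[1] + floor((ys - bb["y0"]) * crop$scale) + 1,
             crop$pad[1] + crop$scaled[1])
  tx <- pmin(crop$pad[2] + floor((xs - bb["x0"]) * crop$scale) + 1,
             crop$pad[2] + crop$scaled[2])
  out[ys, xs] <- pred[ty, tx]
  out
}

#' Pooled class frequencies over a cohort
#'
#' Counts lung voxels per class, pooled over the named slice set of every
#' case. The `"filtered"` set keeps only slices passing the pathology
#' filter, which is what rebalances training (the all-slices pooled class-1
#' share of ~94% drops to ~85% after filtering in the regime the phantom
#' emulates).
#'
#' @param cases list of `rild_case`.
#' @param slice_set `"all"` (every lung-containing slice) or `"filtered"`.
#' @param tau filter threshold used when `slice_set = "filtered"`.
#' @return A `class_frequencies` data.frame: class, voxels, fraction.
#' @export
class_frequencies <- function(cases, slice_set = c("all", "filtered"),
                              tau = 0.01) {
  slice_set <- match.arg(slice_set)
  stopifnot(length(cases) >= 1)
  counts <- stats::setNames(numeric(5), RILD_CLASSES)
  for (cs in cases) {
    filt <- filter_slices(cs$labels, cs$mask, tau)
    zs <- if (slice_set == "all") which(filt$lung_voxels > 0) else
      filt$retained
    for (z in zs) {
      lab <- cs$labels$voxels[z, , ][cs$mask$voxels[z, , ] == 1L]
      tab <- tabulate(lab, nbins = 5)
      counts <- counts + tab
    }
  }
  if (sum(counts) == 0)
    stop("slice set '", slice_set, "' is empty for this cohort",
         call. = FALSE)
  out <- data.frame(class = RILD_CLASSES, voxels = as.numeric(counts),
                    fraction = as.numeric(counts) / sum(counts))
  class(out) <- c("class_frequencies", "data.frame")
  out
}

#' Patient-level K-fold split
#'
#' Assigns each patient to exactly one fold (sizes differ by at most one);
#' all timepoints of a patient therefore share a fold, preventing
#' information leakage between training and validation.
#'
#' @param patients character vector of patient ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the split is deterministic given it.
#' @return Named integer vector mapping patient id to fold in `1..k`.
#' @export
split_patients <- function(patients, k = 5L, seed = 1L) {
  patients <- unique(patients)
  if (k > length(patients))
    stop("more folds than patients", call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(patients)
    folds <- rep(seq_len(k), length.out = length(shuffled))
    stats::setNames(folds, shuffled)[patients]
  })
}

#' Fixed development/test split
#'
#' Holds out a fixed number of patients as a test set (the 40-development /
#' 6-test pattern), all their timepoints with them.
#'
#' @param patients character vector of patient ids.
#' @param n_test number of held-out patients.
#' @param seed RNG seed.
#' @return List with `dev` and `test` patient-id vectors.
#' @export
fixed_split <- function(patients, n_test, seed = 1L) {
  patients <- unique(patients)
  if (n_test < 1 || n_test >= length(patients))
    stop("n_test must leave at least one development patient", call. = FALSE)
  with_seed(seed, {
    test <- sort(sample(patients, n_test))
    list(dev = setdiff(patients, test), test = test)
  })
}
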