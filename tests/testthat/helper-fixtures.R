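# Shared fixtures and independent brute-force oracles. Everything is built
# in code at test time; oracles deliberately use plain voxel loops, not the
# package's vectorised implementations.

tiny_spec <- function(n_patients = 2L, timepoints = 2L, seed = 7L, ...) {
  phantom_spec(n_patients = n_patients,
               timepoints_per_patient = timepoints,
               grid_shape = c(16L, 32L, 48L), seed = seed, ...)
}

unit_grid <- function(arr) array(arr, dim = dim(arr))

# label/mask/volume triple from raw arrays, unit spacing
toy_case <- function(labels, mask = NULL, hu = NULL) {
  if (is.null(mask)) mask <- (labels != 0L) * 1L
  if (is.null(hu)) hu <- array(-500, dim = dim(labels))
  rild_case(ct_volume(unit_grid(hu), c(1, 1, 1)),
            lung_mask(unit_grid(mask), c(1, 1, 1)),
            label_map(unit_grid(labels), c(1, 1, 1)))
}

random_map_pair <- function(dims = c(3L, 6L, 7L), p_lung = 0.7,
                            seed = 1L) {
  set.seed(seed)
  mask <- array(rbinom(prod(dims), 1, p_lung), dim = dims)
  mk <- function() {
    lab <- array(0L, dim = dims)
    lab[mask == 1] <- sample(1:5, sum(mask), replace = TRUE)
    label_map(lab, c(1, 1, 1))
  }
  list(a = mk(), b = mk(), mask = lung_mask(mask, c(1, 1, 1)))
}

# brute-force per-class Dice by explicit voxel loop, pooled over scans
bf_global_dice <- function(preds, truths, masks, cls) {
  tp <- fp <- fn <- 0
  for (i in seq_along(preds)) {
    p <- preds[[i]]$voxels; t <- truths[[i]]$voxels
    m <- masks[[i]]$voxels
    for (v in seq_along(p)) {
      if (m[v] != 1) next
      if (p[v] == cls && t[v] == cls) tp <- tp + 1
      else if (p[v] == cls) fp <- fp + 1
      else if (t[v] == cls) fn <- fn + 1
    }
  }
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

bf_confusion <- function(preds, truths, masks) {
  M <- matrix(0, 5, 5)
  for (i in seq_along(preds)) {
    p <- preds[[i]]$voxels; t <- truths[[i]]$voxels
    m <- masks[[i]]$voxels
    for (v in seq_along(p)) {
      if (m[v] == 1) M[t[v], p[v]] <- M[t[v], p[v]] + 1
    }
  }
  M
}

# brute-force slice filter: explicit per-slice counting
bf_retained_slices <- function(labels, mask, tau = 0.01) {
  nz <- dim(labels$voxels)[1]
  keep <- integer(0)
  for (z in seq_len(nz)) {
    lung <- 0; path <- 0
    for (y in seq_len(dim(labels$voxels)[2]))
      for (x in seq_len(dim(labels$voxels)[3])) {
        if (mask$voxels[z, y, x] == 1) {
          lung <- lung + 1
          if (labels$voxels[z, y, x] >= 2) path <- path + 1
        }
      }
    if (lung > 0 && path / lung >= tau) keep <- c(keep, z)
  }
  keep
}

# hard-label IoU by direct set counting
bf_iou <- function(pred, target, cls) {
  inter <- sum(pred == cls & target == cls)
  uni <- sum(pred == cls | target == cls)
  if (uni == 0) return(NA_real_)
  inter / uni
}

# central finite differences of f at x
fd_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + h
    x2 <- x; x2[i] <- x2[i] - h
    g[i] <- (f(x1) - f(x2)) / (2 * h)
  }
  g
}

# one network-grid sample with all five classes, for segnet tests
demo_sample <- function(seed = 5L, target = c(32L, 48L), slice = NULL) {
  spec <- phantom_spec(n_patients = 1L, seed = seed)
  cs <- generate_case(spec, 1, 4)
  plan <- slice_plan(cs, target = target)
  idx <- if (is.null(slice)) ceiling(length(plan$retained) / 2) else slice
  make_samples(cs, plan, slices = plan$retained[idx])[[1]]
}
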