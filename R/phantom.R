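# Synthetic longitudinal lung-CT phantom.
#
# Each case embeds two ellipsoidal lungs in a soft-tissue body on an air
# background. Inside the lungs a smooth random "damage" field, biased towards
# a per-patient focal region in one lung (radiation fields are local), is
# thresholded by quantiles so the realised class-volume fractions hit the
# configured targets; denser classes occupy the damage core. Per-class HU is
# mean + spread x a spatially correlated unit-variance noise field, with a
# high-frequency line texture added for the reticulation class.

#' Per-class Hounsfield density model of the phantom
#'
#' The five classes form a density ladder from aerated lung to consolidation.
#' Means strictly increase with class id; these are generator parameters,
#' not measurements.
#'
#' @param class_id integer in 1..5.
#' @return List with `mean_hu`, `spread_hu` and a `texture` descriptor
#'   (`"smooth"` for all classes except the reticulation class 3, which is
#'   `"reticulated"`).
#' @export
class_hu_profile <- function(class_id) {
  if (length(class_id) != 1L || !class_id %in% RILD_CLASSES)
    stop("class_id must be a single integer in 1..5", call. = FALSE)
  means <- c(-800, -550, -450, -200, 40)
  spreads <- c(60, 60, 60, 60, 50)
  list(class_id = as.integer(class_id),
       mean_hu = means[class_id],
       spread_hu = spreads[class_id],
       texture = if (class_id == 3L) "reticulated" else "smooth")
}

#' Specify a phantom cohort
#'
#' Defaults mirror the study regime the pipeline is built for: five time
#' points per patient (baseline plus follow-ups), heterogeneous voxel
#' spacing (axial 0.57-1.40 mm, slice thickness 0.7-5 mm) and severe class
#' imbalance (about 94% of lung volume is normal tissue).
#'
#' @param n_patients number of patients.
#' @param timepoints_per_patient scans per patient (default 5).
#' @param grid_shape voxel grid, (z, y, x); axial slices are `grid_shape[2]`
#'   rows by `grid_shape[3]` columns.
#' @param spacing_range_axial in-plane spacing range, mm.
#' @param spacing_range_z slice-thickness range, mm.
#' @param class_volume_targets length-5 non-negative vector summing to 1:
#'   cohort-average lung-volume fraction per class.
#' @param smooth_sigma spatial correlation length of the noise fields, voxels.
#' @param seed integer; fully determines every emitted case.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_patients,
                         timepoints_per_patient = 5L,
                         grid_shape = c(48L, 64L, 96L),
                         spacing_range_axial = c(0.57, 1.40),
                         spacing_range_z = c(0.7, 5.0),
                         class_volume_targets = c(0.937, 0.035, 0.003,
                                                  0.005, 0.020),
                         smooth_sigma = 1.5,
                         seed = 1L) {
  stopifnot(n_patients >= 1, timepoints_per_patient >= 1,
            length(grid_shape) == 3L)
  tw <- class_volume_targets
  if (length(tw) != 5L || any(tw < 0) || abs(sum(tw) - 1) > 1e-8)
    stop("class_volume_targets must be 5 non-negative fractions summing to 1",
         call. = FALSE)
  for (r in list(spacing_range_axial, spacing_range_z)) {
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
      stop("spacing ranges must be positive, finite, increasing intervals",
           call. = FALSE)
  }
  # lesion volume multiplier per timepoint: linear growth, mean 1 across the
  # cohort so pooled class fractions match the targets
  tp <- timepoints_per_patient
  growth <- 2 * seq_len(tp) / (tp + 1)
  lesion_base <- 1 - tw[1]
  if (max(growth) * lesion_base > 0.95)
    stop("infeasible class_volume_targets: lesion fraction at the last ",
         "timepoint would exceed the lung volume", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    timepoints_per_patient = as.integer(tp),
    grid_shape = as.integer(grid_shape),
    spacing_range_axial = as.numeric(spacing_range_axial),
    spacing_range_z = as.numeric(spacing_range_z),
    class_volume_targets = as.numeric(tw),
    growth = growth,
    smooth_sigma = smooth_sigma,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# deterministic per-case RNG stream; kept below 2^31
case_seed <- function(spec, patient, timepoint) {
  as.integer((as.numeric(spec$seed) * 2654435 + patient * 97561 +
                timepoint * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# separable Gaussian smoothing along each array axis via banded matrices
gauss_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= ceiling(3 * sigma), exp(-d^2 / (2 * sigma^2)), 0)
    })
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dims <- dim(ap)
    m <- K %*% matrix(ap, nrow = n)
    ap <- array(m, dim = dims)
    aperm(ap, order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

# unit-variance spatially correlated Gaussian field
correlated_field <- function(dims, sigma) {
  f <- gauss_smooth_3d(array(stats::rnorm(prod(dims)), dim = dims), sigma)
  (f - mean(f)) / stats::sd(f)
}

ellipsoid_mask <- function(dims, center, semi) {
  z <- (seq_len(dims[1]) - center[1]) / semi[1]
  y <- (seq_len(dims[2]) - center[2]) / semi[2]
  x <- (seq_len(dims[3]) - center[3]) / semi[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()].
#' @param patient patient index, 1-based.
#' @param timepoint timepoint index, 1-based (1 = baseline analogue); lesion
#'   volume grows with it.
#' @param seed optional RNG seed override; by default derived
#'   deterministically from the spec seed and the (patient, timepoint) pair.
#' @return A `rild_case` (volume + lung mask + label map).
#' @export
generate_case <- function(spec, patient, timepoint, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (timepoint < 1 || timepoint > spec$timepoints_per_patient)
    stop("timepoint out of range for this spec", call. = FALSE)
  if (is.null(seed)) seed <- case_seed(spec, patient, timepoint)
  with_seed(seed, {
    dims <- spec$grid_shape
    nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
    lung_semi <- c(0.38 * nz, 0.30 * ny, 0.17 * nx)
    if (any(lung_semi < 2))
      stop("grid too small to contain the lung fields", call. = FALSE)

    spacing <- c(stats::runif(1, spec$spacing_range_z[1],
                              spec$spacing_range_z[2]),
                 rep(stats::runif(1, spec$spacing_range_axial[1],
                                  spec$spacing_range_axial[2]), 2))

    body <- ellipsoid_mask(dims, c(nz / 2, ny / 2, nx / 2),
                           c(0.49 * nz, 0.46 * ny, 0.47 * nx))
    lungL <- ellipsoid_mask(dims, c(nz / 2, 0.50 * ny, 0.30 * nx), lung_semi)
    lungR <- ellipsoid_mask(dims, c(nz / 2, 0.50 * ny, 0.70 * nx), lung_semi)
    lungs <- (lungL | lungR) & body
    if (sum(lungs) < 100)
      stop("grid too small to contain the lung fields", call. = FALSE)

    # damage field: smooth noise + focal bias in the treated lung
    treated_left <- (patient %% 2L) == 1L
    fx <- if (treated_left) 0.30 * nx else 0.70 * nx
    focus <- c(stats::runif(1, 0.35, 0.65) * nz,
               stats::runif(1, 0.35, 0.65) * ny,
               fx + stats::runif(1, -0.05, 0.05) * nx)
    zc <- slice_index_grid(dims)
    d2 <- ((zc$z - focus[1]) / (0.45 * nz))^2 +
      ((zc$y - focus[2]) / (0.40 * ny))^2 +
      ((zc$x - focus[3]) / (0.30 * nx))^2
    damage <- correlated_field(dims, spec$smooth_sigma * 2) + 2.2 * exp(-d2)

    # quantile thresholds: exact class counts at this timepoint's lesion load
    tw <- spec$class_volume_targets
    lesion_frac <- min((1 - tw[1]) * spec$growth[timepoint], 0.95)
    n_lung <- sum(lungs)
    shares <- if (sum(tw[2:5]) > 0) tw[2:5] / sum(tw[2:5]) else rep(0, 4)
    n_lesion <- round(lesion_frac * n_lung)
    n_per <- floor(shares * n_lesion)
    rem <- n_lesion - sum(n_per)
    if (rem > 0) { # hand leftovers to the largest shares
      ord <- order(shares, decreasing = TRUE)
      n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
    }
    labels <- array(OUTSIDE, dim = dims)
    lab_lung <- rep(1L, n_lung)
    if (n_lesion > 0) {
      ord <- order(damage[lungs], decreasing = TRUE)
      offset <- 0L
      for (cls in 5:2) { # densest class at the damage core
        k <- n_per[cls - 1L]
        if (k > 0) lab_lung[ord[offset + seq_len(k)]] <- cls
        offset <- offset + k
      }
    }
    labels[lungs] <- lab_lung

    # HU painting
    noise <- correlated_field(dims, spec$smooth_sigma)
    hu <- array(-1000, dim = dims)
    hu[body] <- 30 + 20 * noise[body]
    for (cls in RILD_CLASSES) {
      sel <- labels == cls
      if (!any(sel)) next
      p <- class_hu_profile(cls)
      hu[sel] <- p$mean_hu + p$spread_hu * noise[sel]
      if (p$texture == "reticulated") {
        # high-frequency line texture overlaid on the GGO base
        phase <- stats::runif(1, 0, 2 * pi)
        hu[sel] <- hu[sel] + 80 * sin(2 * pi * (zc$y[sel] + zc$x[sel]) / 3 +
                                        phase)
      }
    }

    rild_case(ct_volume(hu, spacing),
              lung_mask(array(as.integer(lungs), dim = dims), spacing),
              label_map(labels, spacing),
              patient = sprintf("P%03d", patient),
              timepoint = as.integer(timepoint))
  })
}

# coordinate grids in (z,y,x) array order
slice_index_grid <- function(dims) {
  list(z = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims),
       y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
                 dim = dims),
       x = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims))
}

#' Generate a phantom cohort
#'
#' Produces `n_patients x timepoints_per_patient` cases with per-volume
#' spacing drawn independently from the configured ranges, plus a manifest.
#' When `dir` is given, volumes/masks/labels are written as NIfTI and the
#' manifest as CSV alongside the spec as YAML.
#'
#' @param spec a [phantom_spec()].
#' @param dir optional output directory.
#' @return List with `cases` (list of `rild_case`) and `manifest`
#'   (data.frame: patient_id, timepoint, spacing, and file paths when
#'   written).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(dir) || file.access(dir, 2) != 0)
      stop("output location not writable: ", dir, call. = FALSE)
  }
  cases <- list()
  rows <- list()
  for (p in seq_len(spec$n_patients)) {
    for (t in seq_len(spec$timepoints_per_patient)) {
      cs <- generate_case(spec, p, t)
      id <- sprintf("%s_T%d", cs$patient, t)
      paths <- c(volume = NA_character_, mask = NA_character_,
                 labels = NA_character_)
      if (!is.null(dir)) paths <- save_case(cs, dir, prefix = id)
      cases[[id]] <- cs
      rows[[id]] <- data.frame(
        patient_id = cs$patient, timepoint = t,
        spacing_z = cs$volume$spacing[1], spacing_y = cs$volume$spacing[2],
        spacing_x = cs$volume$spacing[3],
        volume_path = paths[["volume"]], mask_path = paths[["mask"]],
        labels_path = paths[["labels"]], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    yaml::write_yaml(unclass(spec), file.path(dir, "phantom_spec.yaml"))
  }
  list(cases = cases, manifest = manifest)
}
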