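#' @useDynLib rildseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Voxel arrays are stored internally in (z, y, x) order: axial slices are
# fixed-z planes of shape (ny rows, nx cols). NIfTI files are written in the
# conventional (x, y, z) order; load/save permute accordingly.

#' Label vocabulary
#'
#' Lung tissue classes are the integers 1 to 5, ordered by increasing tissue
#' density: 1 normal lung, 2 ground-glass-opacity-like change, 3 mixed
#' ground-glass opacity with overlaid reticulation, 4 near-solid tissue,
#' 5 homogeneous dense tissue (consolidation-like). Voxels outside the lung
#' mask carry the sentinel `OUTSIDE` (0), the usual background convention in
#' segmentation label files.
#' @export
OUTSIDE <- 0L

#' @rdname OUTSIDE
#' @export
RILD_CLASSES <- 1:5

new_grid <- function(voxels, spacing, origin, class) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be positive and finite", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), orientation = "LPS"),
    class = c(class, "rild_grid")
  )
}

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of Hounsfield units, dim order (z, y, x).
#' @param spacing voxel spacing in mm, (z, y, x).
#' @param origin scanner-space position of the first voxel, mm.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (any(!is.finite(voxels)))
    stop("CT volume contains non-finite voxel values", call. = FALSE)
  new_grid(voxels, spacing, origin, "ct_volume")
}

#' Construct a binary lung mask
#'
#' @inheritParams ct_volume
#' @param voxels 3D array of 0/1 values, dim order (z, y, x).
#' @export
lung_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  v <- as.integer(voxels)
  if (!all(v %in% c(0L, 1L)))
    stop("lung mask values must be 0 or 1", call. = FALSE)
  voxels <- array(v, dim = dim(voxels))
  new_grid(voxels, spacing, origin, "lung_mask")
}

#' Construct a voxel-wise label map
#'
#' Inside-lung voxels take classes 1-5; everything else is the `OUTSIDE`
#' sentinel (0).
#'
#' @inheritParams ct_volume
#' @param voxels 3D integer array with values in `{0, 1, ..., 5}`.
#' @export
label_map <- function(voxels, spacing, origin = c(0, 0, 0)) {
  v <- as.integer(voxels)
  bad <- setdiff(unique(v), c(OUTSIDE, RILD_CLASSES))
  if (length(bad) > 0)
    stop("label map contains values outside the class vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  voxels <- array(v, dim = dim(voxels))
  new_grid(voxels, spacing, origin, "label_map")
}

#' @export
print.rild_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grids_aligned <- function(a, b, tol = 1e-3) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

check_aligned <- function(a, b, what_a = "grid", what_b = "grid", tol = 1e-3) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop(sprintf("%s and %s have different shapes (%s vs %s)",
                 what_a, what_b,
                 paste(dim(a$voxels), collapse = "x"),
                 paste(dim(b$voxels), collapse = "x")), call. = FALSE)
  if (any(abs(a$spacing - b$spacing) > tol))
    stop(sprintf("%s and %s have different voxel spacing", what_a, what_b),
         call. = FALSE)
  invisible(TRUE)
}

write_grid_nifti <- function(grid, path, datatype) {
  # internal (z,y,x) -> NIfTI (x,y,z)
  arr <- aperm(grid$voxels, c(3, 2, 1))
  sp <- rev(grid$spacing)
  img <- RNifti::asNifti(arr,
                         reference = list(pixdim = c(-1, sp, 0, 0, 0, 0)),
                         datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_grid_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume in ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)
  list(voxels = aperm(array(as.vector(img), dim = dim(img)), c(3, 2, 1)),
       spacing = rev(sp))
}

#' Load a CT case from NIfTI files
#'
#' Reads the volume, lung mask and label map of one scan and enforces grid
#' consistency: the three grids must share shape and spacing (tolerance 1e-3
#' mm) and the label file must use the `{0..5}` vocabulary. Mismatches are
#' errors, never silently repaired.
#'
#' @param volume_path,mask_path,labels_path paths to NIfTI (.nii / .nii.gz)
#'   files.
#' @return A `rild_case` list with elements `volume`, `mask`, `labels`.
#' @export
load_case <- function(volume_path, mask_path, labels_path) {
  v <- read_grid_nifti(volume_path)
  m <- read_grid_nifti(mask_path)
  l <- read_grid_nifti(labels_path)
  vol <- ct_volume(v$voxels, v$spacing)
  for (x in list(list(m, mask_path), list(l, labels_path))) {
    if (!identical(dim(x[[1]]$voxels), dim(v$voxels)))
      stop("grid shape of ", x[[2]], " does not match ", volume_path,
           call. = FALSE)
    if (any(abs(x[[1]]$spacing - v$spacing) > 1e-3))
      stop("voxel spacing of ", x[[2]], " does not match ", volume_path,
           call. = FALSE)
  }
  msk <- lung_mask(m$voxels, m$spacing)
  lab <- tryCatch(label_map(round(l$voxels), l$spacing),
                  error = function(e)
                    stop("label vocabulary error in ", labels_path, ": ",
                         conditionMessage(e), call. = FALSE))
  rild_case(vol, msk, lab)
}

#' Bundle a volume, mask and label map into one case
#'
#' @param volume a `ct_volume`.
#' @param mask a `lung_mask` on the same grid.
#' @param labels a `label_map` on the same grid.
#' @param patient,timepoint optional identifiers.
#' @export
rild_case <- function(volume, mask, labels, patient = NA_character_,
                      timepoint = NA_integer_) {
  check_aligned(volume, mask, "volume", "mask")
  check_aligned(volume, labels, "volume", "labels")
  inside <- mask$voxels == 1L
  if (any(labels$voxels[inside] == OUTSIDE))
    stop("label map has OUTSIDE sentinel inside the lung mask", call. = FALSE)
  if (any(labels$voxels[!inside] != OUTSIDE))
    stop("label map has tissue classes outside the lung mask", call. = FALSE)
  structure(list(volume = volume, mask = mask, labels = labels,
                 patient = patient, timepoint = timepoint),
            class = "rild_case")
}

#' @export
print.rild_case <- function(x, ...) {
  cat(sprintf("<rild_case> patient=%s timepoint=%s\n", x$patient, x$timepoint))
  print(x$volume)
  invisible(x)
}

#' Save a label map as NIfTI
#'
#' The label map must be aligned to the reference volume; the file inherits
#' the reference geometry. Integer labels round-trip bit-identically.
#'
#' @param labels a `label_map`.
#' @param reference a `ct_volume` defining the target geometry.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
save_labels <- function(labels, reference, path) {
  check_aligned(labels, reference, "labels", "reference")
  write_grid_nifti(labels, path, datatype = "int16")
}

#' Save a full case (volume, mask, labels) as NIfTI files
#'
#' @param case a `rild_case`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Named character vector of the three paths written.
#' @export
save_case <- function(case, dir, prefix = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    volume = file.path(dir, paste0(prefix, "_volume.nii.gz")),
    mask   = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    labels = file.path(dir, paste0(prefix, "_labels.nii.gz"))
  )
  write_grid_nifti(case$volume, paths[["volume"]], datatype = "double")
  write_grid_nifti(case$mask, paths[["mask"]], datatype = "int16")
  write_grid_nifti(case$labels, paths[["labels"]], datatype = "int16")
  paths
}
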