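#' Construct a multi-label segmentation volume
#'
#' A `label_volume` is a 3D integer array of segmentation labels together with
#' its geometry: voxel spacing (mm), the world position of the first voxel
#' center (mm), and the anatomical meaning of the three array axes. The
#' canonical axis order is x = mediolateral (ML), y = anteroposterior (AP),
#' z = craniocaudal (CC), and the canonical labels are 0 background, 1 femur,
#' 2 medial tibia, 3 lateral tibia.
#'
#' @param voxels 3D integer array with values in \{0, 1, 2, 3\}.
#' @param spacing_mm Numeric length-3, voxel size per axis in mm (> 0).
#' @param origin_mm Numeric length-3, world mm position of voxel (1,1,1).
#' @param axis_codes Character length-3 naming the array axes; canonical
#'   order is `c("ML", "AP", "CC")`.
#' @param metadata Optional named list carried along (e.g. phantom ground truth).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                         axis_codes = c("ML", "AP", "CC"),
                         metadata = list()) {
  if (length(dim(voxels)) != 3L)
    stop_scd("label volume must be a 3D array, got %d dims", length(dim(voxels)))
  if (!all(spacing_mm > 0) || length(spacing_mm) != 3L)
    stop_scd("spacing_mm must be three strictly positive values")
  storage.mode(voxels) <- "integer"
  v <- structure(list(voxels = voxels,
                      spacing_mm = as.numeric(spacing_mm),
                      origin_mm = as.numeric(origin_mm),
                      axis_codes = axis_codes,
                      metadata = metadata),
                 class = "label_volume")
  validate_label_volume(v)
  v
}

validate_label_volume <- function(v, require_roles = TRUE) {
  labs <- sort(unique(as.integer(v$voxels)))
  bad <- setdiff(labs, 0:3)
  if (length(bad))
    stop_scd("unknown labels present: {%s}", paste(bad, collapse = ","))
  if (require_roles) {
    if (!any(v$voxels == LABEL_FEMUR))
      stop_scd("volume contains no femur voxels (label %d)", LABEL_FEMUR,
               class = "scdmap_validation_error")
    if (!any(v$voxels == LABEL_TIBIA_LAT))
      stop_scd("volume contains no lateral tibia voxels (label %d)",
               LABEL_TIBIA_LAT, class = "scdmap_validation_error")
  }
  invisible(v)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  tab <- table(factor(x$voxels, levels = 0:3,
                      labels = c("background", "femur", "tibia_med", "tibia_lat")))
  print(tab)
  invisible(x)
}

# world mm coordinates of voxel centers given an index matrix [n x 3]
voxel_centers_mm <- function(volume, idx) {
  sweep(sweep(idx - 1, 2, volume$spacing_mm, `*`), 2, volume$origin_mm, `+`)
}

label_indices <- function(volume, labels) {
  which(array(volume$voxels %in% labels, dim(volume$voxels)), arr.ind = TRUE)
}

#' Read a multi-label segmentation volume from NIfTI
#'
#' Reads a 3D integer NIfTI volume, remaps labels into the canonical roles,
#' reorients the array axes to the canonical ML/AP/CC order (assuming an
#' RAS-coded header: R = lateral for a left knee imaged prone; see
#' [build_frame()] for the laterality convention), and validates that the
#' femur and lateral tibia are present. Labels outside the map are reported
#' with a warning and treated as background.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label_map Named integer vector mapping file label integers to the
#'   roles `femur`, `tibia_medial`, `tibia_lateral`.
#' @return A [label_volume()].
#' @export
read_labels <- function(path,
                        label_map = c(femur = 1L, tibia_medial = 2L,
                                      tibia_lateral = 3L)) {
  if (!file.exists(path)) stop_scd("no such file: %s", path, class = "scdmap_io_error")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_scd("%s: expected a 3D volume, got %dD", path, length(dim(img)),
             class = "scdmap_format_error")
  arr <- as.array(img)
  if (is.double(arr)) {
    if (max(abs(arr - round(arr))) > 1e-6)
      stop_scd("%s: voxel values are not integers (float segmentation?)", path,
               class = "scdmap_format_error")
    arr <- round(arr)
  }
  xf0 <- RNifti::xform(img)
  if (!is.null(attr(xf0, "code")) && attr(xf0, "code") > 0)
    RNifti::orientation(img) <- "RAS"   # reorient to canonical axes
  arr <- round(as.array(img))
  storage.mode(arr) <- "integer"
  needed <- c("femur", "tibia_medial", "tibia_lateral")
  if (!all(needed %in% names(label_map)))
    stop_scd("label_map must name roles: %s", paste(needed, collapse = ", "))
  out <- array(0L, dim(arr))
  out[arr == label_map[["femur"]]] <- LABEL_FEMUR
  out[arr == label_map[["tibia_medial"]]] <- LABEL_TIBIA_MED
  out[arr == label_map[["tibia_lateral"]]] <- LABEL_TIBIA_LAT
  stray <- setdiff(unique(as.integer(arr)), c(0L, unname(label_map)))
  if (length(stray))
    warn_scd("unknown labels treated as background: {%s}",
             paste(sort(stray), collapse = ","))
  pix <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  label_volume(out, spacing_mm = pix[1:3], origin_mm = origin)
}

#' Write a label volume to NIfTI
#'
#' Geometry (spacing, origin) is stored in the qform so that
#' `read_labels(write_labels(v))` reproduces voxels, spacing, and origin
#' exactly.
#'
#' @param volume A [label_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_labels <- function(volume, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_scd("directory does not exist: %s", dir, class = "scdmap_io_error")
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing_mm
  m <- diag(c(volume$spacing_mm, 1))
  m[1:3, 4] <- volume$origin_mm
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract per-slice segmentation outlines
#'
#' Boundary voxels of each label are those with at least one face neighbour
#' (6-connectivity) of a different label or background, including volume
#' borders. Outlines are reported per coronal slice (the AP axis index) in
#' world mm coordinates.
#'
#' @param volume A [label_volume()].
#' @return A data.frame with columns `slice` (AP array index), `label`,
#'   `x`, `y`, `z` (mm voxel-center coordinates).
#' @export
extract_outlines <- function(volume) {
  arr <- volume$voxels
  d <- dim(arr)
  boundary <- array(FALSE, d)
  shift_differs <- function(axis, step) {
    idx <- lapply(d, seq_len)
    # compare arr[i] with arr[i + step] along `axis`; out-of-range = background
    out <- array(TRUE, d)   # border voxels differ from implicit background
    n <- d[axis]
    keep <- seq_len(n - 1L)
    a_idx <- idx; a_idx[[axis]] <- if (step > 0) keep else keep + 1L
    b_idx <- idx; b_idx[[axis]] <- if (step > 0) keep + 1L else keep
    a <- do.call(`[`, c(list(arr), a_idx, list(drop = FALSE)))
    b <- do.call(`[`, c(list(arr), b_idx, list(drop = FALSE)))
    out_idx <- a_idx
    out <- do.call(`[<-`, c(list(out), out_idx, list(value = a != b)))
    out
  }
  for (axis in 1:3) for (step in c(-1L, 1L))
    boundary <- boundary | shift_differs(axis, step)
  boundary <- boundary & arr != 0L
  idx <- which(boundary, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(slice = integer(), label = integer(),
                      x = numeric(), y = numeric(), z = numeric()))
  mm <- voxel_centers_mm(volume, idx)
  out <- data.frame(slice = idx[, 2], label = arr[idx],
                    x = mm[, 1], y = mm[, 2], z = mm[, 3])
  out[order(out$slice, out$label, out$x, out$y, out$z), , drop = FALSE]
}
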