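#' Principal tibial bone axis
#'
#' First principal component of the combined medial + lateral tibial voxel
#' point cloud, oriented toward the scanner's +z. This is the craniocaudal
#' reference direction of the joint frame.
#'
#' @param volume A [label_volume()].
#' @return Unit length-3 vector. Warns if the leading two eigenvalues are
#'   within 5\% of each other (near-degenerate, e.g. a symmetric phantom).
#' @export
tibial_axis <- function(volume) {
  idx <- label_indices(volume, c(LABEL_TIBIA_MED, LABEL_TIBIA_LAT))
  if (nrow(idx) < 3L)
    stop_scd("tibia has fewer than 3 voxels", class = "scdmap_frame_error")
  pts <- voxel_centers_mm(volume, idx)
  ev <- eigen(cov(pts), symmetric = TRUE)
  vals <- ev$values
  if (vals[1] <= 0 || vals[2] / vals[1] < 1e-12 || vals[3] / vals[1] < 1e-12)
    stop_scd("degenerate (planar or collinear) tibial point cloud",
             class = "scdmap_frame_error")
  if (vals[1] / vals[2] < 1.05)
    warn_scd("tibial principal axis is near-degenerate (eigenvalue ratio %.3f)",
             vals[1] / vals[2])
  ax <- ev$vectors[, 1]
  if (ax[3] < 0) ax <- -ax
  normalize(ax)
}

#' Build the joint-specific Cartesian coordinate system
#'
#' z is the tibial principal axis (craniocaudal, cranial positive); x is the
#' canonical mediolateral axis orthogonalized against z, with +x pointing
#' lateral (for a left knee in canonical array orientation the lateral
#' direction is +array-x; set `laterality = "right"` to flip); y = z cross x
#' (anteroposterior; in the phantom convention +y is posterior). The origin
#' is the centroid of the lateral tibial condyle's top surface. The frame
#' transform is rigid.
#'
#' @param volume A [label_volume()] containing femur and lateral tibia.
#' @param laterality "left" or "right" knee.
#' @return An object of class `joint_frame` with fields `origin_mm`,
#'   `x_axis`, `y_axis`, `z_axis`, `laterality`.
#' @export
build_frame <- function(volume, laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  z <- tibial_axis(volume)
  ml_raw <- c(if (laterality == "left") 1 else -1, 0, 0)
  x <- normalize(ml_raw - sum(ml_raw * z) * z)
  y <- cross3(z, x)

  idx3 <- label_indices(volume, LABEL_TIBIA_LAT)
  dt <- data.table::as.data.table(idx3)
  data.table::setnames(dt, c("dim1", "dim2", "dim3"))
  top <- dt[, list(k = max(dim3)), by = c("dim1", "dim2")]
  pts <- voxel_centers_mm(volume, as.matrix(top[, c("dim1", "dim2", "k")]))
  pts[, 3] <- pts[, 3] + volume$spacing_mm[3] / 2  # top face
  origin <- colMeans(pts)

  structure(list(origin_mm = origin, x_axis = x, y_axis = y, z_axis = z,
                 laterality = laterality),
            class = "joint_frame")
}

#' @export
print.joint_frame <- function(x, ...) {
  cat(sprintf("<joint_frame> origin (%.2f, %.2f, %.2f) mm, %s knee\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3], x$laterality))
  m <- rbind(x = x$x_axis, y = x$y_axis, z = x$z_axis)
  print(round(m, 4))
  invisible(x)
}

#' Transform world (scanner) coordinates into frame coordinates
#'
#' @param frame A [build_frame()] result.
#' @param pts n x 3 matrix of world mm points.
#' @return n x 3 matrix of frame mm coordinates.
#' @export
world_to_frame <- function(frame, pts) {
  pts <- rbind(pts)  # accept a bare vector
  R <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  sweep(pts, 2, frame$origin_mm, `-`) %*% R
}

#' Transform frame coordinates back into world coordinates
#'
#' @param frame A [build_frame()] result.
#' @param pts n x 3 matrix of frame mm coordinates.
#' @return n x 3 matrix of world mm points.
#' @export
frame_to_world <- function(frame, pts) {
  pts <- rbind(pts)
  R <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  sweep(pts %*% t(R), 2, frame$origin_mm, `+`)
}

#' Femoral extent along the transepicondylar (mediolateral) axis
#'
#' The transepicondylar direction is taken as the frame's mediolateral axis.
#' The diameter is the femur's maximum minus minimum voxel-center coordinate
#' along it, measured over the distal 40\% (by frame z) of the femur label,
#' which contains the epicondylar region; the femoral shaft is thereby
#' excluded by construction. The lateralmost coordinate anchors the
#' lateral-exclusion rule of the measurement grid.
#'
#' @param volume A [label_volume()] with a non-empty femur.
#' @param frame A [build_frame()] result.
#' @param distal_fraction Fraction of the femoral craniocaudal extent,
#'   counted from the distal (joint-facing) end, used for the measurement.
#' @return Object of class `transepicondylar_result`: `axis_direction`,
#'   `diameter_mm`, `lateral_extreme_mm`, `extreme_points` (2 x 3 world mm,
#'   the projections of the extremes onto the transepicondylar line).
#'   Warns if the femur is disconnected along the axis.
#' @export
transepicondylar_axis <- function(volume, frame, distal_fraction = 0.4) {
  idx <- label_indices(volume, LABEL_FEMUR)
  if (nrow(idx) == 0L)
    stop_scd("volume contains no femur voxels", class = "scdmap_validation_error")
  fc <- world_to_frame(frame, voxel_centers_mm(volume, idx))
  zmin <- min(fc[, 3]); zmax <- max(fc[, 3])
  distal <- fc[, 3] <= zmin + distal_fraction * (zmax - zmin) + 1e-9
  fx <- fc[distal, 1]
  lo <- min(fx); hi <- max(fx)
  # disconnected femur along ML: any empty bin of 1.5 voxel widths inside span
  bw <- 1.5 * volume$spacing_mm[1]
  if (hi - lo > 2 * bw) {
    bins <- seq(lo, hi, by = bw)
    occupied <- tabulate(findInterval(fx, bins), nbins = length(bins))
    if (any(occupied[-length(occupied)] == 0L))
      warn_scd("femur appears disconnected along the transepicondylar axis")
  }
  p_lo <- frame_to_world(frame, c(lo, 0, 0))
  p_hi <- frame_to_world(frame, c(hi, 0, 0))
  structure(list(axis_direction = frame$x_axis,
                 diameter_mm = hi - lo,
                 lateral_extreme_mm = hi,
                 extreme_points = rbind(medial = p_lo, lateral = p_hi)),
            class = "transepicondylar_result")
}

#' @export
print.transepicondylar_result <- function(x, ...) {
  cat(sprintf("<transepicondylar_result> diameter %.2f mm, lateral extreme x = %.2f mm\n",
              x$diameter_mm, x$lateral_extreme_mm))
  invisible(x)
}
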