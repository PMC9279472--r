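#' Specification of a voxelized femorotibial phantom
#'
#' Describes a synthetic knee-like geometry: a tibia consisting of a plateau
#' slab (split into medial and lateral condyle labels at the mediolateral
#' midline) on top of a distal shaft block (so the tibial principal axis is
#' craniocaudal, as for a real tibia), and a femur slab with an optional
#' sagittally curved distal surface and a proximal shaft. The femoral surface
#' sits `gap_mm` above the tibial plateau at the condylar apex; varus loading
#' is modelled as a rigid rotation of the femur about a medial hinge line
#' before re-voxelization.
#'
#' All lengths are in mm. The mediolateral axis is array axis 1 (+x =
#' lateral for a left knee), anteroposterior is axis 2 (+y = posterior),
#' craniocaudal is axis 3 (+z = cranial). Coronal slices are indexed along
#' the AP axis.
#'
#' @param volume_shape Integer length-3, voxel counts per axis.
#' @param spacing_mm Numeric length-3, voxel size per axis (> 0).
#' @param femur_width_mm Mediolateral extent of the femoral slab and the
#'   tibial plateau (transepicondylar diameter analogue).
#' @param condyle_radius_mm Sagittal curvature radius of the distal femoral
#'   surface; `Inf` gives a flat plate.
#' @param gap_mm Vertical gap between the femoral surface and the tibial
#'   plateau at the condylar apex (>= 0).
#' @param varus_angle_deg Rigid femur rotation about the hinge line;
#'   0 = unloaded. Positive angles open the lateral compartment. Must be
#'   < 10 degrees.
#' @param hinge_offset_mm Mediolateral (x) position of the hinge line;
#'   `NULL` places it 4 mm lateral of the medial plateau edge, inside the
#'   medial compartment.
#' @param hinge_axis_deg In-plane tilt of the hinge line: 0 runs the hinge
#'   parallel to the AP axis; positive values tilt its posterior end
#'   medially, so that the opening grows both laterally and posteriorly.
#' @param hinge_ap_offset_mm AP (y) offset of the hinge reference point from
#'   the volume centre.
#' @param slice_gap_pattern Integer indices of unsegmented coronal (AP)
#'   slices, emulating interslice gaps; may be empty.
#' @param notch_width_mm Width of an intercondylar notch (no femur) centred
#'   at the tibial midline; 0 disables it.
#' @param plateau_depth_mm,plateau_thickness_mm Tibial plateau AP extent and
#'   CC thickness.
#' @param shaft_width_mm,shaft_length_mm Tibial/femoral shaft block size.
#' @param femur_thickness_mm CC thickness of the femoral slab.
#' @param seed Integer seed for any randomized perturbation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(120L, 84L, 200L),
                         spacing_mm = c(0.5, 0.5, 0.5),
                         femur_width_mm = 54,
                         condyle_radius_mm = 30,
                         gap_mm = 7.8,
                         varus_angle_deg = 0,
                         hinge_offset_mm = NULL,
                         hinge_axis_deg = 0,
                         hinge_ap_offset_mm = 0,
                         slice_gap_pattern = integer(0),
                         notch_width_mm = 0,
                         plateau_depth_mm = 36,
                         plateau_thickness_mm = 7,
                         shaft_width_mm = 26,
                         shaft_length_mm = 52,
                         femur_thickness_mm = 10,
                         seed = 0L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 4))
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_scd("spacing_mm must be three strictly positive values")
  if (gap_mm < 0) stop_scd("gap_mm must be >= 0")
  if (abs(varus_angle_deg) >= 10)
    stop_scd("varus_angle_deg must be < 10 degrees (small-rotation model)")
  if (femur_width_mm > volume_shape[1] * spacing_mm[1])
    stop_scd("femur_width_mm exceeds the volume's mediolateral extent")
  xc <- (volume_shape[1] - 1) * spacing_mm[1] / 2
  if (is.null(hinge_offset_mm))
    hinge_offset_mm <- xc - femur_width_mm / 2 + 4
  if (varus_angle_deg != 0 && hinge_offset_mm >= xc)
    stop_scd("hinge must lie inside the medial compartment (x < %g mm)", xc)
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 femur_width_mm = femur_width_mm,
                 condyle_radius_mm = condyle_radius_mm,
                 gap_mm = gap_mm,
                 varus_angle_deg = varus_angle_deg,
                 hinge_offset_mm = hinge_offset_mm,
                 hinge_axis_deg = hinge_axis_deg,
                 hinge_ap_offset_mm = hinge_ap_offset_mm,
                 slice_gap_pattern = as.integer(slice_gap_pattern),
                 notch_width_mm = notch_width_mm,
                 plateau_depth_mm = plateau_depth_mm,
                 plateau_thickness_mm = plateau_thickness_mm,
                 shaft_width_mm = shaft_width_mm,
                 shaft_length_mm = shaft_length_mm,
                 femur_thickness_mm = femur_thickness_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Derived geometry shared by all generators (all in mm, origin at voxel 1,1,1).
phantom_geometry <- function(spec) {
  d <- spec$volume_shape; sp <- spec$spacing_mm
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  xc <- (d[1] - 1) * sp[1] / 2
  yc <- (d[2] - 1) * sp[2] / 2
  ns <- max(1L, round(spec$shaft_length_mm / sp[3]))
  np <- max(1L, round(spec$plateau_thickness_mm / sp[3]))
  if (ns + np >= d[3])
    stop_scd("volume too small along z for the tibia", class = "scdmap_sizing_error")
  plateau_top_face <- zs[ns + np] + sp[3] / 2
  list(xs = xs, ys = ys, zs = zs, xc = xc, yc = yc,
       ns = ns, np = np, plateau_top_face = plateau_top_face)
}

# Sagittal sag of the femoral surface relative to the condylar apex.
condyle_sag <- function(y, yc, radius) {
  if (!is.finite(radius)) return(rep(0, length(y)))
  dy <- pmin(abs(y - yc), radius)
  radius - sqrt(radius^2 - dy^2)
}

rodrigues <- function(u, theta) {
  u <- normalize(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * tcrossprod(u)
}

hinge_axis_point <- function(spec, geo) {
  alpha <- spec$hinge_axis_deg * pi / 180
  # positive rotation opens the side with positive perpendicular distance
  # d = (x - xh) cos(alpha) + (y - yh) sin(alpha), i.e. lateral/posterior
  u <- c(sin(alpha), -cos(alpha), 0)
  p0 <- c(spec$hinge_offset_mm, geo$yc + spec$hinge_ap_offset_mm,
          geo$plateau_top_face)
  list(u = u, p0 = p0)
}

#' Analytic gap increase of the hinge loading model
#'
#' For a rigid femur rotation by `varus_angle_deg` about the hinge line, the
#' vertical gap at a column (x, y) increases by approximately
#' `d * tan(angle)` where `d` is the in-plane perpendicular distance of the
#' column from the hinge line (positive lateral/posterior). This is the
#' ground truth the voxel measurements are validated against.
#'
#' @param spec A [phantom_spec()] (its hinge and angle fields are used).
#' @param x,y Column coordinates in mm (phantom/world frame).
#' @return Gap increase in mm (negative medial of the hinge).
#' @export
hinge_opening <- function(spec, x, y) {
  geo <- phantom_geometry(spec)
  alpha <- spec$hinge_axis_deg * pi / 180
  yh <- geo$yc + spec$hinge_ap_offset_mm
  d <- (x - spec$hinge_offset_mm) * cos(alpha) + (y - yh) * sin(alpha)
  d * tan(spec$varus_angle_deg * pi / 180)
}

# Core voxelizer. gap_fun(x, y) gives the continuous gap profile (mm) above
# the plateau top face, already including any condylar sag. The femur is
# voxelized by a center-in-solid membership test, optionally after inverse
# rigid rotation about the hinge line, so that a zero-angle loaded phantom is
# voxel-identical to the unloaded one.
voxelize_phantom <- function(spec, gap_fun, rotate = FALSE, kind = "phantom") {
  geo <- phantom_geometry(spec)
  d <- spec$volume_shape; sp <- spec$spacing_mm
  vox <- array(0L, d)

  half_fw <- spec$femur_width_mm / 2
  half_pd <- spec$plateau_depth_mm / 2
  half_sw <- spec$shaft_width_mm / 2
  in_x_plate <- abs(geo$xs - geo$xc) <= half_fw + 1e-9
  in_y_plate <- abs(geo$ys - geo$yc) <= half_pd + 1e-9
  in_x_shaft <- abs(geo$xs - geo$xc) <= half_sw + 1e-9
  in_y_shaft <- abs(geo$ys - geo$yc) <= half_sw + 1e-9
  lat_x <- geo$xs > geo$xc   # left knee: +x = lateral

  # tibia: shaft then plateau, each split at the ML midline
  tib_lab_x <- ifelse(lat_x, LABEL_TIBIA_LAT, LABEL_TIBIA_MED)
  shaft_ix <- which(in_x_shaft); shaft_iy <- which(in_y_shaft)
  vox[shaft_ix, shaft_iy, seq_len(geo$ns)] <-
    rep(tib_lab_x[shaft_ix], times = length(shaft_iy) * geo$ns)
  plate_ix <- which(in_x_plate); plate_iy <- which(in_y_plate)
  vox[plate_ix, plate_iy, geo$ns + seq_len(geo$np)] <-
    rep(tib_lab_x[plate_ix], times = length(plate_iy) * geo$np)

  # femur membership over the z window above the plateau
  k0 <- geo$ns + 1L
  kw <- k0:d[3]
  nw <- length(kw)
  X <- array(rep(geo$xs, times = d[2] * nw), c(d[1], d[2], nw))
  Y <- array(rep(rep(geo$ys, each = d[1]), times = nw), c(d[1], d[2], nw))
  Z <- array(rep(geo$zs[kw], each = d[1] * d[2]), c(d[1], d[2], nw))
  if (rotate && spec$varus_angle_deg != 0) {
    hx <- hinge_axis_point(spec, geo)
    R <- rodrigues(hx$u, -spec$varus_angle_deg * pi / 180)
    dx <- X - hx$p0[1]; dy <- Y - hx$p0[2]; dz <- Z - hx$p0[3]
    qx <- hx$p0[1] + R[1, 1] * dx + R[1, 2] * dy + R[1, 3] * dz
    qy <- hx$p0[2] + R[2, 1] * dx + R[2, 2] * dy + R[2, 3] * dz
    qz <- hx$p0[3] + R[3, 1] * dx + R[3, 2] * dy + R[3, 3] * dz
    rm(dx, dy, dz)
  } else {
    qx <- X; qy <- Y; qz <- Z
  }
  rm(X, Y, Z)
  g <- gap_fun(qx, qy)
  zb <- geo$plateau_top_face + g
  in_slab <- abs(qx - geo$xc) <= half_fw + 1e-9 &
    abs(qy - geo$yc) <= half_pd + 1e-9
  if (any(g[in_slab] < -1e-9, na.rm = TRUE))
    stop_scd("gap profile is negative over the femoral footprint",
             class = "scdmap_parameter_error")
  if (spec$notch_width_mm > 0)
    in_slab <- in_slab & abs(qx - geo$xc) >= spec$notch_width_mm / 2
  in_shaft <- abs(qx - geo$xc) <= half_sw + 1e-9 &
    abs(qy - geo$yc) <= half_sw + 1e-9
  member <- in_slab & qz >= zb &
    (qz <= zb + spec$femur_thickness_mm | in_shaft)
  rm(qx, qy, qz, g, zb, in_slab, in_shaft)

  # sizing check: the femoral slab must fit under the volume top
  top_face <- geo$zs[d[3]] + sp[3] / 2
  px <- geo$xs[in_x_plate]; py <- geo$ys[in_y_plate]
  gmax <- max(gap_fun(rep(px, times = length(py)),
                      rep(py, each = length(px))), na.rm = TRUE)
  if (!rotate || spec$varus_angle_deg == 0) {
    if (geo$plateau_top_face + gmax + spec$femur_thickness_mm > top_face + 1e-9)
      stop_scd("volume too small along z for femur slab plus gap",
               class = "scdmap_sizing_error")
  }

  win <- vox[, , kw, drop = FALSE]
  if (any(member & win != 0L))
    stop_scd("femur rotation collides with the tibia",
             class = "scdmap_collision_error")
  win[member] <- LABEL_FEMUR
  vox[, , kw] <- win

  gaps <- scan_column_gaps_internal(vox, sp)
  sg <- spec$slice_gap_pattern
  if (length(sg)) {
    sg <- sg[sg >= 1L & sg <= d[2]]
    vox[, sg, ] <- 0L
  }

  label_volume(vox, spacing_mm = sp,
               metadata = list(kind = kind, spec = spec,
                               plateau_top_face_mm = geo$plateau_top_face,
                               realized_gap_mm = mean(gaps$gap, na.rm = TRUE),
                               realized_gap_range_mm = range(gaps$gap, na.rm = TRUE)))
}

# Brute-force per-column gap scan used to report realized gaps in metadata.
# gap = femur bottom face minus lateral/medial tibia top face, per (i, j)
# column, restricting the femoral minimum to voxels above the tibial maximum.
scan_column_gaps_internal <- function(vox, spacing_mm, tibia_labels = c(2L, 3L)) {
  d <- dim(vox); nxy <- d[1] * d[2]
  tib_top <- rep(NA_integer_, nxy)
  for (k in seq_len(d[3])) {
    m <- as.vector(vox[, , k] %in% tibia_labels)
    tib_top[m] <- k
  }
  fem_bot <- rep(NA_integer_, nxy)
  for (k in seq_len(d[3])) {
    m <- as.vector(vox[, , k] == LABEL_FEMUR) & is.na(fem_bot) &
      !is.na(tib_top) & k > tib_top
    fem_bot[m] <- k
  }
  ij <- arrayInd(seq_len(nxy), d[1:2])
  ok <- !is.na(tib_top) & !is.na(fem_bot)
  data.frame(i = ij[, 1][ok], j = ij[, 2][ok],
             x = (ij[, 1][ok] - 1) * spacing_mm[1],
             y = (ij[, 2][ok] - 1) * spacing_mm[2],
             gap = (fem_bot[ok] - tib_top[ok] - 1) * spacing_mm[3])
}

#' Per-column femorotibial gaps of a label volume
#'
#' Scans every (x, y) voxel column and reports the vertical distance between
#' the femoral bottom face and the tibial top face, with the femoral minimum
#' restricted to voxels above the tibial maximum. Mainly a phantom inspection
#' utility; the measurement pipeline proper works in the joint frame
#' (see [extract_surfaces()]).
#'
#' @param volume A [label_volume()].
#' @param tibia_labels Tibial labels forming the lower surface.
#' @return data.frame with columns `i, j, x, y, gap` (mm).
#' @export
scan_column_gaps <- function(volume, tibia_labels = c(2L, 3L)) {
  scan_column_gaps_internal(volume$voxels, volume$spacing_mm, tibia_labels)
}

#' Generate a flat-plate phantom
#'
#' Two axis-aligned slabs — femur above, tibia below (split into medial and
#' lateral labels at the mediolateral midline) — separated by a constant
#' vertical gap. The realized, voxel-quantized gap is reported in the
#' volume metadata (`realized_gap_mm`). This is the oracle geometry for
#' validating gap recovery.
#'
#' @param spec A [phantom_spec()] with `condyle_radius_mm = Inf`.
#' @return A [label_volume()].
#' @export
generate_flat_plate <- function(spec) {
  if (is.finite(spec$condyle_radius_mm))
    stop_scd("flat plate requires condyle_radius_mm = Inf")
  voxelize_phantom(spec, function(x, y) rep(spec$gap_mm, length(x)),
                   rotate = FALSE, kind = "flat_plate")
}

#' Generate a wedge phantom with a linear mediolateral gap profile
#'
#' The gap varies linearly along x from `gap_medial_mm` at the medial plateau
#' edge to `gap_lateral_mm` at the lateral edge; the femoral surface is flat
#' in the AP direction. The linear coefficients are stored in the metadata as
#' ground truth.
#'
#' @param spec A [phantom_spec()]; its `condyle_radius_mm` is ignored (the
#'   wedge surface is flat).
#' @param gap_lateral_mm,gap_medial_mm Gap at the lateral / medial plateau
#'   edge (both >= 0).
#' @return A [label_volume()] with `metadata$wedge = list(x_medial, x_lateral,
#'   gap_medial, gap_lateral, slope)`.
#' @export
generate_wedge <- function(spec, gap_lateral_mm, gap_medial_mm) {
  if (min(gap_lateral_mm, gap_medial_mm) < 0)
    stop_scd("wedge gaps must be >= 0", class = "scdmap_parameter_error")
  geo <- phantom_geometry(spec)
  x_med <- geo$xc - spec$femur_width_mm / 2
  x_lat <- geo$xc + spec$femur_width_mm / 2
  slope <- (gap_lateral_mm - gap_medial_mm) / (x_lat - x_med)
  gap_fun <- function(x, y) gap_medial_mm + slope * (x - x_med)
  v <- voxelize_phantom(spec, gap_fun, rotate = FALSE, kind = "wedge")
  v$metadata$wedge <- list(x_medial = x_med, x_lateral = x_lat,
                           gap_medial = gap_medial_mm,
                           gap_lateral = gap_lateral_mm, slope = slope)
  v
}

#' Generate a knee-like phantom
#'
#' Curved femoral condylar surface (sagittal radius `condyle_radius_mm`),
#' optional intercondylar notch, optional unsegmented coronal slices
#' (`slice_gap_pattern`), and varus loading modelled as a rigid rotation of
#' the femur about a medial hinge line before re-voxelization. With
#' `varus_angle_deg = 0` the output is voxel-identical to the unloaded
#' geometry. The analytic gap-increase field is available from
#' [hinge_opening()].
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
generate_knee_like <- function(spec) {
  gap_fun <- function(x, y)
    spec$gap_mm + condyle_sag(y, (spec$volume_shape[2] - 1) * spec$spacing_mm[2] / 2,
                              spec$condyle_radius_mm)
  voxelize_phantom(spec, gap_fun, rotate = TRUE, kind = "knee_like")
}
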