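#' Extract opposing subchondral surface height fields
#'
#' For every (x, y) column over the lateral tibial condyle footprint (in
#' joint-frame coordinates, binned at the in-plane voxel spacing), the tibial
#' height `t` is the top face of the highest lateral-tibia voxel and the
#' femoral height `f` is the bottom face of the lowest femur voxel lying
#' above the tibial surface (so posterior femoral cortex below the joint
#' line cannot capture a column). Columns missing either surface are marked
#' invalid. Columns on unsegmented coronal slices (interslice gaps) are
#' filled by linear interpolation along y from the nearest segmented slices
#' and flagged as interpolated.
#'
#' @param volume A [label_volume()].
#' @param frame A [build_frame()] result for the same specimen (for
#'   measurements across conditions, the baseline frame).
#' @param interpolate_gaps Bridge unsegmented coronal slices (default TRUE).
#' @return Object of class `surface_field`: data.frame with columns
#'   `x, y, t, f, valid, interpolated` plus attributes `bbox` (face-to-face
#'   footprint box), `bins`, `dz`, `frame`, `missing_slices`.
#' @export
extract_surfaces <- function(volume, frame, interpolate_gaps = TRUE) {
  validate_label_volume(volume)
  bx <- volume$spacing_mm[1]; by <- volume$spacing_mm[2]
  dz <- volume$spacing_mm[3]

  # Column bins are anchored at the lateral-tibia footprint minimum so that
  # axis-aligned voxel columns map one-to-one onto bins regardless of where
  # the frame origin falls relative to the voxel lattice. The tibia is the
  # fixed body, so the anchor is stable across conditions/configurations.
  idx_t <- label_indices(volume, LABEL_TIBIA_LAT)
  fc_t <- world_to_frame(frame, voxel_centers_mm(volume, idx_t))
  anchor <- c(min(fc_t[, 1]), min(fc_t[, 2]))
  bin_tab <- function(fc) {
    data.table::data.table(ix = as.integer(round((fc[, 1] - anchor[1]) / bx)),
                           iy = as.integer(round((fc[, 2] - anchor[2]) / by)),
                           z = fc[, 3])
  }
  dt_t <- bin_tab(fc_t)
  idx_f <- label_indices(volume, LABEL_FEMUR)
  dt_f <- bin_tab(world_to_frame(frame, voxel_centers_mm(volume, idx_f)))
  ttab <- dt_t[, list(tc = max(z)), by = c("ix", "iy")]
  joined <- merge(dt_f, ttab, by = c("ix", "iy"))
  joined <- joined[joined$z > joined$tc + dz / 2 - 1e-9, ]
  ftab <- if (nrow(joined)) joined[, list(fc = min(z)), by = c("ix", "iy")]
          else data.table::data.table(ix = integer(), iy = integer(),
                                      fc = numeric())
  tab <- merge(ttab, ftab, by = c("ix", "iy"), all.x = TRUE)

  ix_rng <- range(tab$ix); iy_rng <- range(tab$iy)
  nix <- ix_rng[2] - ix_rng[1] + 1L; niy <- iy_rng[2] - iy_rng[1] + 1L
  Tm <- Fm <- matrix(NA_real_, nix, niy)
  seg <- matrix(FALSE, nix, niy)     # tibia actually segmented here
  ri <- tab$ix - ix_rng[1] + 1L; rj <- tab$iy - iy_rng[1] + 1L
  Tm[cbind(ri, rj)] <- tab$tc + dz / 2
  Fm[cbind(ri, rj)] <- pmax(tab$fc - dz / 2, tab$tc + dz / 2)
  seg[cbind(ri, rj)] <- TRUE
  interp <- matrix(FALSE, nix, niy)

  # coronal slices with no lateral tibia at all, strictly interior
  missing_iy <- which(colSums(seg) == 0L)
  missing_iy <- missing_iy[missing_iy > min(which(colSums(seg) > 0)) &
                             missing_iy < max(which(colSums(seg) > 0))]
  if (interpolate_gaps && length(missing_iy)) {
    present_iy <- which(colSums(seg) > 0L)
    for (i in seq_len(nix)) {
      has <- present_iy[seg[i, present_iy]]
      if (length(has) < 2L) next
      fill <- missing_iy[missing_iy > min(has) & missing_iy < max(has)]
      if (!length(fill)) next
      Tm[i, fill] <- stats::approx(has, Tm[i, has], xout = fill)$y
      okf <- has[!is.na(Fm[i, has])]
      if (length(okf) >= 2L) {
        fillf <- fill[fill > min(okf) & fill < max(okf)]
        Fm[i, fillf] <- stats::approx(okf, Fm[i, okf], xout = fillf)$y
      }
      interp[i, fill] <- TRUE
    }
  }

  in_fp <- seg | interp
  cells <- which(in_fp, arr.ind = TRUE)
  xs <- anchor[1] + (ix_rng[1] + cells[, 1] - 1L) * bx
  ys <- anchor[2] + (iy_rng[1] + cells[, 2] - 1L) * by
  out <- data.frame(x = xs, y = ys,
                    t = Tm[cells], f = Fm[cells],
                    valid = !is.na(Tm[cells]) & !is.na(Fm[cells]),
                    interpolated = interp[cells])
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  if (!any(out$valid))
    stop_scd("no column has both surfaces: measurement domain is empty",
             class = "scdmap_domain_error")
  structure(out,
            class = c("surface_field", "data.frame"),
            bbox = c(xmin = min(xs) - bx / 2, xmax = max(xs) + bx / 2,
                     ymin = min(ys) - by / 2, ymax = max(ys) + by / 2),
            bins = c(bx, by), dz = dz, frame = frame,
            missing_slices_y = anchor[2] + (iy_rng[1] + missing_iy - 1L) * by)
}

# Regular-lattice matrices of a surface field (for interpolation).
surface_matrices <- function(surfaces) {
  bx <- attr(surfaces, "bins")[1]; by <- attr(surfaces, "bins")[2]
  x0 <- min(surfaces$x); y0 <- min(surfaces$y)
  ix <- as.integer(round((surfaces$x - x0) / bx))
  iy <- as.integer(round((surfaces$y - y0) / by))
  xg <- x0 + (0:max(ix)) * bx
  yg <- y0 + (0:max(iy)) * by
  Tm <- Fm <- matrix(NA_real_, length(xg), length(yg))
  i <- ix + 1L; j <- iy + 1L
  ok <- surfaces$valid
  Tm[cbind(i[ok], j[ok])] <- surfaces$t[ok]
  Fm[cbind(i[ok], j[ok])] <- surfaces$f[ok]
  list(xg = xg, yg = yg, Tm = Tm, Fm = Fm)
}

# Interpolate the SCD (f - t) at arbitrary frame (x, y) positions.
# Points up to half a bin outside the column-center lattice are clamped to
# the edge column. Returns NA where any corner column is invalid.
scd_interpolate <- function(surfaces, xp, yp, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  sm <- surface_matrices(surfaces)
  bx <- attr(surfaces, "bins")[1]; by <- attr(surfaces, "bins")[2]
  cx <- pmin(pmax(xp, sm$xg[1]), sm$xg[length(sm$xg)])
  cy <- pmin(pmax(yp, sm$yg[1]), sm$yg[length(sm$yg)])
  cx[abs(cx - xp) > bx / 2 + 1e-9] <- NA
  cy[abs(cy - yp) > by / 2 + 1e-9] <- NA
  if (method == "nearest") {
    i <- pmax(1L, pmin(length(sm$xg), as.integer(round(cx / bx)) -
                         as.integer(round(sm$xg[1] / bx)) + 1L))
    j <- pmax(1L, pmin(length(sm$yg), as.integer(round(cy / by)) -
                         as.integer(round(sm$yg[1] / by)) + 1L))
    out <- sm$Fm[cbind(i, j)] - sm$Tm[cbind(i, j)]
    out[is.na(cx) | is.na(cy)] <- NA
    return(out)
  }
  fI <- bilinear_na(sm$xg, sm$yg, sm$Fm, cx, cy)
  tI <- bilinear_na(sm$xg, sm$yg, sm$Tm, cx, cy)
  fI - tI
}
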