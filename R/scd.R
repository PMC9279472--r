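#' Build the baseline-referenced measurement grid
#'
#' A regular grid with the configured mediolateral and anteroposterior
#' spacings covering the lateral tibial condyle's bounding box in the
#' baseline (intact, unloaded) scan, centred so the box margins are
#' symmetric. The same grid is reused for all subsequent conditions and
#' configurations of the specimen (baseline referencing), with the tibia as
#' the fixed body.
#'
#' @param baseline_surfaces A [extract_surfaces()] result from the baseline
#'   scan.
#' @param spacing_ap Anteroposterior grid spacing in mm (default 3.3).
#' @param spacing_ml Mediolateral grid spacing in mm (default 3.5).
#' @return Object of class `measurement_grid`: data.frame with columns
#'   `point_id, x, y, retained, reason`, plus attributes `spacing`
#'   (ml, ap) and `bbox`.
#' @export
build_grid <- function(baseline_surfaces, spacing_ap = 3.3, spacing_ml = 3.5) {
  if (spacing_ap <= 0 || spacing_ml <= 0) stop_scd("grid spacings must be > 0")
  bb <- attr(baseline_surfaces, "bbox")
  bb <- setNames(as.numeric(bb[c("xmin", "xmax", "ymin", "ymax")]),
                 c("xmin", "xmax", "ymin", "ymax"))
  ext_x <- unname(bb["xmax"] - bb["xmin"]); ext_y <- unname(bb["ymax"] - bb["ymin"])
  nx <- max(1L, floor(ext_x / spacing_ml + 1e-9) + 1L)
  ny <- max(1L, floor(ext_y / spacing_ap + 1e-9) + 1L)
  if (ext_x < spacing_ml || ext_y < spacing_ap)
    warn_scd("footprint smaller than one grid spacing; grid degenerates")
  mx <- (ext_x - (nx - 1) * spacing_ml) / 2
  my <- (ext_y - (ny - 1) * spacing_ap) / 2
  gx <- unname(bb["xmin"]) + mx + (seq_len(nx) - 1) * spacing_ml
  gy <- unname(bb["ymin"]) + my + (seq_len(ny) - 1) * spacing_ap
  pts <- expand.grid(x = gx, y = gy)
  out <- data.frame(point_id = seq_len(nrow(pts)), x = pts$x, y = pts$y,
                    retained = TRUE, reason = NA_character_)
  structure(out, class = c("measurement_grid", "data.frame"),
            spacing = c(ml = spacing_ml, ap = spacing_ap), bbox = bb)
}

#' Exclude the lateralmost grid points
#'
#' Points lying within the lateralmost 10\% (by default) of the femur's
#' maximum diameter along the transepicondylar axis are masked (reason
#' `"lateral-10%"`) to avoid spurious measurements over the curved femoral
#' epicondyle. Previously masked points keep their original reason.
#'
#' @param grid A [build_grid()] result.
#' @param te A [transepicondylar_axis()] result.
#' @param fraction Excluded fraction of the diameter (default 0.10).
#' @return The grid with updated `retained`/`reason`.
#' @export
apply_lateral_exclusion <- function(grid, te, fraction = 0.10) {
  if (te$diameter_mm <= 0) stop_scd("transepicondylar diameter must be > 0")
  if (fraction < 0 || fraction > 0.5) stop_scd("exclusion fraction must be in [0, 0.5]")
  cut <- te$lateral_extreme_mm - fraction * te$diameter_mm
  hit <- grid$retained & grid$x > cut
  grid$retained[hit] <- FALSE
  grid$reason[hit] <- "lateral-10%"
  attr(grid, "lateral_cut_mm") <- cut
  grid
}

#' Compute the SCD map on a measurement grid
#'
#' Per retained grid point, the subchondral cortical distance is the
#' vertical femur-minus-tibia surface distance, interpolated from the height
#' fields (bilinear by default; `"nearest"` uses the nearest column, offered
#' for sensitivity checks). Points over invalid columns are masked with
#' reason `"invalid-column"`.
#'
#' @param surfaces A [extract_surfaces()] result (any condition or
#'   configuration of the specimen).
#' @param grid The specimen's baseline-referenced [build_grid()] result.
#' @param method "bilinear" or "nearest".
#' @param provenance Optional named list (specimen, condition,
#'   configuration) carried in the attributes.
#' @return Object of class `scd_map`: grid data.frame plus `scd` column.
#' @export
compute_scd_map <- function(surfaces, grid, method = "bilinear",
                            provenance = list()) {
  scd <- scd_interpolate(surfaces, grid$x, grid$y, method = method)
  out <- grid
  out$scd <- scd
  bad <- out$retained & is.na(scd)
  out$retained[bad] <- FALSE
  out$reason[bad] <- "invalid-column"
  out$scd[!out$retained] <- NA_real_
  if (!any(out$retained))
    stop_scd("all grid points fall on invalid columns",
             class = "scdmap_domain_error")
  structure(out, class = c("scd_map", "data.frame"),
            spacing = attr(grid, "spacing"), bbox = attr(grid, "bbox"),
            provenance = provenance)
}

#' Compartment-mean SCD
#'
#' Arithmetic mean of the SCD over all retained, unmasked grid points: the
#' computational counterpart of a multi-site manual mean, covering the whole
#' lateral compartment.
#'
#' @param map A [compute_scd_map()] result.
#' @return Mean SCD in mm.
#' @export
scd_compmean <- function(map) {
  v <- map$scd[map$retained]
  if (!length(v)) stop_scd("empty SCD map", class = "scdmap_domain_error")
  mean(v)
}

#' Six manual-site SCD analogues and their mean
#'
#' Mediolateral sites ml1..ml3 (lateral to medial) lie at 25/50/75\% of the
#' lateral condyle's ML extent from the lateral edge, on the mid-coronal
#' line; anteroposterior sites ap1..ap3 (anterior to posterior) at 25/50/75\%
#' of the AP extent on the mid-sagittal line. The AP sites are fractional
#' proxies for the meniscus-based anatomical landmarks (anterior horn base,
#' meniscus body centre, posterior horn base), since no meniscus is
#' segmented. A site falling on an invalid column is moved to the nearest
#' valid column and flagged.
#'
#' @param surfaces A [extract_surfaces()] result.
#' @param bbox Optional footprint box to define the sites (defaults to the
#'   surfaces' own; pass the baseline box for baseline-referenced sites).
#' @return List with `sites` (data.frame site, x, y, scd, flagged) and
#'   `manmean` (mean of the six values).
#' @export
manual_site_scd <- function(surfaces, bbox = NULL) {
  bb <- bbox %||% attr(surfaces, "bbox")
  bb <- setNames(as.numeric(bb[c("xmin", "xmax", "ymin", "ymax")]),
                 c("xmin", "xmax", "ymin", "ymax"))
  ext_x <- unname(bb["xmax"] - bb["xmin"]); ext_y <- unname(bb["ymax"] - bb["ymin"])
  # lateral edge is xmax (left-knee convention: +x lateral);
  # anterior edge is ymin (+y posterior)
  xml <- unname(bb["xmax"]) - c(0.25, 0.50, 0.75) * ext_x
  yap <- unname(bb["ymin"]) + c(0.25, 0.50, 0.75) * ext_y
  ymid <- (bb["ymin"] + bb["ymax"]) / 2
  xmid <- (bb["xmin"] + bb["xmax"]) / 2
  sites <- data.frame(site = c("ml1", "ml2", "ml3", "ap1", "ap2", "ap3"),
                      x = c(xml, rep(xmid, 3)),
                      y = c(rep(ymid, 3), yap))
  scd <- scd_interpolate(surfaces, sites$x, sites$y)
  flagged <- is.na(scd)
  if (any(flagged)) {
    ok <- surfaces[surfaces$valid, ]
    for (i in which(flagged)) {
      d2 <- (ok$x - sites$x[i])^2 + (ok$y - sites$y[i])^2
      j <- which.min(d2)
      scd[i] <- ok$f[j] - ok$t[j]
    }
  }
  sites$scd <- as.numeric(scd)
  sites$flagged <- flagged
  list(sites = sites, manmean = mean(sites$scd))
}

#' Match manual sites to their nearest retained grid points
#'
#' Per site, the retained grid point with minimal Euclidean (x, y) distance;
#' exact ties are broken toward smaller x, then smaller y.
#'
#' @param grid A [build_grid()] (possibly masked) result.
#' @param sites data.frame with columns `site, x, y` (e.g.
#'   `manual_site_scd(...)$sites`).
#' @return data.frame: site, point_id, grid x/y, distance_mm.
#' @export
nearest_grid_to_sites <- function(grid, sites) {
  g <- grid[grid$retained, ]
  if (!nrow(g)) stop_scd("grid has no retained points")
  out <- lapply(seq_len(nrow(sites)), function(i) {
    d <- sqrt((g$x - sites$x[i])^2 + (g$y - sites$y[i])^2)
    cand <- order(round(d, 9), g$x, g$y)[1]
    data.frame(site = sites$site[i], point_id = g$point_id[cand],
               x = g$x[cand], y = g$y[cand], distance_mm = d[cand])
  })
  do.call(rbind, out)
}
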