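#' Per-point loading-difference map
#'
#' Per-grid-point difference between a loaded and an unloaded SCD map of the
#' same specimen and condition, on the intersection of their retained
#' points. The default is the absolute difference |SCD_LO - SCD_UL| used for
#' the heat maps; `signed = TRUE` keeps the sign (SCD_LO - SCD_UL).
#'
#' @param loaded,unloaded [compute_scd_map()] results sharing the grid.
#' @param signed Keep the sign of the difference (default FALSE).
#' @return Object of class `difference_map`: data.frame `point_id, x, y,
#'   delta`, with condition/specimen provenance attributes.
#' @export
difference_map <- function(loaded, unloaded, signed = FALSE) {
  pl <- attr(loaded, "provenance"); pu <- attr(unloaded, "provenance")
  for (k in c("specimen", "condition")) {
    if (!is.null(pl[[k]]) && !is.null(pu[[k]]) && !identical(pl[[k]], pu[[k]]))
      stop_scd("maps are from different %ss (%s vs %s)", k, pl[[k]], pu[[k]],
               class = "scdmap_pairing_error")
  }
  if (nrow(loaded) != nrow(unloaded) ||
      max(abs(loaded$x - unloaded$x), abs(loaded$y - unloaded$y)) > 1e-9)
    stop_scd("maps are not on the same grid", class = "scdmap_pairing_error")
  keep <- loaded$retained & unloaded$retained
  d <- loaded$scd[keep] - unloaded$scd[keep]
  if (!signed) d <- abs(d)
  structure(data.frame(point_id = loaded$point_id[keep],
                       x = loaded$x[keep], y = loaded$y[keep], delta = d),
            class = c("difference_map", "data.frame"),
            condition = pl$condition %||% pu$condition,
            specimen = pl$specimen %||% pu$specimen,
            signed = signed,
            spacing = attr(loaded, "spacing"))
}

#' Specimen-averaged difference map
#'
#' Per-point arithmetic mean of per-specimen difference maps sharing one
#' condition and grid topology. Points missing (not retained) in some
#' specimens are averaged over the available ones, provided at least
#' `min_support` of the specimens contribute.
#'
#' @param maps List of [difference_map()] objects.
#' @param condition Condition label of the average (defaults to the maps').
#' @param min_support Minimum fraction of specimens a point must be present
#'   in (default 0.5).
#' @return A `difference_map` with specimen provenance
#'   `"mean-of-specimens"` and a `support` column.
#' @export
average_maps <- function(maps, condition = NULL, min_support = 0.5) {
  if (!length(maps)) stop_scd("no maps to average")
  conds <- unique(unlist(lapply(maps, attr, "condition")))
  if (length(conds) > 1)
    stop_scd("maps mix conditions: %s", paste(conds, collapse = ", "),
             class = "scdmap_pairing_error")
  all_pts <- do.call(rbind, lapply(maps, function(m)
    data.frame(point_id = m$point_id, x = m$x, y = m$y, delta = m$delta)))
  dt <- data.table::as.data.table(all_pts)
  agg <- dt[, list(x = x[1], y = y[1], delta = mean(delta),
                   support = .N / length(maps)), by = "point_id"]
  agg <- agg[agg$support >= min_support - 1e-9, ]
  agg <- agg[order(agg$point_id), ]
  structure(data.frame(point_id = agg$point_id, x = agg$x, y = agg$y,
                       delta = agg$delta, support = agg$support),
            class = c("difference_map", "data.frame"),
            condition = condition %||% conds,
            specimen = "mean-of-specimens",
            signed = isTRUE(attr(maps[[1]], "signed")),
            spacing = attr(maps[[1]], "spacing"))
}

#' Render a difference map as a heat map
#'
#' Writes a PNG raster in the axial convention (mediolateral on the image x
#' axis, anterior at the top) and the underlying grid as CSV next to it.
#' Colours ramp from dark blue (0) through yellow to red (scale maximum);
#' grid points absent from the map are transparent.
#'
#' @param map A [difference_map()].
#' @param path Output PNG path; the CSV replaces the extension with `.csv`.
#' @param zlim Colour scale limits (default 0 to the data maximum).
#' @param pixels_per_cell Magnification of the raster (default 12).
#' @return Invisibly, a list with the PNG and CSV paths.
#' @export
render_heatmap <- function(map, path, zlim = NULL, pixels_per_cell = 12L) {
  if (!nrow(map)) stop_scd("empty difference map")
  zlim <- zlim %||% c(0, max(map$delta, 1e-9))
  xs <- sort(unique(round(map$x, 6))); ys <- sort(unique(round(map$y, 6)))
  M <- matrix(NA_real_, length(xs), length(ys))
  M[cbind(match(round(map$x, 6), xs), match(round(map$y, 6), ys))] <- map$delta
  ramp <- grDevices::colorRamp(c("#00204D", "#2C728E", "#5DC863", "#FDE725",
                                 "#D7191C"))
  z <- pmin(pmax((M - zlim[1]) / diff(zlim), 0), 1)
  rgba <- array(0, c(length(ys), length(xs), 4))
  for (j in seq_along(ys)) {
    zi <- z[, j]
    ok <- !is.na(zi)
    # image row 1 = smallest y (anterior) at the top
    if (any(ok)) {
      cols <- ramp(zi[ok]) / 255
      rgba[j, ok, 1:3] <- cols
      rgba[j, ok, 4] <- 1
    }
  }
  big <- rgba[rep(seq_along(ys), each = pixels_per_cell),
              rep(seq_along(xs), each = pixels_per_cell), , drop = FALSE]
  png::writePNG(big, path)
  csv <- sub("\\.png$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  df <- as.data.frame(map)
  df$condition <- attr(map, "condition") %||% NA_character_
  write.csv(df, csv, row.names = FALSE)
  invisible(list(png = path, csv = csv))
}
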