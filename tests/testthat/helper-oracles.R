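# Compact phantom specs for fast tests, plus independent brute-force oracles
# (deliberately naive loop implementations, kept separate from the package's
# vectorized code paths).

small_spec <- function(...) {
  args <- utils::modifyList(list(volume_shape = c(72L, 56L, 150L),
                                 spacing_mm = c(0.5, 0.5, 0.5),
                                 femur_width_mm = 32,
                                 plateau_depth_mm = 24,
                                 shaft_width_mm = 20,
                                 shaft_length_mm = 40,
                                 condyle_radius_mm = Inf),
                           list(...))
  do.call(phantom_spec, args)
}

knee_spec <- function(...) small_spec(condyle_radius_mm = 20, ...)

# Exhaustive per-column gap scan: for every (i, j) column, the distance from
# the tibial top face to the femoral bottom face (femur restricted to above
# the tibia). Written as plain loops.
oracle_column_gaps <- function(volume) {
  arr <- volume$voxels
  d <- dim(arr)
  dz <- volume$spacing_mm[3]
  out <- list()
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    col <- arr[i, j, ]
    tk <- which(col == 2L | col == 3L)
    if (!length(tk)) next
    tt <- max(tk)
    fk <- which(col == 1L)
    fk <- fk[fk > tt]
    if (!length(fk)) next
    n <- n + 1L
    out[[n]] <- c(i, j, (min(fk) - tt - 1L) * dz)
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2],
             x = (m[, 1] - 1) * volume$spacing_mm[1],
             y = (m[, 2] - 1) * volume$spacing_mm[2],
             gap = m[, 3])
}

# Brute-force boundary-voxel count (6-neighbourhood, borders count).
oracle_boundary_count <- function(arr, label) {
  d <- dim(arr)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (arr[i, j, k] != label) next
    nb <- c(if (i > 1) arr[i - 1, j, k] else -1L,
            if (i < d[1]) arr[i + 1, j, k] else -1L,
            if (j > 1) arr[i, j - 1, k] else -1L,
            if (j < d[2]) arr[i, j + 1, k] else -1L,
            if (k > 1) arr[i, j, k - 1] else -1L,
            if (k < d[3]) arr[i, j, k + 1] else -1L)
    if (any(nb != label)) n <- n + 1L
  }
  n
}

# Label-volume invariants asserted by exhaustive voxel scan: labels disjoint
# by construction of a single array; femur strictly above tibia in every
# shared column.
expect_phantom_invariants <- function(volume) {
  arr <- volume$voxels
  expect_true(all(arr %in% 0:3))
  d <- dim(arr)
  ok <- TRUE
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    col <- arr[i, j, ]
    tk <- which(col == 2L | col == 3L)
    fk <- which(col == 1L)
    if (length(tk) && length(fk) && min(fk) <= max(tk)) ok <- FALSE
  }
  expect_true(ok, label = "femur lies strictly above tibia in every column")
}

# Measure a volume end to end with the package pipeline; frame/grid from a
# reference (baseline) volume when given.
measure_compmean <- function(volume, baseline = NULL) {
  base <- baseline %||% volume
  fr <- build_frame(base)
  te <- transepicondylar_axis(base, fr)
  s0 <- extract_surfaces(base, fr)
  g <- apply_lateral_exclusion(build_grid(s0), te)
  s <- if (is.null(baseline)) s0 else extract_surfaces(volume, fr)
  scd_compmean(compute_scd_map(s, g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
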