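test_that("flat plates realize the requested gap in every column", {
  for (gap in c(8.0, 0.0)) {
    v <- generate_flat_plate(small_spec(gap_mm = gap))
    g <- oracle_column_gaps(v)
    expect_true(nrow(g) > 100)
    expect_true(all(abs(g$gap - gap) < 1e-9),
                label = sprintf("all column gaps equal %.1f mm", gap))
    expect_phantom_invariants(v)
  }
})

test_that("non-lattice gaps are voxel-quantized and reported as realized", {
  v <- generate_flat_plate(small_spec(gap_mm = 5.25))
  g <- oracle_column_gaps(v)
  realized <- unique(g$gap)
  expect_length(realized, 1L)
  expect_equal(realized %% 0.5, 0)            # multiple of the z voxel
  expect_lt(abs(realized - 5.25), 0.5)        # within one z voxel of request
  expect_equal(v$metadata$realized_gap_mm, realized)
})

test_that("wedge per-column gaps follow the linear profile within one z voxel", {
  spec <- small_spec()
  v <- generate_wedge(spec, gap_lateral_mm = 12, gap_medial_mm = 4)
  w <- v$metadata$wedge
  g <- oracle_column_gaps(v)
  pred <- w$gap_medial + w$slope * (g$x - w$x_medial)
  expect_true(all(abs(g$gap - pred) <= 0.5 + 1e-9))
  # mean over the symmetric footprint equals the profile midpoint
  expect_lt(abs(mean(g$gap) - 8.0), 0.25)
  expect_phantom_invariants(v)

  # degenerate wedge reduces to a flat plate
  v2 <- generate_wedge(spec, gap_lateral_mm = 6, gap_medial_mm = 6)
  expect_true(all(abs(oracle_column_gaps(v2)$gap - 6) < 1e-9))

  expect_error(generate_wedge(spec, gap_lateral_mm = 5, gap_medial_mm = -1),
               class = "scdmap_parameter_error")
})

test_that("zero-angle loading is the identity and regeneration is bit-identical", {
  spec <- knee_spec(gap_mm = 7.8)
  v0 <- generate_knee_like(spec)
  spec0 <- spec; spec0$varus_angle_deg <- 0
  expect_identical(generate_knee_like(spec0)$voxels, v0$voxels)
  expect_identical(generate_knee_like(spec)$voxels, v0$voxels)
})

test_that("hinge rotation opens the lateral gap by the analytic lever-arm amount", {
  spec <- knee_spec(gap_mm = 7.8, varus_angle_deg = 2)
  vL <- generate_knee_like(spec)
  spec0 <- spec; spec0$varus_angle_deg <- 0
  v0 <- generate_knee_like(spec0)
  gL <- oracle_column_gaps(vL); g0 <- oracle_column_gaps(v0)
  m <- merge(g0, gL, by = c("i", "j"), suffixes = c("_ul", "_lo"))

  # ~20.25 mm lateral of the hinge (nearest voxel column on the mid-coronal
  # line; the analytic opening there is lever * tan(angle))
  yc <- (spec$volume_shape[2] - 1) * spec$spacing_mm[2] / 2
  xq <- spec$hinge_offset_mm + 20.25
  row <- m[abs(m$x_ul - xq) < 0.26 & abs(m$y_ul - yc) < 0.26, ]
  expect_true(nrow(row) >= 1)
  pred <- hinge_opening(spec, row$x_ul[1], row$y_ul[1])
  expect_equal(pred, (row$x_ul[1] - spec$hinge_offset_mm) * tan(2 * pi / 180),
               tolerance = 1e-9)
  expect_lt(abs((row$gap_lo[1] - row$gap_ul[1]) - pred), 0.5 + 1e-9)

  # medial-compartment gap unchanged (within one voxel) at the hinge line
  hx <- m[abs(m$x_ul - spec$hinge_offset_mm) < 0.26, ]
  expect_true(nrow(hx) >= 1)
  expect_true(all(abs(hx$gap_lo - hx$gap_ul) <= 0.5 + 1e-9))

  expect_phantom_invariants(vL)
})

test_that("compartment means increase strictly with varus angle", {
  vals <- sapply(c(0, 1, 2, 3, 5), function(a) {
    spec <- knee_spec(gap_mm = 7.8, varus_angle_deg = a)
    mean(oracle_column_gaps(generate_knee_like(spec))$gap)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("interslice gaps leave segmented-slice measurements unchanged", {
  spec <- knee_spec(gap_mm = 7.8)
  v_full <- generate_knee_like(spec)
  gaps_y <- seq(4L, spec$volume_shape[2] - 4L, by = 2L)
  spec_g <- knee_spec(gap_mm = 7.8, slice_gap_pattern = gaps_y)
  v_gap <- generate_knee_like(spec_g)
  expect_true(all(v_gap$voxels[, gaps_y, ] == 0L))
  kept <- setdiff(seq_len(spec$volume_shape[2]), gaps_y)
  expect_identical(v_gap$voxels[, kept, ], v_full$voxels[, kept, ])
})

test_that("femur-tibia collisions are detected", {
  spec <- knee_spec(gap_mm = 0, varus_angle_deg = 5)
  expect_error(generate_knee_like(spec), class = "scdmap_collision_error")
})

test_that("volumes too small for the requested geometry raise sizing errors", {
  spec <- small_spec(volume_shape = c(72L, 56L, 100L), gap_mm = 18)
  expect_error(generate_flat_plate(spec), class = "scdmap_sizing_error")
})

test_that("synthetic studies are deterministic and honour a null design", {
  base <- knee_spec(gap_mm = 8)
  null_design <- study_design(n_specimens = 2, noise_sd_mm = 0,
                              cell_noise_sd_mm = 0,
                              opening_increment_mm = rep(0, 5),
                              unloaded_drift_mm = rep(0, 5),
                              load_effect_mm = 0, seed = 7)
  st <- generate_study(null_design, base)
  expect_equal(unique(st$truth$true_gap_mm), 8)
  v_ul <- st$volume(1, "intact", "UL")
  v_lo <- st$volume(1, "LCL+PT+PFL+ACL", "LO")
  expect_identical(v_ul$voxels, v_lo$voxels)

  st2 <- generate_study(null_design, base)
  expect_identical(st2$truth, st$truth)
  expect_identical(st2$volume(2, "LCL", "LO")$voxels,
                   st$volume(2, "LCL", "LO")$voxels)
})

test_that("study designs validate their effect structure", {
  expect_error(study_design(opening_increment_mm = c(0, 2, 1, 3, 4)),
               "non-decreasing")
  expect_error(study_design(opening_increment_mm = c(0, 1, 2)), "per condition")
  expect_error(study_design(unloaded_drift_mm = c(0, -0.1, 0, 0, 0)), ">= 0")
})
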