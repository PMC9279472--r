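# A bare surface field with a controlled bounding box, for grid arithmetic.
fake_surfaces <- function(xmin, xmax, ymin, ymax, bins = c(0.5, 0.5)) {
  structure(data.frame(x = numeric(), y = numeric(), t = numeric(),
                       f = numeric(), valid = logical(),
                       interpolated = logical()),
            class = c("surface_field", "data.frame"),
            bbox = c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            bins = bins, dz = 0.5)
}

test_that("grid point counts follow the floor arithmetic of the footprint", {
  g1 <- build_grid(fake_surfaces(0, 35, 0, 33))
  expect_equal(nrow(g1), 121)
  expect_equal(length(unique(g1$x)), 11)
  expect_equal(length(unique(g1$y)), 11)
  # symmetric margins
  expect_equal(min(g1$x) - 0, 35 - max(g1$x))

  g2 <- build_grid(fake_surfaces(0, 34.9, 0, 32.9))
  expect_equal(nrow(g2), 100)

  # identical regeneration from the same baseline
  expect_identical(build_grid(fake_surfaces(0, 35, 0, 33)), g1)

  expect_warning(build_grid(fake_surfaces(0, 2, 0, 2)), "degenerates")
})

test_that("grid spacing is exactly the configured values", {
  g <- build_grid(fake_surfaces(-10, 25, 3, 30))
  expect_true(all(abs(diff(sort(unique(g$x))) - 3.5) < 1e-9))
  expect_true(all(abs(diff(sort(unique(g$y))) - 3.3) < 1e-9))
})

test_that("lateral exclusion implements the 10% transepicondylar rule", {
  te <- structure(list(axis_direction = c(1, 0, 0), diameter_mm = 80,
                       lateral_extreme_mm = 40),
                  class = "transepicondylar_result")
  g <- build_grid(fake_surfaces(0, 38, 0, 20))
  gx <- apply_lateral_exclusion(g, te)
  expect_true(all(!gx$retained[gx$x > 32]))
  expect_true(all(gx$retained[gx$x <= 32]))
  expect_true(all(gx$reason[!gx$retained] == "lateral-10%"))

  # no-op when the grid is entirely medial of the cut
  te2 <- structure(list(axis_direction = c(1, 0, 0), diameter_mm = 80,
                        lateral_extreme_mm = 200),
                   class = "transepicondylar_result")
  expect_true(all(apply_lateral_exclusion(g, te2)$retained))
})

test_that("exclusion equals a brute-force filter on randomized configurations", {
  set.seed(42)
  for (r in 1:100) {
    xmax <- runif(1, 10, 60)
    g <- build_grid(fake_surfaces(runif(1, -20, 0), xmax, 0, runif(1, 5, 40)))
    diam <- runif(1, 20, 100)
    extreme <- runif(1, min(g$x), max(g$x) + 10)
    frac <- runif(1, 0, 0.5)
    te <- structure(list(axis_direction = c(1, 0, 0), diameter_mm = diam,
                         lateral_extreme_mm = extreme),
                    class = "transepicondylar_result")
    gx <- apply_lateral_exclusion(g, te, fraction = frac)
    brute <- logical(nrow(g))
    for (i in seq_len(nrow(g)))
      brute[i] <- g$x[i] > (extreme - frac * diam)
    expect_identical(!gx$retained, brute)
  }
})

test_that("SCD maps recover flat and wedge profiles at the grid points", {
  spec <- small_spec(gap_mm = 8)
  v <- generate_flat_plate(spec)
  fr <- build_frame(v)
  s <- extract_surfaces(v, fr)
  g <- apply_lateral_exclusion(build_grid(s), transepicondylar_axis(v, fr))
  m <- compute_scd_map(s, g)
  expect_true(all(abs(m$scd[m$retained] - 8) < 1e-9))
  expect_equal(scd_compmean(m), 8)

  w <- generate_wedge(small_spec(), gap_lateral_mm = 12, gap_medial_mm = 4)
  sw <- extract_surfaces(w, fr)     # same tibia geometry: frame is shared
  mw <- compute_scd_map(sw, g)
  wd <- w$metadata$wedge
  x_world <- mw$x + fr$origin_mm[1]
  pred <- wd$gap_medial + wd$slope * (x_world - wd$x_medial)
  ok <- mw$retained
  expect_true(all(abs(mw$scd[ok] - pred[ok]) <= 0.5 + 1e-9))
  expect_lt(abs(scd_compmean(mw) - mean(pred[ok])), 0.25)
})

test_that("compartment mean is the arithmetic mean of retained points", {
  g <- build_grid(fake_surfaces(0, 7, 0, 3.3))
  m <- g
  m$scd <- NA_real_
  m$scd[1:3] <- c(6, 8, 10)
  m$retained <- FALSE; m$retained[1:3] <- TRUE
  class(m) <- c("scd_map", "data.frame")
  expect_equal(scd_compmean(m), 8)
  m$retained[] <- FALSE
  expect_error(scd_compmean(m), class = "scdmap_domain_error")
})

test_that("manual sites follow the quarter conventions and flag fallbacks", {
  v <- generate_flat_plate(small_spec(gap_mm = 8))
  fr <- build_frame(v)
  s <- extract_surfaces(v, fr)
  ms <- manual_site_scd(s)
  expect_equal(ms$sites$scd, rep(8, 6))
  expect_equal(ms$manmean, 8)
  expect_false(any(ms$sites$flagged))
  bb <- attr(s, "bbox")
  ml <- ms$sites[1:3, ]
  expect_equal(ml$x, unname(bb["xmax"] - c(0.25, 0.5, 0.75) *
                              (bb["xmax"] - bb["xmin"])), tolerance = 1e-9)
  expect_equal(unique(ml$y), unname((bb["ymin"] + bb["ymax"]) / 2))

  # wedge: ml1 (lateral) > ml2 > ml3, matching the linear profile
  w <- generate_wedge(small_spec(), gap_lateral_mm = 12, gap_medial_mm = 4)
  sw <- extract_surfaces(w, build_frame(w))
  msw <- manual_site_scd(sw)
  mlw <- msw$sites$scd[1:3]
  expect_true(mlw[1] > mlw[2] && mlw[2] > mlw[3])
  wd <- w$metadata$wedge
  frw <- build_frame(w)
  pred <- wd$gap_medial + wd$slope * (msw$sites$x[1:3] + frw$origin_mm[1] -
                                        wd$x_medial)
  expect_true(all(abs(mlw - pred) <= 0.5 + 1e-9))
})

test_that("site-to-grid matching equals a brute-force nearest scan", {
  g <- build_grid(fake_surfaces(0, 21, 0, 19.8))
  sites <- data.frame(site = c("on", "tie", "r1", "r2"),
                      x = c(g$x[5], (g$x[1] + g$x[2]) / 2, 7.31, 15.9),
                      y = c(g$y[5], g$y[1], 3.02, 12.77))
  res <- nearest_grid_to_sites(g, sites)
  expect_equal(res$point_id[1], g$point_id[5])
  expect_equal(res$distance_mm[1], 0)
  # tie broken toward smaller x
  expect_equal(res$x[2], min(g$x[1], g$x[2]))
  # brute force over every retained point
  for (i in 3:4) {
    d <- sqrt((g$x - sites$x[i])^2 + (g$y - sites$y[i])^2)
    expect_equal(res$point_id[i], g$point_id[which.min(d)])
  }
})

test_that("baseline-referenced grids are identical across conditions", {
  base <- knee_spec(gap_mm = 8)
  design <- study_design(n_specimens = 1, seed = 5)
  st <- generate_study(design, base)
  v0 <- st$volume(1, "intact", "UL")
  fr <- build_frame(v0)
  te <- transepicondylar_axis(v0, fr)
  g0 <- apply_lateral_exclusion(build_grid(extract_surfaces(v0, fr)), te)
  for (cell in list(c("LCL", "LO"), c("LCL+PT+PFL+ACL", "UL"))) {
    v <- st$volume(1, cell[1], cell[2])
    g <- apply_lateral_exclusion(build_grid(extract_surfaces(v, fr)), te)
    expect_equal(g$x, g0$x, tolerance = 1e-9)
    expect_equal(g$y, g0$y, tolerance = 1e-9)
  }
})
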