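reader_table <- function(values, source = "reader1",
                         sites = c("ml1", "ml2", "ml3", "ap1", "ap2", "ap3")) {
  data.frame(specimen = 1, condition = "intact", configuration = "UL",
             measure = sites, source = source, value = values)
}

test_that("reader pooling averages per key and derives the six-site mean", {
  r1 <- reader_table(c(6.6, 6.6, 7.0, 10.5, 6.8, 9.0))
  r2 <- reader_table(c(6.6, 6.6, 7.0, 10.5, 6.8, 9.0), source = "reader2")
  pooled <- pool_readers(r1, r2)
  expect_equal(pooled$value[match(r1$measure, pooled$measure)], r1$value)
  # six printed intact-unloaded site means average to 7.75 (printed row: 7.8)
  expect_equal(pooled$value[pooled$measure == "manmean"], 7.75)

  # plain mean of two readers
  r2b <- r2; r2b$value <- r2$value + 2
  pooled2 <- pool_readers(r1, r2b)
  expect_equal(pooled2$value[pooled2$measure == "ml1"], 7.6)

  # symmetric in its inputs
  expect_equal(pool_readers(r2b, r1)$value, pooled2$value)

  # unmatched keys
  r3 <- r2[-2, ]
  expect_error(pool_readers(r1, r3), class = "scdmap_pairing_error")
})

test_that("ICC is 1 for duplicated readers and undefined for constants", {
  x <- c(5.2, 7.1, 8.4, 6.6, 9.9, 7.3)
  icc <- icc_two_readers(x, x)
  expect_equal(icc$value, 1.0)
  const <- icc_two_readers(rep(4, 5), rep(4, 5))
  expect_true(const$undefined)
  expect_error(icc_two_readers(1:2, 1:2), "at least 3")
})

test_that("ICC is invariant to a common additive shift", {
  set.seed(2)
  a <- rnorm(50, 8, 1.4); b <- a + rnorm(50, 0, 0.3)
  i1 <- icc_two_readers(a, b)$value
  i2 <- icc_two_readers(a + 10, b + 10)$value
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("ICC is near zero under the independence null", {
  set.seed(99)
  n <- 1e4
  a <- rnorm(n); b <- rnorm(n)
  expect_lt(abs(icc_two_readers(a, b)$value), 0.05)
})

test_that("ICC matches its variance-component construction", {
  # between-target SD 1.4, within-pair SD 0.15: expected ICC
  # 1.4^2 / (1.4^2 + 0.15^2) = 0.989, emulating the observed 0.95-0.99 range
  for (s in 1:5) {
    set.seed(100 + s)
    truth <- rnorm(200, 8, 1.4)
    a <- truth + rnorm(200, 0, 0.15)
    b <- truth + rnorm(200, 0, 0.15)
    expect_lt(abs(icc_two_readers(a, b)$value - 0.98), 0.02)
  }
})

test_that("RM-ANOVA F statistics equal a hand sum-of-squares oracle", {
  set.seed(21)
  d <- expand.grid(specimen = 1:4, condition = c("intact", "LCL"),
                   configuration = c("UL", "LO"), stringsAsFactors = FALSE)
  d$measure <- "compmean"; d$source <- "computational"
  d$value <- round(8 + rnorm(16, 0, 1) +
                     ifelse(d$configuration == "LO", 2, 0) +
                     ifelse(d$condition == "LCL", 0.8, 0), 3)
  res <- rm_anova(study_table(d), "compmean", posthoc = FALSE)

  # independent from-scratch partitioning of the sums of squares
  y <- d$value
  gm <- mean(y)
  mean_by <- function(...) tapply(y, list(...), mean)
  mA <- mean_by(d$condition); mB <- mean_by(d$configuration)
  mS <- mean_by(d$specimen)
  mAB <- mean_by(d$condition, d$configuration)
  mAS <- mean_by(d$condition, d$specimen)
  mBS <- mean_by(d$configuration, d$specimen)
  ss_A <- 8 * sum((mA - gm)^2)
  ss_B <- 8 * sum((mB - gm)^2)
  ss_AB <- 4 * sum((mAB - gm)^2) - ss_A - ss_B
  ss_AS <- 2 * sum((mAS - gm)^2) - ss_A - 4 * sum((mS - gm)^2)
  ss_BS <- 2 * sum((mBS - gm)^2) - ss_B - 4 * sum((mS - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - 4 * sum((mS - gm)^2) - ss_A - ss_B - ss_AB - ss_AS - ss_BS
  F_A <- (ss_A / 1) / (ss_AS / 3)
  F_B <- (ss_B / 1) / (ss_BS / 3)
  F_AB <- (ss_AB / 1) / (ss_res / 3)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "condition"], F_A, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "configuration"], F_B, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "condition:configuration"], F_AB,
               tolerance = 1e-9)
  expect_true(all(eff$p >= 0 & eff$p <= 1))
  expect_true(all(eff$p_gg >= eff$p - 1e-12))
})

test_that("RM-ANOVA handles null data and is invariant to unit rescaling", {
  d <- expand.grid(specimen = 1:4, condition = scd_conditions(),
                   configuration = scd_configurations(),
                   stringsAsFactors = FALSE)
  d$measure <- "compmean"; d$source <- "computational"
  d$value <- 8
  res <- suppressWarnings(rm_anova(study_table(d), "compmean", posthoc = FALSE))
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$p == 1))

  set.seed(5)
  d$value <- 8 + rnorm(nrow(d), 0, 1) + ifelse(d$configuration == "LO", 1.5, 0)
  f_mm <- rm_anova(study_table(d), "compmean", posthoc = FALSE)$effects$F
  d_cm <- d; d_cm$value <- d$value / 10
  f_cm <- rm_anova(study_table(d_cm), "compmean", posthoc = FALSE)$effects$F
  expect_equal(f_mm, f_cm, tolerance = 1e-9)

  # specimen relabelling leaves p-values unchanged
  d_rl <- d; d_rl$specimen <- match(d$specimen, c(3, 1, 4, 2))
  p1 <- rm_anova(study_table(d), "compmean", posthoc = FALSE)$effects$p
  p2 <- rm_anova(study_table(d_rl), "compmean", posthoc = FALSE)$effects$p
  expect_equal(p1, p2, tolerance = 1e-12)

  # incomplete designs are named
  expect_error(rm_anova(study_table(d[-1, ]), "compmean"),
               class = "scdmap_design_error")
})

test_that("Tukey post hocs are multiplicity-adjusted and ordered", {
  tab <- simulate_scd_table(study_design(seed = 31), seed = 31)
  res <- rm_anova(tab, "compmean")
  expect_false(is.null(res$posthoc))
  expect_true(all(res$posthoc$p.value >= 0 & res$posthoc$p.value <= 1))
  # strong loading effects: loaded-configuration condition differences emerge
  expect_true(any(res$posthoc$p.value < 0.05))
})

test_that("condition contrasts reproduce group-mean arithmetic", {
  tab <- simulate_scd_table(study_design(noise_sd_mm = 0, cell_noise_sd_mm = 0,
                                         seed = 3), seed = 3)
  cc <- condition_contrasts(tab, "compmean")
  lo <- cc[cc$configuration == "LO", ]
  expect_equal(lo$delta_mm[match(scd_conditions(), lo$condition)],
               c(0, 1.3, 1.7, 2.2, 2.6), tolerance = 1e-9)
  ul <- cc[cc$configuration == "UL", ]
  expect_equal(ul$delta_mm[match(scd_conditions(), ul$condition)],
               c(0, 0.2, 0.3, 0.4, 0.9), tolerance = 1e-9)
  # zero diagonal and antisymmetry
  expect_equal(cc$delta_mm[cc$condition == "intact"], c(0, 0))
  expect_equal(contrast_pair(tab, "compmean", "LO", "LCL", "intact"),
               -contrast_pair(tab, "compmean", "LO", "intact", "LCL"),
               tolerance = 1e-12)
})
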