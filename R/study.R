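#' Design of a synthetic varus stress study
#'
#' Describes a repeated-measures study: `n_specimens` knees, each imaged in
#' five graded ligament-deficiency conditions and two loading configurations
#' (unloaded "UL", loaded "LO"). The default effect structure follows the
#' magnitudes observed in cadaveric varus stress MRI: a baseline load effect
#' of 2.1 mm in the intact joint, additional loaded-configuration lateral
#' opening increments of 0, 1.3, 1.7, 2.2, 2.6 mm across conditions, and
#' small unloaded drifts of 0, 0.2, 0.3, 0.4, 0.9 mm.
#'
#' Two noise sources: `noise_sd_mm` is the between-specimen SD of the
#' baseline gap; `cell_noise_sd_mm` is a small per-scan repositioning
#' variability applied independently to every specimen x condition x
#' configuration cell.
#'
#' @param n_specimens Number of specimens (default 10).
#' @param conditions Ordered condition labels (default [scd_conditions()]).
#' @param configurations Configurations (default `c("UL", "LO")`).
#' @param opening_increment_mm Per-condition extra lateral gap in the loaded
#'   configuration, beyond the intact load effect; non-decreasing, >= 0.
#' @param unloaded_drift_mm Per-condition unloaded gap increase; >= 0.
#' @param load_effect_mm Loaded-vs-unloaded gap increase in the intact
#'   condition.
#' @param noise_sd_mm Between-specimen SD of the baseline gap.
#' @param cell_noise_sd_mm Per-scan repositioning SD.
#' @param seed Integer RNG seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_specimens = 10L,
                         conditions = scd_conditions(),
                         configurations = scd_configurations(),
                         opening_increment_mm = c(0, 1.3, 1.7, 2.2, 2.6),
                         unloaded_drift_mm = c(0, 0.2, 0.3, 0.4, 0.9),
                         load_effect_mm = 2.1,
                         noise_sd_mm = 1.0,
                         cell_noise_sd_mm = 0.15,
                         seed = 1L) {
  if (length(opening_increment_mm) != length(conditions))
    stop_scd("opening_increment_mm must have one value per condition")
  if (length(unloaded_drift_mm) != length(conditions))
    stop_scd("unloaded_drift_mm must have one value per condition")
  if (any(opening_increment_mm < 0) || any(diff(opening_increment_mm) < -1e-12))
    stop_scd("opening increments must be >= 0 and non-decreasing")
  if (any(unloaded_drift_mm < 0))
    stop_scd("unloaded drifts must be >= 0")
  if (!all(is.finite(c(opening_increment_mm, unloaded_drift_mm, load_effect_mm))))
    stop_scd("effect sizes must be finite")
  structure(list(n_specimens = as.integer(n_specimens),
                 conditions = conditions,
                 configurations = configurations,
                 opening_increment_mm = opening_increment_mm,
                 unloaded_drift_mm = unloaded_drift_mm,
                 load_effect_mm = load_effect_mm,
                 noise_sd_mm = noise_sd_mm,
                 cell_noise_sd_mm = cell_noise_sd_mm,
                 seed = as.integer(seed)),
            class = "study_design")
}

# Intended (ground-truth) apex gap per cell, drawn deterministically from the
# design seed. Loading is modelled as uniform femoral distraction so the
# injected increments are exact ground truth for compartment-mean contrasts.
study_truth_table <- function(design, base) {
  n <- design$n_specimens
  nc <- length(design$conditions)
  nk <- length(design$configurations)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(design$seed)
  baseline <- base$gap_mm + rnorm(n, 0, design$noise_sd_mm)
  eps <- array(rnorm(n * nc * nk, 0, design$cell_noise_sd_mm), c(n, nc, nk))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  rows <- expand.grid(specimen = seq_len(n),
                      condition = design$conditions,
                      configuration = design$configurations,
                      stringsAsFactors = FALSE)
  ci <- match(rows$condition, design$conditions)
  ki <- match(rows$configuration, design$configurations)
  loaded <- rows$configuration == "LO"
  # effect structure mirrors the published group means: unloaded cells carry
  # the per-condition drift, loaded cells the intact load effect plus the
  # condition's opening increment, so condition-vs-intact contrasts within
  # each configuration are exactly the injected drift / increment vectors
  g <- baseline[rows$specimen] +
    ifelse(loaded,
           design$load_effect_mm + design$opening_increment_mm[ci],
           design$unloaded_drift_mm[ci]) +
    eps[cbind(rows$specimen, ci, ki)]
  rows$true_gap_mm <- pmax(g, 0.5)
  rows
}

#' Generate a whole synthetic study
#'
#' Produces the ground-truth table of intended apex gaps for every specimen x
#' condition x configuration cell and a deterministic volume generator. The
#' loaded configuration is modelled as uniform femoral distraction (the gap
#' simply increases by the load effect plus the condition's opening
#' increment), so the injected increments are exact ground truth for
#' compartment-mean contrasts; hinge-rotation loading is available directly
#' through [generate_knee_like()].
#'
#' Volumes are generated lazily through `$volume(specimen, condition,
#' configuration)` (a full default study is ~100 volumes and is better
#' streamed than held in memory); `dir` writes all volumes as NIfTI plus the
#' ground-truth CSV. Identical design and seed give bit-identical volumes and
#' tables.
#'
#' @param design A [study_design()].
#' @param base A [phantom_spec()] giving the common geometry; its `gap_mm` is
#'   the population baseline apex gap.
#' @param dir Optional output directory for NIfTI volumes + `truth.csv`.
#' @return List with `truth` (data.frame), `volume` (generator function),
#'   `design`, `base`, and — if `dir` was given — `paths`.
#' @export
generate_study <- function(design, base = phantom_spec(), dir = NULL) {
  truth <- study_truth_table(design, base)
  vol_fun <- function(specimen, condition, configuration) {
    row <- truth[truth$specimen == specimen & truth$condition == condition &
                   truth$configuration == configuration, ]
    if (nrow(row) != 1L)
      stop_scd("no such study cell: %s/%s/%s", specimen, condition, configuration)
    spec <- base
    spec$gap_mm <- row$true_gap_mm
    spec$varus_angle_deg <- 0
    generate_knee_like(spec)
  }
  out <- list(truth = truth, volume = vol_fun, design = design, base = base)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(nrow(truth))
    for (r in seq_len(nrow(truth))) {
      v <- vol_fun(truth$specimen[r], truth$condition[r], truth$configuration[r])
      fn <- sprintf("spec%02d_cond%d_%s.nii.gz", truth$specimen[r],
                    match(truth$condition[r], design$conditions),
                    truth$configuration[r])
      paths[r] <- file.path(dir, fn)
      write_labels(v, paths[r])
    }
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    out$paths <- data.frame(truth[, c("specimen", "condition", "configuration")],
                            path = paths)
  }
  out
}

#' Simulate a measurement-level study table
#'
#' Draws per-cell SCD values directly at the study-table level (no volumes):
#' value = specimen baseline + condition drift + load effect (+ increment) +
#' cell noise. Used for statistical power checks of the repeated-measures
#' layer.
#'
#' @param design A [study_design()]; `noise_sd_mm` is the between-specimen SD
#'   and `cell_noise_sd_mm` the residual cell SD.
#' @param baseline_mm Population baseline value.
#' @param measure Measure name for the table rows.
#' @param seed Optional seed overriding `design$seed`.
#' @return A [study_table()] with source "simulated".
#' @export
simulate_scd_table <- function(design, baseline_mm = 7.8,
                               measure = "compmean", seed = NULL) {
  d <- design
  if (!is.null(seed)) d$seed <- as.integer(seed)
  truth <- study_truth_table(d, list(gap_mm = baseline_mm))
  study_table(data.frame(specimen = truth$specimen,
                         condition = truth$condition,
                         configuration = truth$configuration,
                         measure = measure,
                         source = "simulated",
                         value = truth$true_gap_mm))
}
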