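#' Configuration of a measurement run
#'
#' Bundles everything a reproducible run needs: either a synthetic
#' [study_design()] (plus base [phantom_spec()]) or a manifest of volume
#' paths keyed by specimen/condition/configuration, the grid spacings, the
#' lateral exclusion fraction, interpolation mode, laterality, output
#' directory and seed.
#'
#' @param design Optional [study_design()] (synthetic study).
#' @param base [phantom_spec()] used with `design`.
#' @param manifest Optional data.frame with columns `specimen, condition,
#'   configuration, path` pointing at NIfTI label volumes.
#' @param spacing_ml,spacing_ap Grid spacings in mm (defaults 3.5 / 3.3).
#' @param exclusion_fraction Lateral exclusion fraction in [0, 0.5]
#'   (default 0.10).
#' @param interpolation "bilinear" (default) or "nearest".
#' @param laterality "left" or "right".
#' @param out_dir Output directory (default a tempdir subdirectory).
#' @param seed Integer seed (overrides `design$seed` when given).
#' @return Object of class `run_config`.
#' @export
run_config <- function(design = NULL, base = phantom_spec(), manifest = NULL,
                       spacing_ml = 3.5, spacing_ap = 3.3,
                       exclusion_fraction = 0.10,
                       interpolation = c("bilinear", "nearest"),
                       laterality = c("left", "right"),
                       out_dir = NULL, seed = NULL) {
  if (is.null(design) == is.null(manifest))
    stop_scd("exactly one of `design` or `manifest` must be given")
  if (exclusion_fraction < 0 || exclusion_fraction > 0.5)
    stop_scd("exclusion_fraction must be in [0, 0.5]")
  if (spacing_ml <= 0 || spacing_ap <= 0) stop_scd("grid spacings must be > 0")
  if (!is.null(seed) && !is.null(design)) design$seed <- as.integer(seed)
  structure(list(design = design, base = base, manifest = manifest,
                 spacing_ml = spacing_ml, spacing_ap = spacing_ap,
                 exclusion_fraction = exclusion_fraction,
                 interpolation = match.arg(interpolation),
                 laterality = match.arg(laterality),
                 out_dir = out_dir %||% file.path(tempdir(), "scdmap_run"),
                 seed = seed %||% (design$seed %||% NA_integer_)),
            class = "run_config")
}

#' Serialize / parse a run configuration
#'
#' JSON round trip of a [run_config()]: `parse_config(serialize_config(x))`
#' reproduces the configuration.
#'
#' @param config A [run_config()].
#' @param path Optional file to write to / read from.
#' @return `serialize_config`: JSON string (invisibly, if written to file);
#'   `parse_config`: a `run_config`.
#' @export
serialize_config <- function(config, path = NULL) {
  x <- unclass(config)
  x$design <- if (!is.null(x$design)) unclass(x$design)
  x$base <- unclass(x$base)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname serialize_config
#' @param json JSON string or path produced by [serialize_config()].
#' @export
parse_config <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  design <- if (!is.null(x$design)) do.call(study_design, x$design)
  base <- do.call(phantom_spec, x$base)
  run_config(design = design, base = base, manifest = x$manifest,
             spacing_ml = x$spacing_ml, spacing_ap = x$spacing_ap,
             exclusion_fraction = x$exclusion_fraction,
             interpolation = x$interpolation, laterality = x$laterality,
             out_dir = x$out_dir,
             seed = if (!is.null(x$seed) && !is.na(x$seed)) x$seed)
}

# Measure one specimen across all its conditions/configurations against its
# baseline-referenced grid. `get_volume(condition, configuration)` returns a
# label_volume.
measure_specimen <- function(specimen, get_volume, conditions, configurations,
                             config) {
  baseline <- get_volume(conditions[1], "UL")
  frame <- build_frame(baseline, laterality = config$laterality)
  te <- transepicondylar_axis(baseline, frame)
  surf0 <- extract_surfaces(baseline, frame)
  grid <- build_grid(surf0, spacing_ap = config$spacing_ap,
                     spacing_ml = config$spacing_ml)
  grid <- apply_lateral_exclusion(grid, te, fraction = config$exclusion_fraction)
  bbox0 <- attr(surf0, "bbox")

  rows <- list(); maps <- list()
  for (cond in conditions) for (cf in configurations) {
    vol <- if (cond == conditions[1] && cf == "UL") baseline
           else get_volume(cond, cf)
    surf <- extract_surfaces(vol, frame)
    map <- compute_scd_map(surf, grid, method = config$interpolation,
                           provenance = list(specimen = specimen,
                                             condition = cond,
                                             configuration = cf))
    sites <- manual_site_scd(surf, bbox = bbox0)
    maps[[paste(cond, cf)]] <- map
    rows[[paste(cond, cf)]] <- data.frame(
      specimen = specimen, condition = cond, configuration = cf,
      measure = c("compmean", sites$sites$site),
      source = "computational",
      value = c(scd_compmean(map), sites$sites$scd))
  }
  list(rows = do.call(rbind, rows), maps = maps,
       retained = sum(grid$retained), frame = frame, te = te)
}

#' Run a whole study through the measurement pipeline
#'
#' Orchestrates phantom generation (or volume loading), per-specimen frame /
#' grid construction, SCD mapping, loading-difference heat maps, and the
#' statistical layer into a deterministic output directory: `study_table.csv`,
#' `contrasts.csv`, per-condition heat maps (PNG + CSV), an ANOVA report,
#' and a machine-readable `manifest.json`. Rerunning with the same config
#' and seed is value-identical.
#'
#' @param config A [run_config()].
#' @param render Write heat-map PNGs (default TRUE).
#' @return List: `study_table`, `contrasts`, `anova`, `mean_maps`,
#'   `retained_points`, `truth` (synthetic runs), `out_dir`.
#' @export
run_study <- function(config, render = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  synthetic <- !is.null(config$design)
  if (synthetic) {
    study <- generate_study(config$design, config$base)
    conditions <- config$design$conditions
    configurations <- config$design$configurations
    specimens <- seq_len(config$design$n_specimens)
    volume_for <- function(sp) function(cond, cf) study$volume(sp, cond, cf)
  } else {
    mf <- config$manifest
    conditions <- intersect(scd_conditions(), unique(mf$condition))
    configurations <- intersect(scd_configurations(), unique(mf$configuration))
    specimens <- sort(unique(mf$specimen))
    volume_for <- function(sp) function(cond, cf) {
      p <- mf$path[mf$specimen == sp & mf$condition == cond &
                     mf$configuration == cf]
      if (length(p) != 1L)
        stop_scd("manifest: no volume for %s/%s/%s", sp, cond, cf,
                 class = "scdmap_io_error")
      read_labels(p)
    }
  }

  all_rows <- list(); all_maps <- list(); retained <- integer(0)
  for (sp in specimens) {
    res <- measure_specimen(sp, volume_for(sp), conditions, configurations,
                            config)
    all_rows[[as.character(sp)]] <- res$rows
    all_maps[[as.character(sp)]] <- res$maps
    retained[as.character(sp)] <- res$retained
  }
  tab <- study_table(do.call(rbind, c(all_rows, list(make.row.names = FALSE))))
  write.csv(tab, file.path(config$out_dir, "study_table.csv"), row.names = FALSE)

  mean_maps <- list()
  for (cond in conditions) {
    per_spec <- lapply(all_maps, function(m)
      difference_map(m[[paste(cond, "LO")]], m[[paste(cond, "UL")]]))
    avg <- average_maps(per_spec, condition = cond)
    mean_maps[[cond]] <- avg
    if (render) {
      safe <- gsub("[^A-Za-z0-9]+", "_", cond)
      render_heatmap(avg, file.path(config$out_dir,
                                    sprintf("%s_abs_diff.png", safe)))
    }
  }

  contrasts <- condition_contrasts(tab, "compmean", source = "computational")
  write.csv(contrasts, file.path(config$out_dir, "contrasts.csv"),
            row.names = FALSE)
  anova <- if (length(specimens) >= 3 && length(conditions) >= 2)
    rm_anova(tab, "compmean", source = "computational") else NULL
  if (!is.null(anova)) {
    con <- file(file.path(config$out_dir, "anova.txt"), "w")
    sink(con); print(anova); sink(); close(con)
  }

  manifest <- list(package = "scdmap",
                   version = as.character(utils::packageVersion("scdmap")),
                   seed = config$seed,
                   retained_points = as.list(retained),
                   config = jsonlite::fromJSON(serialize_config(config)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- list(study_table = tab, contrasts = contrasts, anova = anova,
              mean_maps = mean_maps, retained_points = retained,
              out_dir = config$out_dir)
  if (synthetic) {
    out$truth <- study$truth
    write.csv(study$truth, file.path(config$out_dir, "truth.csv"),
              row.names = FALSE)
  }
  invisible(out)
}
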