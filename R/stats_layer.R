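#' Construct / validate a long-format study table
#'
#' One row per (specimen, condition, configuration, measure, source); value
#' in mm. Conditions must come from the ordered set [scd_conditions()] and
#' configurations from [scd_configurations()].
#'
#' @param df data.frame with columns `specimen, condition, configuration,
#'   measure, source, value`.
#' @return The validated data.frame with class `study_table`.
#' @export
study_table <- function(df) {
  need <- c("specimen", "condition", "configuration", "measure", "source", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_scd("study table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(df$condition %in% scd_conditions()))
    stop_scd("conditions outside the ordered set: %s",
             paste(setdiff(unique(df$condition), scd_conditions()), collapse = ", "))
  if (!all(df$configuration %in% scd_configurations()))
    stop_scd("configurations must be in {%s}", paste(scd_configurations(), collapse = ", "))
  if (any(df$value < 0, na.rm = TRUE)) stop_scd("SCD values must be >= 0")
  key <- do.call(paste, c(df[c("specimen", "condition", "configuration",
                               "measure", "source")], sep = "\r"))
  if (anyDuplicated(key))
    stop_scd("duplicate (specimen, condition, configuration, measure, source) rows")
  class(df) <- unique(c("study_table", class(df)))
  df
}

#' Pool two readers' manual measurements
#'
#' Per matching (specimen, condition, configuration, measure) key, the
#' pooled value is the mean of the two readers; a `manmean` row (mean over
#' the six manual sites) is appended per specimen/condition/configuration.
#'
#' @param reader1,reader2 [study_table()]s (or plain data.frames) of the two
#'   readers' site measurements.
#' @param site_measures Names of the site measures entering `manmean`.
#' @return A [study_table()] with source "pooled".
#' @export
pool_readers <- function(reader1, reader2,
                         site_measures = c("ml1", "ml2", "ml3",
                                           "ap1", "ap2", "ap3")) {
  keys <- c("specimen", "condition", "configuration", "measure")
  m <- merge(reader1[, c(keys, "value")], reader2[, c(keys, "value")],
             by = keys, all = TRUE, suffixes = c("_r1", "_r2"))
  bad <- !complete.cases(m[, c("value_r1", "value_r2")])
  if (any(bad)) {
    off <- m[bad, keys]
    stop_scd("unmatched reader keys: %s",
             paste(utils::head(do.call(paste, c(off, sep = "/")), 5), collapse = "; "),
             class = "scdmap_pairing_error")
  }
  pooled <- data.frame(m[keys],
                       source = "pooled",
                       value = (m$value_r1 + m$value_r2) / 2)
  sites <- pooled[pooled$measure %in% site_measures, ]
  dt <- data.table::as.data.table(sites)
  mm <- dt[, list(measure = "manmean", source = "pooled",
                  value = mean(value), n_sites = .N),
           by = c("specimen", "condition", "configuration")]
  if (any(mm$n_sites != length(site_measures)))
    warn_scd("manmean averaged over fewer than %d sites for some cells",
             length(site_measures))
  mm$n_sites <- NULL
  study_table(rbind(pooled, as.data.frame(mm)[, names(pooled)]))
}

#' Two-reader intraclass correlation coefficient
#'
#' Single-measures ICC between two readers' paired values. The default
#' `"oneway"` form is the one-way random-effects, absolute-agreement,
#' single-scorer ICC(1,1); `"twoway"` gives the two-way random-effects
#' ICC(2,1) for comparison.
#'
#' @param reader1,reader2 Paired numeric vectors (>= 3 complete pairs).
#' @param type "oneway" (default) or "twoway".
#' @return List of class `scd_icc`: `value`, `type`, `n`. `value` is `NA`
#'   (flagged `undefined`) when the total variance is zero.
#' @export
icc_two_readers <- function(reader1, reader2, type = c("oneway", "twoway")) {
  type <- match.arg(type)
  ok <- complete.cases(cbind(reader1, reader2))
  x <- cbind(reader1[ok], reader2[ok])
  n <- nrow(x); k <- 2
  if (n < 3) stop_scd("need at least 3 paired observations, got %d", n)
  if (max(x) - min(x) < 1e-12)
    return(structure(list(value = NA_real_, type = type, n = n,
                          undefined = TRUE), class = "scd_icc"))
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssb <- k * sum((rowm - grand)^2)            # between targets
  ssw <- sum((x - rowm)^2)                    # within targets
  msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
  if (type == "oneway") {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
  } else {
    ssc <- n * sum((colm - grand)^2)          # readers
    sse <- ssw - ssc
    msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    icc <- (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n)
  }
  structure(list(value = icc, type = type, n = n, undefined = FALSE),
            class = "scd_icc")
}

#' @export
print.scd_icc <- function(x, ...) {
  cat(sprintf("ICC(%s, single measures): %s  [n = %d pairs]\n",
              if (x$type == "oneway") "1,1" else "2,1",
              if (x$undefined) "undefined (zero variance)" else sprintf("%.4f", x$value),
              x$n))
  invisible(x)
}

# Greenhouse-Geisser epsilon for one within-subject effect, from the
# covariance of the subject x cell matrix and an orthonormal basis A of the
# effect subspace.
gg_epsilon <- function(Sigma, A) {
  S <- t(A) %*% Sigma %*% A
  d <- ncol(A)
  tr <- function(M) sum(diag(M))
  eps <- tr(S)^2 / (d * tr(S %*% S))
  min(max(eps, 1 / d), 1)
}

#' Repeated-measures two-way ANOVA with Tukey post hocs
#'
#' Within-subject two-factor ANOVA (condition x configuration, both repeated
#' on every specimen) with interaction, for one measure of a study table.
#' F tests use the classic univariate partitioning with effect-by-specimen
#' error strata; sphericity-uncorrected and Greenhouse-Geisser-corrected
#' p-values are reported side by side. Pairwise Tukey-adjusted post hoc
#' comparisons between conditions are computed within each configuration.
#'
#' @param table A [study_table()].
#' @param measure Measure to analyse (e.g. "compmean").
#' @param source Source to analyse; may be omitted when unambiguous.
#' @param posthoc Compute Tukey post hocs (default TRUE; skip for speed in
#'   simulations).
#' @return Object of class `scd_anova`: `effects` (data.frame with F, df,
#'   p, GG epsilon and corrected p), `posthoc` (Tukey-adjusted pairs), and
#'   the fitted `aov` object.
#' @export
rm_anova <- function(table, measure, source = NULL, posthoc = TRUE) {
  d <- table[table$measure == measure, , drop = FALSE]
  if (!nrow(d)) stop_scd("no rows for measure '%s'", measure)
  if (is.null(source)) {
    if (length(unique(d$source)) > 1)
      stop_scd("measure '%s' has multiple sources (%s); pick one", measure,
               paste(unique(d$source), collapse = ", "))
  } else d <- d[d$source == source, , drop = FALSE]
  conds <- intersect(scd_conditions(), unique(d$condition))
  confs <- intersect(scd_configurations(), unique(d$configuration))
  specs <- sort(unique(d$specimen))
  full <- expand.grid(specimen = specs, condition = conds, configuration = confs,
                      stringsAsFactors = FALSE)
  key <- function(z) paste(z$specimen, z$condition, z$configuration, sep = "\r")
  missing_cells <- setdiff(key(full), key(d))
  if (length(missing_cells))
    stop_scd("incomplete crossed design; missing cells: %s",
             paste(gsub("\r", "/", utils::head(missing_cells, 5)), collapse = "; "),
             class = "scdmap_design_error")
  d$condition <- factor(d$condition, levels = conds)
  d$configuration <- factor(d$configuration, levels = confs)
  d$specimen <- factor(d$specimen)
  n <- length(specs); nc <- length(conds); nk <- length(confs)

  # do.call embeds the data in the call so emmeans can re-fit the model
  fit <- do.call(aov, list(value ~ condition * configuration +
                             Error(specimen / (condition * configuration)),
                           data = d))
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[paste0("Error: specimen:", stratum)]][[1]]
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tab)))
    r <- grep("Residuals", rownames(tab))
    ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[r, "Sum Sq"]
    df1 <- tab[i, "Df"]; df2 <- tab[r, "Df"]
    if (ss_e < 1e-12 && ss_r < 1e-12) {      # degenerate null data
      list(df1 = df1, df2 = df2, F = 0, p = 1)
    } else {
      Fv <- (ss_e / df1) / (ss_r / df2)
      list(df1 = df1, df2 = df2, F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE))
    }
  }
  eff <- list(condition = pull("condition", "condition"),
              configuration = pull("configuration", "configuration"),
              `condition:configuration` =
                pull("condition:configuration", "condition:configuration"))

  # GG epsilon from the subject x cell covariance
  wide <- matrix(NA_real_, n, nc * nk)
  cell_idx <- (as.integer(d$condition) - 1L) * nk + as.integer(d$configuration)
  wide[cbind(as.integer(d$specimen), cell_idx)] <- d$value
  Sigma <- cov(wide)
  orth <- function(m) qr.Q(qr(m))
  Qc <- orth(stats::contr.sum(nc)); Qk <- orth(stats::contr.sum(nk))
  one_c <- matrix(1 / sqrt(nc), nc, 1); one_k <- matrix(1 / sqrt(nk), nk, 1)
  bases <- list(condition = kronecker(Qc, one_k),
                configuration = kronecker(one_c, Qk),
                `condition:configuration` = kronecker(Qc, Qk))
  effects <- do.call(rbind, lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    epsv <- if (any(!is.finite(Sigma)) || sum(abs(Sigma)) < 1e-12) NA_real_
            else gg_epsilon(Sigma, bases[[nm]])
    p_gg <- if (is.na(epsv) || e$F == 0) e$p
            else pf(e$F, e$df1 * epsv, e$df2 * epsv, lower.tail = FALSE)
    data.frame(effect = nm, df1 = e$df1, df2 = e$df2, F = e$F, p = e$p,
               gg_epsilon = epsv, p_gg = p_gg)
  }))
  rownames(effects) <- NULL

  ph <- if (!posthoc) NULL else tryCatch({
    emm <- suppressMessages(emmeans::emmeans(fit, ~ condition | configuration,
                                             data = d))
    as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  }, error = function(e) {
    warn_scd("post hoc comparisons unavailable: %s", conditionMessage(e))
    NULL
  })
  structure(list(effects = effects, posthoc = ph, fit = fit,
                 measure = measure, n_specimens = n),
            class = "scd_anova")
}

#' @export
print.scd_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures two-way ANOVA on '%s' (n = %d specimens)\n",
              x$measure, x$n_specimens))
  print(transform(x$effects, F = round(F, 3), p = signif(p, 3),
                  gg_epsilon = round(gg_epsilon, 3), p_gg = signif(p_gg, 3)))
  invisible(x)
}

#' Condition-versus-intact contrasts of group means
#'
#' For each configuration, the difference of each condition's group mean
#' (over specimens, or the printed mean if the table holds one value per
#' cell) against the intact condition. Results are reported at full
#' precision and rounded to 0.1 mm.
#'
#' @param table A [study_table()] (or a printed-means table with one row per
#'   cell).
#' @param measure Measure name.
#' @param source Optional source filter.
#' @param reference Reference condition (default "intact").
#' @return data.frame: measure, configuration, condition, reference,
#'   delta_mm, delta_rounded_mm.
#' @export
condition_contrasts <- function(table, measure, source = NULL,
                                reference = "intact") {
  d <- table[table$measure == measure, , drop = FALSE]
  if (!is.null(source)) d <- d[d$source == source, , drop = FALSE]
  if (!nrow(d)) stop_scd("no rows for measure '%s'", measure)
  dt <- data.table::as.data.table(d)
  gm <- as.data.frame(dt[, list(mean = mean(value)),
                         by = c("condition", "configuration")])
  out <- list()
  for (cf in intersect(scd_configurations(), unique(gm$configuration))) {
    ref <- gm$mean[gm$condition == reference & gm$configuration == cf]
    if (!length(ref))
      stop_scd("reference condition '%s' missing for configuration %s",
               reference, cf, class = "scdmap_design_error")
    sub <- gm[gm$configuration == cf, ]
    sub <- sub[match(intersect(scd_conditions(), sub$condition), sub$condition), ]
    out[[cf]] <- data.frame(measure = measure, configuration = cf,
                            condition = sub$condition, reference = reference,
                            delta_mm = sub$mean - ref,
                            delta_rounded_mm = round(sub$mean - ref, 1))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-mean difference between two conditions
#'
#' `contrast_pair(t, m, cf, a, b)` = mean(a) - mean(b) within configuration
#' `cf`; antisymmetric in (a, b).
#'
#' @param table A [study_table()].
#' @param measure Measure name.
#' @param configuration "UL" or "LO".
#' @param cond_a,cond_b Condition labels.
#' @param source Optional source filter.
#' @return Difference of group means in mm.
#' @export
contrast_pair <- function(table, measure, configuration, cond_a, cond_b,
                          source = NULL) {
  d <- table[table$measure == measure & table$configuration == configuration, ,
             drop = FALSE]
  if (!is.null(source)) d <- d[d$source == source, , drop = FALSE]
  ma <- mean(d$value[d$condition == cond_a])
  mb <- mean(d$value[d$condition == cond_b])
  if (is.nan(ma) || is.nan(mb))
    stop_scd("missing group for contrast", class = "scdmap_design_error")
  ma - mb
}
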