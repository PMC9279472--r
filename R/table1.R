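#' Packaged table of printed group means
#'
#' The published study table of manually and computationally measured SCDs
#' (group mean and SD per measure, condition, and configuration; 10
#' specimens, values printed at 0.1 mm precision) is shipped as a CSV
#' fixture. It feeds the printed-mean contrast arithmetic of
#' [reproduce_table1_contrasts()].
#'
#' @param path Optional path to an alternative fixture CSV.
#' @return data.frame: method, measure, condition, configuration, mean_mm,
#'   sd_mm (140 rows).
#' @export
table1_means <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_means.csv",
                                package = "scdmap", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("method", "measure", "condition", "configuration", "mean_mm", "sd_mm")
  if (!all(need %in% names(df)) || nrow(df) != 140 ||
      any(!df$condition %in% scd_conditions()) ||
      any(!df$configuration %in% scd_configurations()) ||
      anyNA(df$mean_mm) || anyNA(df$sd_mm) ||
      any(df$mean_mm <= 0 | df$mean_mm > 50))
    stop_scd("printed-means fixture failed its integrity check: %s", path,
             class = "scdmap_checksum_error")
  want <- expand.grid(measure = c("manmean", "ml1", "ml2", "ml3",
                                  "ap1", "ap2", "ap3"),
                      condition = scd_conditions(),
                      configuration = scd_configurations())
  have <- paste(df$measure, df$condition, df$configuration)
  if (!all(paste(want$measure, want$condition, want$configuration) %in% have) ||
      sum(df$measure == "compmean") != 10)
    stop_scd("printed-means fixture is missing cells: %s", path,
             class = "scdmap_checksum_error")
  df
}

#' Headline loading/deficiency contrasts from the printed group means
#'
#' Recomputes, from the packaged printed means, the study's headline
#' contrast arithmetic: the additional loaded-configuration lateral opening
#' of each deficiency state versus the intact joint (for the manual
#' six-site mean and the computational compartment mean), and the
#' unloaded-configuration difference between the intact and fully deficient
#' joint. Printed means carry 0.1 mm precision, so the deltas are reported
#' rounded to 0.1 mm (`delta_mm`) alongside the raw floating-point
#' difference.
#'
#' @param fixture Optional data.frame from [table1_means()] (or a path).
#' @return data.frame: label, method, measure, configuration, condition,
#'   reference, delta_mm, delta_raw_mm.
#' @export
reproduce_table1_contrasts <- function(fixture = NULL) {
  tab <- if (is.character(fixture)) table1_means(fixture)
         else fixture %||% table1_means()
  mean_of <- function(method, measure, condition, configuration) {
    v <- tab$mean_mm[tab$method == method & tab$measure == measure &
                       tab$condition == condition &
                       tab$configuration == configuration]
    if (length(v) != 1L)
      stop_scd("fixture cell %s/%s/%s/%s not unique", method, measure,
               condition, configuration, class = "scdmap_checksum_error")
    v
  }
  spec <- list(
    list("manual_loaded_lcl_vs_intact", "manual", "manmean", "LO", "LCL"),
    list("computational_loaded_lcl_vs_intact", "computational", "compmean", "LO", "LCL"),
    list("manual_loaded_plc_vs_intact", "manual", "manmean", "LO", "LCL+PT+PFL"),
    list("computational_loaded_plc_vs_intact", "computational", "compmean", "LO", "LCL+PT+PFL"),
    list("manual_loaded_plc_acl_vs_intact", "manual", "manmean", "LO", "LCL+PT+PFL+ACL"),
    list("computational_loaded_plc_acl_vs_intact", "computational", "compmean", "LO", "LCL+PT+PFL+ACL"),
    list("manual_unloaded_plc_acl_vs_intact", "manual", "manmean", "UL", "LCL+PT+PFL+ACL"),
    list("computational_unloaded_plc_acl_vs_intact", "computational", "compmean", "UL", "LCL+PT+PFL+ACL"))
  out <- do.call(rbind, lapply(spec, function(s) {
    d <- mean_of(s[[2]], s[[3]], s[[5]], s[[4]]) -
      mean_of(s[[2]], s[[3]], "intact", s[[4]])
    data.frame(label = s[[1]], method = s[[2]], measure = s[[3]],
               configuration = s[[4]], condition = s[[5]],
               reference = "intact",
               delta_mm = round(d, 1), delta_raw_mm = d)
  }))
  rownames(out) <- NULL
  out
}
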