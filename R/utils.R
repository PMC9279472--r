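#' @importFrom stats aov cov pf rnorm sd setNames complete.cases approx contr.sum
#' @importFrom utils read.csv write.csv head
#' @importFrom data.table data.table as.data.table setnames :=
NULL

# Canonical label integers. The roles come from the segmentation protocol:
# femur, medial tibial condyle, lateral tibial condyle; 0 is background.
LABEL_FEMUR <- 1L
LABEL_TIBIA_MED <- 2L
LABEL_TIBIA_LAT <- 3L

#' Ordered condition labels of the graded posterolateral-corner injury model
#'
#' Five joint conditions from intact to combined PLC (LCL + popliteus tendon +
#' popliteofibular ligament) and ACL deficiency, in transection order.
#'
#' @return Character vector of length 5.
#' @export
scd_conditions <- function() {
  c("intact", "LCL", "LCL+PT", "LCL+PT+PFL", "LCL+PT+PFL+ACL")
}

#' Loading configurations
#'
#' @return Character vector: unloaded ("UL") and loaded ("LO").
#' @export
scd_configurations <- function() c("UL", "LO")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scd <- function(fmt, ..., class = "scdmap_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warn_scd <- function(fmt, ..., class = "scdmap_warning") {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "warning", "condition")))
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_scd("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Bilinear interpolation on a regular grid with NA-aware semantics: if any of
# the four corner cells is NA the result is NA (the caller decides how to mask).
# xg, yg: strictly increasing grid coordinates; Z: matrix [length(xg), length(yg)].
bilinear_na <- function(xg, yg, Z, xp, yp) {
  ix <- findInterval(xp, xg, rightmost.closed = TRUE)
  iy <- findInterval(yp, yg, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(xp))
  ok <- ix >= 1L & ix < length(xg) & iy >= 1L & iy < length(yg)
  # points exactly on the last grid line are handled by rightmost.closed
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- iy[ok]
  x1 <- xg[i]; x2 <- xg[i + 1L]; y1 <- yg[j]; y2 <- yg[j + 1L]
  wx <- (xp[ok] - x1) / (x2 - x1)
  wy <- (yp[ok] - y1) / (y2 - y1)
  z11 <- Z[cbind(i, j)]
  z21 <- Z[cbind(i + 1L, j)]
  z12 <- Z[cbind(i, j + 1L)]
  z22 <- Z[cbind(i + 1L, j + 1L)]
  out[ok] <- (1 - wx) * (1 - wy) * z11 + wx * (1 - wy) * z21 +
    (1 - wx) * wy * z12 + wx * wy * z22
  out
}
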