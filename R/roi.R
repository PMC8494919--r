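#' Region-of-interest mean of a scalar field
#'
#' Emulates the study's MRI fat-fraction readout: several small circular
#' regions of interest (default five, 5 mm^2 each) are placed in the liver,
#' the field is averaged over each disc by midpoint quadrature, and the mean
#' of the per-ROI means -- clipped to [0, 100] -- is reported.
#'
#' @param field a function \code{f(x, y)} returning the field value
#'   (percent) at cm coordinates, or a constant
#' @param roiCenters n x 2 matrix of ROI centres (cm)
#' @param liverPolygon polygon (cm) the ROIs must lie inside
#' @param roiAreaMM2 ROI area in mm^2 (default 5)
#' @param nGrid quadrature grid resolution per ROI (default 8)
#' @return mean of per-ROI means, clipped to [0, 100]
#' @examples
#' liver <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
#' roiMean(function(x, y) 6.2, rbind(c(2, 2)), liver)
#' @export
roiMean <- function(field, roiCenters, liverPolygon, roiAreaMM2 = 5,
                    nGrid = 8) {
  if (is.numeric(field) && length(field) == 1) {
    val <- field
    field <- function(x, y) rep(val, length(x))
  }
  roiCenters <- matrix(roiCenters, ncol = 2)
  if (nrow(roiCenters) < 1) stop("need at least one ROI", call. = FALSE)
  r <- sqrt(roiAreaMM2 / pi) / 10   # mm -> cm
  inside <- pointInPolygon(roiCenters, liverPolygon)
  if (!all(inside))
    stop("ROI centre(s) outside the liver region: ",
         paste(which(!inside), collapse = ", "), call. = FALSE)
  # midpoint quadrature over the disc
  g <- (seq_len(nGrid) - 0.5) / nGrid * 2 - 1
  gg <- expand.grid(x = g, y = g)
  keep <- gg$x^2 + gg$y^2 <= 1
  gg <- gg[keep, ]
  per <- vapply(seq_len(nrow(roiCenters)), function(i) {
    mean(field(roiCenters[i, 1] + r * gg$x, roiCenters[i, 2] + r * gg$y))
  }, numeric(1))
  min(100, max(0, mean(per)))
}
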