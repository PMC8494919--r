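#' Scatter plot with the linear-slope confidence band
#'
#' Mirrors the study's correlation figures: points, ordinary least-squares
#' line, shaded 95 percent confidence band of the slope, and the Pearson r
#' and p in the subtitle.
#'
#' @param x,y numeric vectors
#' @param xlab,ylab axis labels
#' @param level confidence level (default 0.95)
#' @return a ggplot object
#' @export
correlationPlot <- function(x, y, xlab = "x", ylab = "y", level = 0.95) {
  pc <- pearsonCorr(x, y)
  df <- data.frame(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = level,
                         colour = "steelblue", fill = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = sprintf("R = %.2f, p = %.3g, n = %d",
                                     pc$r, pc$p, pc$n)) +
    ggplot2::theme_minimal()
}

#' Render a conductivity map on its mesh
#'
#' Filled-triangle rendering of a per-element conductivity field, with the
#' electrode positions marked on the boundary.
#'
#' @param mesh a \code{\link{TriMesh}}
#' @param field a \code{\link{ConductivityField}},
#'   \code{\link{ReconstructionResult}} or numeric vector
#' @param main plot title
#' @param palette colour ramp function (default blue-white-red)
#' @return invisibly, the value range mapped to the palette
#' @export
plotConductivity <- function(mesh, field, main = "Conductivity (S/m)",
                             palette = NULL) {
  vals <- if (is(field, "ReconstructionResult")) field@sigma@values
          else if (is(field, "ConductivityField")) field@values
          else as.numeric(field)
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))
  rng <- range(vals)
  cols <- palette(64)[pmin(64L, pmax(1L, 1L + floor(
    63 * (vals - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps))))]
  graphics::plot(NA, xlim = range(mesh@nodes[, 1]), ylim = range(mesh@nodes[, 2]),
                 asp = 1, xlab = "x (cm)", ylab = "y (cm)", main = main)
  el <- mesh@elements
  for (e in seq_len(nrow(el))) {
    p <- mesh@nodes[el[e, ], ]
    graphics::polygon(p[, 1], p[, 2], col = cols[e], border = NA)
  }
  ctr <- mesh@nodes[mesh@electrodeCenters, , drop = FALSE]
  graphics::points(ctr[, 1], ctr[, 2], pch = 15, cex = 0.8)
  invisible(rng)
}
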