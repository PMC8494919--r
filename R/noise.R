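#' Corrupt a measurement set with seeded noise
#'
#' Adds measurement noise to simulated voltages under a stated model:
#' \code{"additive"} Gaussian with a fixed SD in volts, or
#' \code{"multiplicative"} Gaussian with a fixed relative fraction. The EIT
#' inverse problem is ill-posed, so small voltage perturbations are the
#' stress test of the regularized solver; identical seeds give bit-identical
#' outputs.
#'
#' @param data a \code{\link{MeasurementSet}}
#' @param type \code{"additive"} or \code{"multiplicative"}
#' @param sd additive noise SD in volts (additive model)
#' @param fraction relative noise SD (multiplicative model)
#' @param seed integer seed (required for reproducibility)
#' @return a \code{\link{MeasurementSet}} with the same shape and the noise
#'   model recorded
#' @examples
#' mesh <- buildPhantom(referencePhantom(), targetElementSize = 4)
#' pat <- makeSkipPattern(32, 4, current = 2)
#' clean <- solveForward(mesh, trueConductivity(mesh), pat)
#' noisy <- addNoise(clean, "multiplicative", fraction = 1e-3, seed = 7)
#' @export
addNoise <- function(data, type = c("additive", "multiplicative"),
                     sd = NULL, fraction = NULL, seed) {
  type <- match.arg(type)
  if (missing(seed) || !is.finite(seed))
    stop("a finite integer seed is required", call. = FALSE)
  v <- data@voltages
  if (type == "additive") {
    if (is.null(sd) || sd < 0) stop("additive noise needs sd >= 0", call. = FALSE)
    noiseModel <- list(type = "additive", sd = sd)
    scale <- rep(sd, length(v))
  } else {
    if (is.null(fraction) || fraction < 0)
      stop("multiplicative noise needs fraction >= 0", call. = FALSE)
    noiseModel <- list(type = "multiplicative", fraction = fraction)
    scale <- abs(v) * fraction
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  eps <- stats::rnorm(length(v)) * scale
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  new("MeasurementSet", pattern = data@pattern, voltages = v + eps,
      frequencyKHz = data@frequencyKHz, noiseModel = noiseModel,
      seed = as.integer(seed), meshId = data@meshId)
}

#' Noise level matching a relative target
#'
#' Helper converting a relative noise level (e.g. 0.1 percent) into the
#' additive SD used by \code{\link{addNoise}}: SD = level times the RMS of
#' the clean voltages.
#'
#' @param data a \code{\link{MeasurementSet}}
#' @param level relative level (0.001 for 0.1 percent)
#' @return additive SD in volts
#' @export
relativeNoiseSD <- function(data, level) {
  level * sqrt(mean(data@voltages^2))
}
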