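# J rows from port solutions: measurement k with drive port d, measurement
# port q and current I has dV_k/dsigma_e = -I * area_e * grad(w_d).grad(w_q)
# on element e (adjoint identity; exact for the discrete system because the
# stiffness matrix is linear in each element conductivity).
jacobianFromPorts <- function(ps) {
  fs <- ps$sys$fs
  Wn <- ps$W[seq_len(fs$n), , drop = FALSE]
  GxW <- as.matrix(fs$Gx %*% Wn)
  GyW <- as.matrix(fs$Gy %*% Wn)
  nk <- length(ps$pp$driveOf)
  J <- matrix(0, nk, fs$m)
  for (k in seq_len(nk)) {
    d <- ps$pp$driveOf[k]; q <- ps$pp$measOf[k]
    J[k, ] <- -ps$pp$currentA[k] * fs$areas *
      (GxW[, d] * GxW[, q] + GyW[, d] * GyW[, q])
  }
  J
}

#' Sensitivity matrix of the forward map
#'
#' Computes the Jacobian J of the boundary-voltage vector with respect to the
#' per-element conductivities at a linearization point, by the adjoint
#' method: entry (k, e) is minus the injected current times the integral over
#' element e of the dot product of the potential gradients of the drive and
#' measurement ports. One linear solve per distinct electrode pair suffices.
#'
#' @inheritParams solveForward
#' @param sigma linearization point (\code{\link{ConductivityField}})
#' @return a \code{\link{SensitivityMatrix}} (measurements x elements)
#' @examples
#' mesh <- buildPhantom(referencePhantom(nElectrodes = 8), targetElementSize = 6)
#' pat <- makeSkipPattern(8, 2, current = 2)
#' J <- jacobian(mesh, conductivityField(0.4, mesh), pat)
#' dim(J@entries)
#' @export
jacobian <- function(mesh, sigma, pattern,
                     electrodeModel = c("complete", "point"),
                     contactImpedance = 30) {
  electrodeModel <- match.arg(electrodeModel)
  ps <- solvePorts(mesh, sigma, pattern, electrodeModel, contactImpedance)
  if (is.numeric(sigma)) sigma <- conductivityField(sigma, mesh)
  new("SensitivityMatrix", entries = jacobianFromPorts(ps), sigma0 = sigma)
}

setMethod("show", "SensitivityMatrix", function(object) {
  cat(sprintf("SensitivityMatrix: %d measurements x %d elements, |J| range [%.3g, %.3g]\n",
              nrow(object@entries), ncol(object@entries),
              min(abs(object@entries)), max(abs(object@entries))))
})
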