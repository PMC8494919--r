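# Internal FEM structure for a mesh: linear (P1) triangles, piecewise
# constant conductivity. All lengths converted to metres here, so voltages
# come out in volts for currents in amperes on a unit-thickness slice; this
# is the one place the cm-to-m conversion happens.
femStructure <- function(mesh) {
  nodes <- mesh@nodes * 0.01          # cm -> m
  el <- mesh@elements
  n <- nrow(nodes); m <- nrow(el)
  p1 <- nodes[el[, 1], , drop = FALSE]
  p2 <- nodes[el[, 2], , drop = FALSE]
  p3 <- nodes[el[, 3], , drop = FALSE]
  A <- ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
          (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
  # gradient of basis i: rotate opposite edge by 90 degrees / (2A)
  bx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / (2 * A)
  by <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / (2 * A)
  # local stiffness per unit sigma: A * (b b^T)
  ii <- jj <- integer(9 * m); ss <- numeric(9 * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- el[, a]; jj[idx] <- el[, b]
    ss[idx] <- A * (bx[, a] * bx[, b] + by[, a] * by[, b])
    k <- k + 1L
  }
  Gx <- Matrix::sparseMatrix(i = rep(seq_len(m), 3), j = as.vector(el),
                             x = as.vector(bx), dims = c(m, n))
  Gy <- Matrix::sparseMatrix(i = rep(seq_len(m), 3), j = as.vector(el),
                             x = as.vector(by), dims = c(m, n))
  list(n = n, m = m, areas = A, ii = ii, jj = jj, ss = ss,
       eOf = rep(seq_len(m), times = 9L), elem = el, Gx = Gx, Gy = Gy)
}

# electrode boundary integrals (complete electrode model); z in ohm*m
electrodeIntegrals <- function(mesh) {
  be <- mesh@boundaryEdges
  nodes <- mesh@nodes * 0.01
  edgeLen <- sqrt(rowSums((nodes[be[, 2], , drop = FALSE] -
                             nodes[be[, 1], , drop = FALSE])^2))
  lapply(mesh@electrodeArcs, function(arcs) {
    rows <- lapply(seq_len(nrow(arcs)), function(r) {
      j <- as.integer(arcs[r, 1]); t0 <- arcs[r, 2]; t1 <- arcs[r, 3]
      le <- edgeLen[j]
      a <- be[j, 1]; b <- be[j, 2]
      i2 <- function(f) f(t1) - f(t0)
      maa <- le * i2(function(t) t - t^2 + t^3 / 3)     # int (1-t)^2
      mbb <- le * i2(function(t) t^3 / 3)               # int t^2
      mab <- le * i2(function(t) t^2 / 2 - t^3 / 3)     # int t(1-t)
      sa <- le * i2(function(t) t - t^2 / 2)            # int (1-t)
      sb <- le * i2(function(t) t^2 / 2)                # int t
      list(a = a, b = b, maa = maa, mbb = mbb, mab = mab,
           sa = sa, sb = sb, len = le * (t1 - t0))
    })
    list(rows = rows, length = sum(vapply(rows, `[[`, numeric(1), "len")))
  })
}

# Assemble the grounded linear system for a conductivity field.
# Returns list(A, n, L, model, portRHS(pair), extract(w, pair)).
#
# point model: unknowns [node potentials; multiplier], ground = zero-mean
#   potential; current enters at electrode centre nodes.
# complete model: unknowns [node potentials; electrode potentials;
#   multiplier], ground = zero-sum electrode potentials; contact impedance z
#   couples tissue and electrodes with shunting.
buildSystem <- function(mesh, sigma, electrodeModel = c("complete", "point"),
                        contactImpedance = 30, fs = NULL) {
  electrodeModel <- match.arg(electrodeModel)
  if (is(sigma, "ConductivityField")) {
    checkMeshMatch(mesh, sigma)
    sigma <- sigma@values
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("conductivity must be strictly positive", call. = FALSE)
  if (is.null(fs)) fs <- femStructure(mesh)
  if (length(sigma) != fs$m)
    stop("sigma must have one value per element", call. = FALSE)
  K <- Matrix::sparseMatrix(i = fs$ii, j = fs$jj, x = fs$ss * sigma[fs$eOf],
                            dims = c(fs$n, fs$n))
  n <- fs$n
  L <- length(mesh@electrodeNodes)
  if (electrodeModel == "point") {
    A <- rbind(cbind(K, Matrix::Matrix(1, n, 1)),
               cbind(Matrix::Matrix(1, 1, n), 0))
    centers <- mesh@electrodeCenters
    portRHS <- function(pairs) {
      B <- matrix(0, n + 1L, nrow(pairs))
      for (q in seq_len(nrow(pairs))) {
        B[centers[pairs[q, 1]], q] <- 1
        B[centers[pairs[q, 2]], q] <- -1
      }
      B
    }
    extract <- function(W, pairs)
      W[centers[pairs[, 1]], , drop = FALSE] - W[centers[pairs[, 2]], , drop = FALSE]
  } else {
    if (contactImpedance <= 0)
      stop("contactImpedance must be > 0 for the complete electrode model",
           call. = FALSE)
    z <- contactImpedance * 0.01   # ohm*cm -> ohm*m (per unit slice thickness)
    ei <- electrodeIntegrals(mesh)
    ti <- tj <- integer(0); tx <- numeric(0)
    vi <- vl <- integer(0); vx <- numeric(0)
    elen <- numeric(L)
    for (l in seq_len(L)) {
      elen[l] <- ei[[l]]$length
      if (elen[l] <= 0)
        stop("electrode ", l, " has zero covered arc length; widen electrodes ",
             "or refine the mesh", call. = FALSE)
      for (r in ei[[l]]$rows) {
        ti <- c(ti, r$a, r$b, r$a, r$b); tj <- c(tj, r$a, r$b, r$b, r$a)
        tx <- c(tx, r$maa, r$mbb, r$mab, r$mab)
        vi <- c(vi, r$a, r$b); vl <- c(vl, l, l); vx <- c(vx, r$sa, r$sb)
      }
    }
    M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx / z, dims = c(n, n))
    S <- Matrix::sparseMatrix(i = vi, j = vl, x = vx / z, dims = c(n, L))
    D <- Matrix::Diagonal(L, elen / z)
    A <- rbind(
      cbind(K + M, -S, Matrix::Matrix(0, n, 1)),
      cbind(Matrix::t(-S), D, Matrix::Matrix(1, L, 1)),
      cbind(Matrix::Matrix(0, 1, n), Matrix::Matrix(1, 1, L), 0))
    portRHS <- function(pairs) {
      B <- matrix(0, n + L + 1L, nrow(pairs))
      for (q in seq_len(nrow(pairs))) {
        B[n + pairs[q, 1], q] <- 1
        B[n + pairs[q, 2], q] <- -1
      }
      B
    }
    extract <- function(W, pairs)
      W[n + pairs[, 1], , drop = FALSE] - W[n + pairs[, 2], , drop = FALSE]
  }
  list(A = methods::as(A, "CsparseMatrix"), n = n, L = L,
       model = electrodeModel, portRHS = portRHS, extract = extract, fs = fs)
}

#' Assemble the finite-element system for a conductivity field
#'
#' Exposes the grounded linear system of the forward problem (conductivity
#' equation with either a point or a complete electrode model, grounded by a
#' zero-mean constraint) for inspection. The stiffness block is symmetric
#' positive-semidefinite and depends linearly on the per-element
#' conductivity.
#'
#' @param mesh a \code{\link{TriMesh}}
#' @param sigma a \code{\link{ConductivityField}} (or numeric vector)
#' @param electrodeModel \code{"complete"} (contact impedance + shunting,
#'   default) or \code{"point"} (current injected at electrode centre nodes;
#'   closed-form oracles exist for this mode)
#' @param contactImpedance contact impedance in ohm cm (complete model)
#' @return a list with the system matrix \code{A} (dgCMatrix, bordered by the
#'   grounding constraint), node count \code{n}, electrode count \code{L} and
#'   the model name
#' @export
assembleSystem <- function(mesh, sigma, electrodeModel = c("complete", "point"),
                           contactImpedance = 30) {
  sys <- buildSystem(mesh, sigma, electrodeModel, contactImpedance)
  sys[c("A", "n", "L", "model")]
}

# unique electrode ports (pairs) used by a pattern, plus index maps
patternPorts <- function(pattern) {
  idx <- measurementIndex(pattern)
  allPairs <- rbind(as.matrix(idx[, c("drive_pos", "drive_neg")]),
                    as.matrix(idx[, c("meas_pos", "meas_neg")]))
  key <- paste(allPairs[, 1], allPairs[, 2])
  ports <- allPairs[!duplicated(key), , drop = FALSE]
  portKey <- paste(ports[, 1], ports[, 2])
  list(ports = ports,
       driveOf = match(paste(idx$drive_pos, idx$drive_neg), portKey),
       measOf = match(paste(idx$meas_pos, idx$meas_neg), portKey),
       currentA = idx$current_mA * 1e-3,
       idx = idx)
}

# Solve all unit-current port problems once; everything downstream (voltages,
# Jacobian) is assembled from the port solutions.
solvePorts <- function(mesh, sigma, pattern,
                       electrodeModel = "complete", contactImpedance = 30,
                       fs = NULL) {
  sys <- buildSystem(mesh, sigma, electrodeModel, contactImpedance, fs = fs)
  pp <- patternPorts(pattern)
  B <- sys$portRHS(pp$ports)
  W <- as.matrix(Matrix::solve(sys$A, B))
  if (any(!is.finite(W)))
    stop("forward system solve failed (singular after grounding)", call. = FALSE)
  transfer <- sys$extract(W, pp$ports)     # ports x ports transfer impedances
  volts <- pp$currentA * transfer[cbind(pp$measOf, pp$driveOf)]
  list(sys = sys, pp = pp, W = W, voltages = volts)
}

#' Solve the forward problem for a stimulation pattern
#'
#' Computes noise-free differential boundary voltages for every
#' frame/measurement pair of the pattern by solving the conductivity
#' equation with the chosen electrode model. The potential is grounded by a
#' zero-mean constraint; differential voltages are independent of the ground
#' choice.
#'
#' @inheritParams assembleSystem
#' @param pattern a \code{\link{StimulationPattern}} addressing the mesh's
#'   electrode count
#' @param frequencyKHz metadata stored on the result (default 50, the channel
#'   the study reconstructed from)
#' @return a \code{\link{MeasurementSet}} with noise model \code{"none"}
#' @examples
#' mesh <- buildPhantom(referencePhantom(), targetElementSize = 4)
#' pat <- makeSkipPattern(32, 4, current = 2)
#' data <- solveForward(mesh, trueConductivity(mesh), pat)
#' @export
solveForward <- function(mesh, sigma, pattern,
                         electrodeModel = c("complete", "point"),
                         contactImpedance = 30, frequencyKHz = 50) {
  electrodeModel <- match.arg(electrodeModel)
  if (pattern@nElectrodes != length(mesh@electrodeNodes))
    stop("pattern electrode count does not match the mesh", call. = FALSE)
  ps <- solvePorts(mesh, sigma, pattern, electrodeModel, contactImpedance)
  new("MeasurementSet", pattern = pattern, voltages = ps$voltages,
      frequencyKHz = frequencyKHz, noiseModel = list(type = "none"),
      seed = NA_integer_, meshId = mesh@meshId)
}
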