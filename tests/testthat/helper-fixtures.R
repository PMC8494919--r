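# shared fixtures, built in code; heavier meshes are cached per test run

circlePoly <- function(r = 1, n = 64, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

diskSpec <- function(r = 8, sigma = 0.5, nElectrodes = 16,
                     electrodeWidth = 0.02, nPoly = 64) {
  phantomSpec(circlePoly(r, nPoly), list(), backgroundConductivity = sigma,
              nElectrodes = nElectrodes, electrodeWidth = electrodeWidth)
}

# minimal hand-built meshes (bypass buildPhantom) -----------------------------

# unit square split along the main diagonal into two P1 triangles
squareMesh2 <- function() {
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  elements <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  new("TriMesh", nodes = nodes, elements = elements,
      boundaryEdges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
      elementRegion = c("background", "background"),
      electrodeNodes = list(1L, 2L, 3L, 4L),
      electrodeCenters = c(1L, 2L, 3L, 4L),
      electrodeArcs = list(), regionConductivity = c(background = 1),
      meshId = "square2")
}

# unit square fanned around its centre into four triangles (cycle adjacency)
fanMesh4 <- function(region = rep("background", 4)) {
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  elements <- rbind(c(1L, 2L, 5L), c(2L, 3L, 5L), c(3L, 4L, 5L), c(4L, 1L, 5L))
  new("TriMesh", nodes = nodes, elements = elements,
      boundaryEdges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
      elementRegion = region,
      electrodeNodes = list(1L, 2L, 3L, 4L),
      electrodeCenters = c(1L, 2L, 3L, 4L),
      electrodeArcs = list(), regionConductivity = c(background = 1),
      meshId = "fan4")
}

# cached disk meshes (shared by forward/jacobian tests)
.meshCache <- new.env(parent = emptyenv())
cachedMesh <- function(key, builder) {
  if (is.null(.meshCache[[key]])) .meshCache[[key]] <- builder()
  .meshCache[[key]]
}

# closed-form boundary potential for a point current dipole on a homogeneous
# disk (unit-thickness 2-D): u(x) = (I / (pi * sigma)) * ln(|x - B| / |x - A|)
# for source at A, sink at B on the boundary
diskDipoleVoltages <- function(mesh, pattern, sigma) {
  idx <- liverEIT:::measurementIndex(pattern)
  centers <- mesh@nodes[mesh@electrodeCenters, , drop = FALSE] * 0.01
  I <- idx$current_mA * 1e-3
  d <- function(P, Q) sqrt(rowSums((P - Q)^2))
  A <- centers[idx$drive_pos, , drop = FALSE]
  B <- centers[idx$drive_neg, , drop = FALSE]
  M1 <- centers[idx$meas_pos, , drop = FALSE]
  M2 <- centers[idx$meas_neg, , drop = FALSE]
  (I / (pi * sigma)) *
    (log(d(M1, B) / d(M1, A)) - log(d(M2, B) / d(M2, A)))
}
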