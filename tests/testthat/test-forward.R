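test_that("P1 stiffness matches the hand-assembled two-triangle square", {
  mesh <- squareMesh2()
  fs <- liverEIT:::femStructure(mesh)
  K <- as.matrix(Matrix::sparseMatrix(i = fs$ii, j = fs$jj,
                                      x = fs$ss * rep(1, 2)[fs$eOf],
                                      dims = c(4, 4)))
  # hand assembly: both triangles are right isoceles; local matrix
  # 0.5*[[2,-1,-1],[-1,1,0],[-1,0,1]] in (right-angle, leg, leg) order
  Khand <- matrix(0, 4, 4)
  add <- function(K, nodes, loc) { K[nodes, nodes] <- K[nodes, nodes] + loc; K }
  loc1 <- 0.5 * rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1))   # (1,2,3)
  loc2 <- 0.5 * rbind(c(1, 0, -1), c(0, 1, -1), c(-1, -1, 2))   # (1,3,4)
  Khand <- add(Khand, c(1L, 2L, 3L), loc1)
  Khand <- add(Khand, c(1L, 3L, 4L), loc2)
  expect_equal(K, Khand, tolerance = 1e-12)
})

test_that("stiffness rows sum to zero before grounding and scale linearly in sigma", {
  mesh <- cachedMesh("disk16", function()
    buildPhantom(diskSpec(r = 8, nElectrodes = 16), targetElementSize = 1.6))
  sys1 <- assembleSystem(mesh, conductivityField(0.5, mesh),
                         electrodeModel = "point")
  n <- sys1$n
  K1 <- sys1$A[seq_len(n), seq_len(n)]
  expect_lt(max(abs(Matrix::rowSums(K1))), 1e-12)    # constants in the kernel
  sys2 <- assembleSystem(mesh, conductivityField(1.0, mesh),
                         electrodeModel = "point")
  K2 <- sys2$A[seq_len(n), seq_len(n)]
  expect_lt(max(abs(K2 - 2 * K1)), 1e-12)            # linear in sigma
  expect_error(assembleSystem(mesh, rep(-1, nElements(mesh))), "positive")
})

test_that("point-electrode disk voltages match the log-dipole closed form", {
  spec <- diskSpec(r = 8, sigma = 0.5, nElectrodes = 16, nPoly = 128)
  pat <- makeSkipPattern(16, 4, current = 2)
  mesh <- buildPhantom(spec, targetElementSize = 0.45)
  got <- voltages(solveForward(mesh, conductivityField(0.5, mesh), pat,
                               electrodeModel = "point"))
  want <- diskDipoleVoltages(mesh, pat, 0.5)
  expect_lt(max(abs(got - want)) / max(abs(want)), 0.01)
})

test_that("reciprocity and conductivity scaling hold to solver precision", {
  mesh <- cachedMesh("disk16", function()
    buildPhantom(diskSpec(r = 8, nElectrodes = 16), targetElementSize = 1.6))
  pat <- makeSkipPattern(16, 4, current = 2)
  for (model in c("point", "complete")) {
    v <- voltages(solveForward(mesh, conductivityField(0.5, mesh), pat,
                               electrodeModel = model))
    idx <- liverEIT:::measurementIndex(pat)
    # swapped drive/measurement roles appear within the skip pattern itself
    a <- which(idx$drive_pos == 1 & idx$meas_pos == 8)
    b <- which(idx$drive_pos == 8 & idx$meas_pos == 1)
    expect_lt(abs(v[a] - v[b]) / abs(v[a]), 1e-10)
  }
  v1 <- voltages(solveForward(mesh, conductivityField(0.5, mesh), pat,
                              electrodeModel = "point"))
  v3 <- voltages(solveForward(mesh, conductivityField(1.5, mesh), pat,
                              electrodeModel = "point"))
  expect_equal(v3 * 3, v1, tolerance = 1e-13)
})

test_that("voltages form a Cauchy sequence under mesh refinement", {
  spec <- diskSpec(r = 8, sigma = 0.5, nElectrodes = 16, nPoly = 128)
  pat <- makeSkipPattern(16, 4, current = 2)
  vs <- lapply(c(2, 1, 0.5), function(h) {
    mesh <- buildPhantom(spec, targetElementSize = h)
    voltages(solveForward(mesh, conductivityField(0.5, mesh), pat,
                          electrodeModel = "point"))
  })
  d12 <- max(abs(vs[[2]] - vs[[1]])) / max(abs(vs[[1]]))
  d23 <- max(abs(vs[[3]] - vs[[2]])) / max(abs(vs[[2]]))
  expect_lt(d23, d12)                                # contracting
  expect_lt(d23, 0.01)                               # < 1 % at finest levels
})

test_that("complete model approaches the point solution as z and width shrink", {
  pat <- makeSkipPattern(16, 4, current = 2)
  specWide <- diskSpec(r = 8, nElectrodes = 16, electrodeWidth = 0.002,
                       nPoly = 128)
  mesh <- buildPhantom(specWide, targetElementSize = 0.8)
  vp <- voltages(solveForward(mesh, conductivityField(0.5, mesh), pat,
                              electrodeModel = "point"))
  vc <- voltages(solveForward(mesh, conductivityField(0.5, mesh), pat,
                              electrodeModel = "complete",
                              contactImpedance = 0.01))
  expect_lt(max(abs(vc - vp)) / max(abs(vp)), 0.02)
})

test_that("seeded noise is reproducible and matches its stated model", {
  pat <- makeSkipPattern(40, 4, current = 2)    # 1480 measurements
  clean <- new("MeasurementSet", pattern = pat,
               voltages = rep(1e-3, nMeasurements(pat)), frequencyKHz = 50,
               noiseModel = list(type = "none"), seed = NA_integer_,
               meshId = "")
  expect_identical(voltages(addNoise(clean, "additive", sd = 0, seed = 3)),
                   voltages(clean))                         # sd 0 is identity
  n1 <- addNoise(clean, "additive", sd = 1e-4, seed = 9)
  n2 <- addNoise(clean, "additive", sd = 1e-4, seed = 9)
  expect_identical(voltages(n1), voltages(n2))              # determinism
  expect_false(identical(voltages(n1),
                         voltages(addNoise(clean, "additive", sd = 1e-4,
                                           seed = 10))))
  resid <- voltages(n1) - voltages(clean)
  expect_equal(sd(resid), 1e-4, tolerance = 0.1)            # stated SD, N >= 1000
  m <- addNoise(clean, "multiplicative", fraction = 0.01, seed = 5)
  expect_equal(sd(voltages(m) / voltages(clean) - 1), 0.01, tolerance = 0.1)
  expect_error(addNoise(clean, "additive", sd = -1, seed = 2), "sd >= 0")
  expect_error(addNoise(clean, "additive", sd = 1e-5), "seed")
})
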