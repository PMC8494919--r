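smallDisk <- function() cachedMesh("diskInv", function()
  buildPhantom(diskSpec(r = 8, sigma = 0.4, nElectrodes = 16,
                        electrodeWidth = 0.02), targetElementSize = 1.6))

test_that("Gauss-Newton step is a fixed point at zero residual", {
  mesh <- smallDisk()
  pat <- makeSkipPattern(16, 4, current = 2)
  sig <- conductivityField(0.4, mesh)
  data <- solveForward(mesh, sig, pat)
  J <- jacobian(mesh, sig, pat)
  G <- buildGamma(mesh)
  out <- gnStep(sig, data, J, regularization(lambda = 1e-8), G,
                residual = data@voltages - data@voltages, mesh = NULL)
  expect_equal(out@values, sig@values)
})

test_that("an overwhelming lambda confines the step to the smoothness kernel", {
  # the graph Laplacian annihilates constants, so even an enormous lambda
  # leaves the spatially constant component of the update free: the step
  # collapses onto a uniform shift and all spatial structure is suppressed
  mesh <- smallDisk()
  pat <- makeSkipPattern(16, 4, current = 2)
  sig <- conductivityField(0.35, mesh)
  truth <- conductivityField(0.45, mesh)
  data <- solveForward(mesh, truth, pat)
  J <- jacobian(mesh, sig, pat)
  G <- buildGamma(mesh)
  lamHuge <- 1e12 * sum(J@entries^2)
  out <- gnStep(sig, data, J, regularization(lambda = lamHuge), G,
                residual = data@voltages -
                  voltages(solveForward(mesh, sig, pat)), mesh = NULL)
  expect_lt(sd(out@values), 1e-8)                  # no spatial structure
  delta <- mean(out@values) - 0.35
  expect_gt(delta, 0)                              # shifts toward the truth
  expect_lt(mean(out@values), 0.46)
})

test_that("homogeneous truth is a fixed point of the iteration", {
  mesh <- smallDisk()
  pat <- makeSkipPattern(16, 4, current = 2)
  data <- solveForward(mesh, conductivityField(0.4, mesh), pat)
  rec <- reconstruct(mesh, data, sigma0 = 0.4, maxIter = 2)
  expect_equal(rec@sigma@values, rep(0.4, nElements(mesh)), tolerance = 1e-6)
})

test_that("noise-free homogeneous disk is recovered within 2 % from a wrong start", {
  mesh <- smallDisk()
  pat <- makeSkipPattern(16, 4, current = 2)
  data <- solveForward(mesh, conductivityField(0.4, mesh), pat)
  rec <- reconstruct(mesh, data, sigma0 = 0.2)
  expect_equal(mean(conductivity(rec)), 0.4, tolerance = 0.02)
  expect_true(rec@converged)
})

test_that("tol = Inf returns after a single iteration", {
  mesh <- smallDisk()
  pat <- makeSkipPattern(16, 4, current = 2)
  data <- solveForward(mesh, conductivityField(0.4, mesh), pat)
  rec <- reconstruct(mesh, data, sigma0 = 0.3, tol = Inf)
  expect_identical(rec@iterations, 1L)
  expect_true(rec@converged)
})

test_that("objective trace never increases and the field stays positive", {
  mesh <- buildPhantom(referencePhantom(), targetElementSize = 3)
  pat <- makeSkipPattern(32, 4, current = 2)
  clean <- solveForward(mesh, trueConductivity(mesh), pat)
  noisy <- addNoise(clean, "multiplicative", fraction = 1e-3, seed = 21)
  rec <- reconstruct(mesh, noisy, maxIter = 8)
  expect_true(all(diff(rec@objectiveTrace) <= 1e-12))
  expect_lte(rec@objectiveTrace[length(rec@objectiveTrace)],
             rec@objectiveTrace[1])
  expect_true(all(conductivity(rec) > 0))
  expect_equal(length(rec@residual), nMeasurements(pat))
})

test_that("the homogeneous reference fit recovers the true scalar", {
  mesh <- smallDisk()
  pat <- makeSkipPattern(16, 4, current = 2)
  data <- solveForward(mesh, conductivityField(0.4, mesh), pat)
  s0 <- liverEIT:::fitHomogeneousSigma(mesh, data)
  expect_equal(s0, 0.4, tolerance = 1e-6)
  s0p <- liverEIT:::fitHomogeneousSigma(
    mesh, solveForward(mesh, conductivityField(0.4, mesh), pat,
                       electrodeModel = "point"),
    electrodeModel = "point")
  expect_equal(s0p, 0.4, tolerance = 1e-12)        # closed form is exact here
})

test_that("liver statistics are area-weighted over the liver mask", {
  mesh <- fanMesh4(region = c("liver", "liver", "background", "background"))
  # constant field: mean is the constant, sd zero
  out <- liverConductivity(conductivityField(0.35, mesh), mesh)
  expect_equal(unname(out), c(0.35, 0))
  # two equal-area liver elements at 0.3 and 0.4 average to 0.35
  f <- conductivityField(c(0.3, 0.4, 1, 1), mesh)
  expect_equal(liverConductivity(f, mesh)[["mean"]], 0.35)
  expect_equal(liverConductivity(f, mesh)[["sd"]], 0.05)
  expect_error(liverConductivity(f, buildPhantom(diskSpec(),
                                                 targetElementSize = 2)),
               "not present")
})

test_that("liver estimates are robust over two decades of lambda", {
  pat <- makeSkipPattern(32, 4, current = 2)
  mesh <- buildPhantom(referencePhantom(), targetElementSize = 3)
  clean <- solveForward(mesh, trueConductivity(mesh), pat)
  noisy <- addNoise(clean, "additive", sd = relativeNoiseSD(clean, 0.001),
                    seed = 17)
  means <- vapply(c(1, 10, 100), function(alpha) {
    rec <- reconstruct(mesh, noisy, reg = regularization(alpha = alpha))
    liverConductivity(rec, mesh)[["mean"]]
  }, numeric(1))
  expect_lt((max(means) - min(means)) / mean(means), 0.15)
})

test_that("a noise-free inclusion phantom is recovered within 10 %", {
  pat <- makeSkipPattern(32, 4, current = 2)
  mesh <- buildPhantom(referencePhantom(), targetElementSize = 3)
  data <- solveForward(mesh, trueConductivity(mesh), pat)
  rec <- reconstruct(mesh, data)
  expect_equal(liverConductivity(rec, mesh)[["mean"]], 0.30, tolerance = 0.1)
  expect_equal(liverConductivity(rec, mesh, "background")[["mean"]], 0.45,
               tolerance = 0.1)
})
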