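test_that("unit-disk mesh reproduces the disk area with disjoint electrodes", {
  spec <- phantomSpec(circlePoly(1, 128), list(), backgroundConductivity = 1,
                      nElectrodes = 32, electrodeWidth = 0.01)
  mesh <- buildPhantom(spec, targetElementSize = 0.1)
  expect_equal(meshArea(mesh), pi, tolerance = 0.01)
  expect_length(mesh@electrodeNodes, 32)
  expect_false(anyDuplicated(unlist(mesh@electrodeNodes)) > 0)
  expect_true(all(liverEIT:::triangleAreas(mesh@nodes, mesh@elements) > 0))
})

test_that("region labelling recovers the liver polygon area (shoelace oracle)", {
  spec <- referencePhantom(semiAxes = c(30, 20))
  liverArea <- abs(polygonArea(spec@regions[[1]]$polygon))
  mesh <- buildPhantom(spec, targetElementSize = 2)
  got <- sum(liverEIT:::triangleAreas(mesh@nodes, mesh@elements)[
    regionMask(mesh, "liver")])
  expect_equal(got, liverArea, tolerance = 0.02)
  # centroid-in-polygon oracle: the mask is exactly the centroid predicate
  cent <- liverEIT:::elementCentroids(mesh@nodes, mesh@elements)
  expect_equal(sort(regionMask(mesh, "liver")),
               which(pointInPolygon(cent, spec@regions[[1]]$polygon)))
})

test_that("electrodes are equally spaced counter-clockwise and stable under refinement", {
  spec <- diskSpec(r = 4, nElectrodes = 8)
  mesh <- buildPhantom(spec, targetElementSize = 0.8)
  ctr <- mesh@nodes[mesh@electrodeCenters, ]
  ang <- atan2(ctr[, 2], ctr[, 1])
  ang <- (ang - ang[1]) %% (2 * pi)                   # unwrap from electrode 1
  expect_true(all(diff(ang) > 0))                     # counter-clockwise order
  gaps <- diff(c(ang, 2 * pi))
  edgeLen <- polygonPerimeter(spec@outline) /
    length(unique(mesh@boundaryEdges[, 1]))
  expect_true(all(abs(gaps - pi / 4) * 4 < edgeLen))  # arc gap = P/8 +- one edge
  fine <- buildPhantom(spec, targetElementSize = 0.4)
  drift <- sqrt(rowSums((fine@nodes[fine@electrodeCenters, ] - ctr)^2))
  expect_true(all(drift < edgeLen))
})

test_that("halving the element size changes total area by < 0.5 %", {
  spec <- referencePhantom()
  a1 <- meshArea(buildPhantom(spec, targetElementSize = 3))
  a2 <- meshArea(buildPhantom(spec, targetElementSize = 1.5))
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("mesh invariants hold: index ranges, closed boundary loop", {
  mesh <- buildPhantom(referencePhantom(withSpine = TRUE), targetElementSize = 2.5)
  expect_true(max(mesh@elements) <= nNodes(mesh))
  expect_true(min(mesh@elements) >= 1)
  be <- mesh@boundaryEdges
  expect_equal(be[, 2], c(be[-1, 1], be[1, 1]))       # single closed loop
  expect_setequal(unique(mesh@elementRegion), c("background", "liver", "spine"))
})

test_that("regionMask partitions elements and rejects absent labels", {
  mesh <- buildPhantom(diskSpec(), targetElementSize = 1.5)
  expect_equal(regionMask(mesh, "background"), seq_len(nElements(mesh)))
  mesh2 <- buildPhantom(referencePhantom(), targetElementSize = 3)
  liver <- regionMask(mesh2, "liver")
  bg <- regionMask(mesh2, "background")
  expect_setequal(c(liver, bg), seq_len(nElements(mesh2)))
  expect_length(intersect(liver, bg), 0)
  expect_error(regionMask(mesh2, "spine"), "not present")
})

test_that("too-coarse meshes fail with a resolution error", {
  tiny <- phantomSpec(circlePoly(10, 64),
                      list(list(label = "spine",
                                polygon = circlePoly(0.3, 12, center = c(4, 4)),
                                conductivity = 0.05)),
                      backgroundConductivity = 0.45)
  expect_error(buildPhantom(tiny, targetElementSize = 8), "too coarse")
  # the same region is resolved at adequate resolution
  mesh <- buildPhantom(tiny, targetElementSize = 0.3)
  expect_gt(length(regionMask(mesh, "spine")), 0)
})

test_that("mesh text format round-trips bit-exactly", {
  mesh <- buildPhantom(referencePhantom(), targetElementSize = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  writeMesh(mesh, path)
  back <- readMesh(path)
  expect_identical(back@nodes, mesh@nodes)
  expect_identical(back@elements, mesh@elements)
  expect_identical(back@boundaryEdges, mesh@boundaryEdges)
  expect_identical(back@elementRegion, mesh@elementRegion)
  expect_identical(back@electrodeNodes, mesh@electrodeNodes)
  expect_identical(back@electrodeCenters, mesh@electrodeCenters)
  expect_equal(back@electrodeArcs, mesh@electrodeArcs, tolerance = 0)
  expect_identical(back@regionConductivity, mesh@regionConductivity)
  expect_identical(back@meshId, mesh@meshId)
})

test_that("phantom JSON round-trips", {
  spec <- referencePhantom(withSpine = TRUE, withFat = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  writePhantomSpec(spec, path)
  back <- readPhantomSpec(path)
  expect_equal(back@outline, spec@outline)
  expect_equal(length(back@regions), 3L)
  expect_equal(back@regions[[1]]$conductivity, spec@regions[[1]]$conductivity)
  expect_equal(back@nElectrodes, spec@nElectrodes)
})

test_that("scalePhantom tracks the target waist perimeter", {
  spec <- referencePhantom()
  out <- scalePhantom(spec, waist = 100)
  expect_equal(polygonPerimeter(out@outline), 100, tolerance = 1e-10)
  expect_true(all(pointInPolygon(out@regions[[1]]$polygon, out@outline)))
})
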