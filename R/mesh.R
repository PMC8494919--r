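#' Triangulate a phantom into a finite-element mesh
#'
#' Builds a structured radial mesh of the phantom domain: the outline is
#' resampled at equal arc length (a multiple of the electrode count, so
#' electrode centres land exactly on boundary nodes), then concentric rings
#' shrink the boundary loop toward the area centroid. The outline must be
#' star-shaped about its centroid (true of elliptical abdominal sections).
#' Each element inherits the label of the innermost region polygon containing
#' its centroid; electrodes are centred at equally spaced arc-length
#' positions counter-clockwise starting from the positive-x axis.
#'
#' @param spec a valid \code{\link{PhantomSpec}}
#' @param targetElementSize target element edge length in cm (> 0)
#' @return a \code{\link{TriMesh}}
#' @examples
#' mesh <- buildPhantom(referencePhantom(), targetElementSize = 3)
#' nElements(mesh)
#' @export
buildPhantom <- function(spec, targetElementSize) {
  validObject(spec)
  if (!is.numeric(targetElementSize) || targetElementSize <= 0)
    stop("targetElementSize must be > 0", call. = FALSE)
  h <- targetElementSize
  outline <- ensureCCW(spec@outline)
  ctr <- polygonCentroid(outline)
  P <- polygonPerimeter(outline)
  nE <- spec@nElectrodes
  N <- nE * max(2L, as.integer(ceiling(P / (h * nE))))
  bnd <- resampleBoundary(outline, N, ctr)
  rmax <- max(sqrt(rowSums(sweep(bnd, 2, ctr)^2)))
  R <- max(2L, as.integer(ceiling(rmax / h)))

  # nodes: centre, then rings r = 1..R (ring R is the boundary)
  nodes <- matrix(0, nrow = 1 + N * R, ncol = 2)
  nodes[1, ] <- ctr
  for (r in seq_len(R)) {
    t <- r / R
    nodes[1 + (r - 1) * N + seq_len(N), ] <-
      sweep(sweep(bnd, 2, ctr) * t, 2, ctr, "+")
  }
  ringId <- function(r, j) 1L + (r - 1L) * N + ((j - 1L) %% N) + 1L

  j <- seq_len(N); jn <- j %% N + 1L
  fan <- cbind(1L, ringId(1L, j), ringId(1L, jn))
  quads <- NULL
  if (R >= 2L) {
    tri1 <- tri2 <- vector("list", R - 1L)
    for (r in seq_len(R - 1L)) {
      tri1[[r]] <- cbind(ringId(r, j), ringId(r + 1L, j), ringId(r + 1L, jn))
      tri2[[r]] <- cbind(ringId(r, j), ringId(r + 1L, jn), ringId(r, jn))
    }
    quads <- do.call(rbind, c(tri1, tri2))
  }
  elements <- rbind(fan, quads)
  storage.mode(elements) <- "integer"

  boundaryEdges <- cbind(ringId(R, j), ringId(R, jn))
  storage.mode(boundaryEdges) <- "integer"

  # region labels by innermost containing polygon (smallest area wins)
  cent <- elementCentroids(nodes, elements)
  region <- rep("background", nrow(elements))
  if (length(spec@regions)) {
    areas <- vapply(spec@regions, function(r) abs(polygonArea(r$polygon)), numeric(1))
    for (ri in order(areas, decreasing = TRUE)) {
      inside <- pointInPolygon(cent, spec@regions[[ri]]$polygon)
      region[inside] <- spec@regions[[ri]]$label
    }
    for (ri in seq_along(spec@regions)) {
      lab <- spec@regions[[ri]]$label
      if (!any(region == lab))
        stop(sprintf(paste0("targetElementSize %.3g cm too coarse to resolve ",
                            "region '%s'"), h, lab), call. = FALSE)
    }
  }

  # electrodes: centres at arc positions (i-1) * P/nE, boundary node arc
  # positions are (j-1) * P/N with N a multiple of nE
  m <- N %/% nE
  hw <- spec@electrodeWidth * P / 2
  ds <- P / N
  sNode <- (j - 1) * ds
  electrodeNodes <- vector("list", nE)
  electrodeCenters <- integer(nE)
  electrodeArcs <- vector("list", nE)
  for (i in seq_len(nE)) {
    sc <- (i - 1) * P / nE
    circd <- abs((sNode - sc + P / 2) %% P - P / 2)
    electrodeNodes[[i]] <- ringId(R, which(circd <= hw + 1e-9))
    electrodeCenters[i] <- ringId(R, (i - 1L) * m + 1L)
    # boundary-edge coverage of the arc window [sc - hw, sc + hw] (mod P)
    w0 <- sc - hw; w1 <- sc + hw
    cov <- list()
    for (jj in seq_len(N)) {
      e0 <- (jj - 1) * ds; e1 <- jj * ds
      for (shift in c(-P, 0, P)) {
        lo <- max(e0, w0 + shift); hi <- min(e1, w1 + shift)
        if (hi > lo + 1e-12)
          cov[[length(cov) + 1L]] <- c(edge = jj, t0 = (lo - e0) / ds,
                                       t1 = (hi - e0) / ds)
      }
    }
    electrodeArcs[[i]] <- do.call(rbind, cov)
  }

  rc <- c(vapply(spec@regions, function(r) r$conductivity, numeric(1)),
          spec@backgroundConductivity)
  names(rc) <- c(vapply(spec@regions, function(r) r$label, character(1)),
                 "background")

  new("TriMesh", nodes = nodes, elements = elements,
      boundaryEdges = boundaryEdges, elementRegion = region,
      electrodeNodes = electrodeNodes, electrodeCenters = electrodeCenters,
      electrodeArcs = electrodeArcs, regionConductivity = rc,
      meshId = sprintf("mesh-%d-%d-%.10e", nrow(nodes), nrow(elements),
                       sum(nodes)))
}

#' Construct a conductivity field on a mesh
#'
#' @param values per-element conductivities (S/m, > 0); a single value is
#'   recycled to all elements.
#' @param mesh the \code{\link{TriMesh}} the values index
#' @return a \code{\link{ConductivityField}}
#' @export
conductivityField <- function(values, mesh) {
  if (length(values) == 1L) values <- rep(values, nrow(mesh@elements))
  if (length(values) != nrow(mesh@elements))
    stop("values must have one entry per mesh element", call. = FALSE)
  new("ConductivityField", values = as.numeric(values), meshId = mesh@meshId)
}

checkMeshMatch <- function(mesh, obj) {
  if (nchar(obj@meshId) && obj@meshId != mesh@meshId)
    stop("object was built on a different mesh (meshId mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Total mesh area
#' @param mesh a \code{\link{TriMesh}}
#' @return sum of element areas (cm^2)
#' @export
meshArea <- function(mesh) sum(triangleAreas(mesh@nodes, mesh@elements))

setMethod("nNodes", "TriMesh", function(x) nrow(x@nodes))
setMethod("nElements", "TriMesh", function(x) nrow(x@elements))
setMethod("nElectrodes", "TriMesh", function(x) length(x@electrodeNodes))
setMethod("regionLabels", "TriMesh", function(x) unique(x@elementRegion))

setMethod("regionMask", "TriMesh", function(x, label) {
  if (!label %in% x@elementRegion)
    stop(sprintf("region label '%s' not present in mesh (have: %s)", label,
                 paste(unique(x@elementRegion), collapse = ", ")), call. = FALSE)
  which(x@elementRegion == label)
})

setMethod("conductivity", "ConductivityField", function(x) x@values)

setMethod("nElements", "ConductivityField", function(x) length(x@values))

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d nodes, %d elements, %d boundary edges, %d electrodes\n",
              nNodes(object), nElements(object), nrow(object@boundaryEdges),
              nElectrodes(object)))
  tab <- table(object@elementRegion)
  cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  total area %.2f cm^2\n", meshArea(object)))
})

setMethod("show", "ConductivityField", function(object) {
  cat(sprintf("ConductivityField: %d elements, range [%.4g, %.4g] S/m\n",
              length(object@values), min(object@values), max(object@values)))
})
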