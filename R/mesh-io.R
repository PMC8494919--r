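fmtG <- function(x) sprintf("%.17g", x)

#' Write / read a mesh in the plain-text exchange format
#'
#' Sectioned ASCII format (\code{# nodes}, \code{# elements} with region
#' label per row, \code{# boundary_edges}, \code{# electrode} blocks with the
#' centre node, member nodes and arc coverage, \code{# region_conductivity},
#' \code{# mesh_id}). Coordinates are written with 17 significant digits so a
#' write/read round trip is bit-exact.
#'
#' @param mesh a \code{\link{TriMesh}}
#' @param path file path
#' @return \code{readMesh} returns a \code{TriMesh}; \code{writeMesh} returns
#'   \code{path} invisibly.
#' @export
writeMesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# liverEIT mesh v1")
  wl("# mesh_id ", mesh@meshId)
  wl("# nodes ", nrow(mesh@nodes))
  writeLines(paste(fmtG(mesh@nodes[, 1]), fmtG(mesh@nodes[, 2])), con)
  wl("# elements ", nrow(mesh@elements))
  writeLines(paste(mesh@elements[, 1], mesh@elements[, 2], mesh@elements[, 3],
                   mesh@elementRegion), con)
  wl("# boundary_edges ", nrow(mesh@boundaryEdges))
  writeLines(paste(mesh@boundaryEdges[, 1], mesh@boundaryEdges[, 2]), con)
  wl("# region_conductivity ", length(mesh@regionConductivity))
  if (length(mesh@regionConductivity))
    writeLines(paste(names(mesh@regionConductivity),
                     fmtG(mesh@regionConductivity)), con)
  wl("# electrodes ", length(mesh@electrodeNodes))
  for (i in seq_along(mesh@electrodeNodes)) {
    wl("# electrode ", i, " center ", mesh@electrodeCenters[i],
       " nodes ", paste(mesh@electrodeNodes[[i]], collapse = " "))
    arcs <- mesh@electrodeArcs[[i]]
    wl("# electrode ", i, " arcs ", nrow(arcs))
    writeLines(paste(arcs[, 1], fmtG(arcs[, 2]), fmtG(arcs[, 3])), con)
  }
  invisible(path)
}

#' @rdname writeMesh
#' @export
readMesh <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  expectHeader <- function(prefix) {
    if (!startsWith(lines[pos], prefix))
      stop(sprintf("malformed mesh file: expected '%s' at line %d", prefix, pos),
           call. = FALSE)
    out <- lines[pos]; pos <<- pos + 1L
    out
  }
  takeBlock <- function(n) {
    out <- lines[pos + seq_len(n) - 1L]; pos <<- pos + n
    out
  }
  expectHeader("# liverEIT mesh v1")
  meshId <- sub("^# mesh_id ", "", expectHeader("# mesh_id"))
  nn <- as.integer(sub("^# nodes ", "", expectHeader("# nodes")))
  nodeRows <- strsplit(takeBlock(nn), " ", fixed = TRUE)
  nodes <- matrix(as.numeric(unlist(nodeRows)), ncol = 2, byrow = TRUE)
  ne <- as.integer(sub("^# elements ", "", expectHeader("# elements")))
  elRows <- strsplit(takeBlock(ne), " ", fixed = TRUE)
  elements <- matrix(as.integer(vapply(elRows, function(r) r[1:3], character(3))),
                     ncol = 3, byrow = TRUE)
  elementRegion <- vapply(elRows, `[`, character(1), 4L)
  nb <- as.integer(sub("^# boundary_edges ", "", expectHeader("# boundary_edges")))
  beRows <- strsplit(takeBlock(nb), " ", fixed = TRUE)
  boundaryEdges <- matrix(as.integer(unlist(beRows)), ncol = 2, byrow = TRUE)
  nrc <- as.integer(sub("^# region_conductivity ", "",
                        expectHeader("# region_conductivity")))
  rc <- numeric(0)
  if (nrc > 0) {
    rcRows <- strsplit(takeBlock(nrc), " ", fixed = TRUE)
    rc <- vapply(rcRows, function(r) as.numeric(r[2]), numeric(1))
    names(rc) <- vapply(rcRows, `[`, character(1), 1L)
  }
  nel <- as.integer(sub("^# electrodes ", "", expectHeader("# electrodes")))
  electrodeNodes <- vector("list", nel)
  electrodeCenters <- integer(nel)
  electrodeArcs <- vector("list", nel)
  for (i in seq_len(nel)) {
    hd <- expectHeader(sprintf("# electrode %d center", i))
    parts <- strsplit(hd, " ", fixed = TRUE)[[1]]
    electrodeCenters[i] <- as.integer(parts[5])
    electrodeNodes[[i]] <- as.integer(parts[-(1:6)])
    na <- as.integer(sub(sprintf("^# electrode %d arcs ", i), "",
                         expectHeader(sprintf("# electrode %d arcs", i))))
    arcRows <- strsplit(takeBlock(na), " ", fixed = TRUE)
    arcs <- matrix(as.numeric(unlist(arcRows)), ncol = 3, byrow = TRUE)
    colnames(arcs) <- c("edge", "t0", "t1")
    electrodeArcs[[i]] <- arcs
  }
  new("TriMesh", nodes = nodes, elements = elements,
      boundaryEdges = boundaryEdges, elementRegion = elementRegion,
      electrodeNodes = electrodeNodes, electrodeCenters = electrodeCenters,
      electrodeArcs = electrodeArcs, regionConductivity = rc, meshId = meshId)
}
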