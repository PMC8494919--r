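`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed polygon area (shoelace formula)
#'
#' @param poly numeric matrix (k x 2) of vertices; the closing edge is
#'   implicit. Positive for counter-clockwise orientation.
#' @return signed area in the square of the coordinate unit (cm^2 for
#'   phantom polygons)
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon perimeter
#' @param poly numeric matrix (k x 2) of vertices
#' @return total edge length (cm for phantom polygons)
#' @export
polygonPerimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1), , drop = FALSE] - poly
  sum(sqrt(rowSums(d^2)))
}

#' Point-in-polygon test
#'
#' Even-odd ray casting; points on an edge count as inside (adequate for
#' centroid labelling, where ties are measure-zero).
#'
#' @param pts numeric matrix (n x 2) or length-2 vector of query points
#' @param poly numeric matrix (k x 2) polygon vertices
#' @return logical vector of length n
#' @export
pointInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- poly[, 1]; py <- poly[, 2]
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1]; y <- pts[i, 2]
    crosses <- ((py > y) != (ny > y))
    if (!any(crosses)) return(FALSE)
    xint <- px[crosses] + (y - py[crosses]) * (nx[crosses] - px[crosses]) /
      (ny[crosses] - py[crosses])
    sum(xint > x) %% 2 == 1
  }, logical(1))
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#' @param poly numeric matrix (k x 2) of vertices
#' @return logical
#' @export
polygonIsSimple <- function(poly) {
  k <- nrow(poly)
  if (k < 3) return(FALSE)
  idx <- cbind(seq_len(k), c(2:k, 1))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      # skip edges sharing a vertex
      shared <- length(intersect(idx[i, ], idx[j, ])) > 0
      if (shared) next
      if (segmentsIntersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                            poly[idx[j, 1], ], poly[idx[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

# area centroid of a simple polygon
polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# force counter-clockwise orientation
ensureCCW <- function(poly) {
  if (polygonArea(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Re-parameterize a closed polygon to start at the intersection of the ray
# from `center` along +x with the polygon boundary, then resample `n` points
# at equal arc-length spacing (counter-clockwise). Returns the n x 2 matrix
# of boundary points; all points lie exactly on the original polygon edges.
resampleBoundary <- function(poly, n, center) {
  poly <- ensureCCW(poly)
  k <- nrow(poly)
  a <- poly; b <- poly[c(2:k, 1), , drop = FALSE]
  # ray-edge intersection: center + t*(1,0) = a + u*(b-a), 0 <= u < 1, t > 0
  hit <- NULL; hitEdge <- NA
  eps <- 1e-9
  for (i in seq_len(k)) {
    dy <- b[i, 2] - a[i, 2]
    if (dy == 0) next
    u <- (center[2] - a[i, 2]) / dy
    if (u < -eps || u >= 1 - eps) next   # vertex hits resolve to one edge
    u <- min(1, max(0, u))
    x <- a[i, 1] + u * (b[i, 1] - a[i, 1])
    t <- x - center[1]
    if (t <= 0) next
    if (is.null(hit) || t < hit[1]) { hit <- c(t, x); hitEdge <- i }
  }
  if (is.null(hit))
    stop("phantom centroid has no boundary intersection along +x; ",
         "outline must be star-shaped about its centroid", call. = FALSE)
  start <- c(hit[2], center[2])
  # rebuild vertex loop starting at the intersection point
  ord <- c(hitEdge:k, seq_len(hitEdge - 1))
  verts <- rbind(start, poly[c(if (hitEdge < k) (hitEdge + 1):k else integer(0),
                               seq_len(hitEdge)), , drop = FALSE])
  # cumulative arc length along the restarted loop
  segs <- rbind(verts[-1, , drop = FALSE], verts[1, , drop = FALSE]) - verts
  len <- sqrt(rowSums(segs^2))
  keep <- len > 1e-12
  verts <- verts[keep, , drop = FALSE]
  segs <- segs[keep, , drop = FALSE]
  len <- len[keep]
  cs <- c(0, cumsum(len))
  P <- cs[length(cs)]
  s <- (seq_len(n) - 1) * P / n
  seg <- findInterval(s, cs, rightmost.closed = TRUE)
  seg[seg > nrow(verts)] <- nrow(verts)
  frac <- (s - cs[seg]) / len[seg]
  verts[seg, , drop = FALSE] + segs[seg, , drop = FALSE] * frac
}

# positive areas of all triangles
triangleAreas <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
     (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

elementCentroids <- function(nodes, elements) {
  (nodes[elements[, 1], , drop = FALSE] +
     nodes[elements[, 2], , drop = FALSE] +
     nodes[elements[, 3], , drop = FALSE]) / 3
}
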