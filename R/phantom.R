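#' Create a phantom specification
#'
#' Convenience constructor for \code{\link{PhantomSpec}}. Coordinates are in
#' cm, conductivities in S/m.
#'
#' @param outline k x 2 matrix, simple closed polygon (cm).
#' @param regions list of regions, each \code{list(label=, polygon=,
#'   conductivity=)} with label in \code{liver}, \code{subcutaneous_fat},
#'   \code{spine}.
#' @param backgroundConductivity conductivity outside all regions (S/m).
#' @param nElectrodes electrode count (even, >= 8).
#' @param electrodeWidth electrode width as an arc-length fraction of the
#'   perimeter. The study hardware does not fix this; the packaged default
#'   0.012 corresponds to roughly 1.2 cm on a 96 cm belt, the footprint of a
#'   disposable ECG electrode.
#' @return a validated \code{PhantomSpec}
#' @export
phantomSpec <- function(outline, regions = list(),
                        backgroundConductivity = 0.45,
                        nElectrodes = 32L, electrodeWidth = 0.012) {
  new("PhantomSpec",
      outline = ensureCCW(as.matrix(outline)),
      regions = regions,
      backgroundConductivity = backgroundConductivity,
      nElectrodes = as.integer(nElectrodes),
      electrodeWidth = electrodeWidth)
}

ellipsePolygon <- function(center, a, b, n = 64, rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(rot) - y * sin(rot),
        center[2] + x * sin(rot) + y * cos(rot))
}

#' Reference abdomen phantom
#'
#' Elliptical abdominal cross-section (semi-axes 18 x 12 cm, perimeter about
#' 95 cm -- a typical overweight waistline) with a liver-shaped inclusion in
#' the right-upper quadrant. Default conductivities: soft-tissue background
#' 0.45 S/m, liver 0.30 S/m (a moderately fatty liver; healthy liver sits
#' near 0.35 S/m on the study's scale and conductivity falls as fat
#' fraction rises). Optional spine and subcutaneous fat regions make the
#' phantom less idealized.
#'
#' @param liverConductivity liver conductivity (S/m), default 0.30.
#' @param backgroundConductivity background conductivity (S/m), default 0.45.
#' @param semiAxes length-2, outline semi-axes in cm (default \code{c(18, 12)}).
#' @param withSpine include a low-conductivity spine disc (0.05 S/m).
#' @param withFat include a subcutaneous fat strip (0.08 S/m).
#' @param nElectrodes electrode count, default 32.
#' @return a \code{\link{PhantomSpec}}
#' @examples
#' spec <- referencePhantom()
#' mesh <- buildPhantom(spec, targetElementSize = 3)
#' @export
referencePhantom <- function(liverConductivity = 0.30,
                             backgroundConductivity = 0.45,
                             semiAxes = c(18, 12),
                             withSpine = FALSE, withFat = FALSE,
                             nElectrodes = 32L) {
  outline <- ellipsePolygon(c(0, 0), semiAxes[1], semiAxes[2], n = 96)
  sc <- semiAxes / c(18, 12)   # organ layout scales with the outline
  liver <- ellipsePolygon(c(-7 * sc[1], 2.5 * sc[2]), 6.5 * sc[1], 5 * sc[2],
                          n = 40, rot = -0.35)
  regions <- list(list(label = "liver", polygon = liver,
                       conductivity = liverConductivity))
  if (withSpine)
    regions <- c(regions, list(list(label = "spine",
      polygon = ellipsePolygon(c(0, -8.5 * sc[2]), 2 * sc[1], 2 * sc[2], n = 24),
      conductivity = 0.05)))
  if (withFat)
    regions <- c(regions, list(list(label = "subcutaneous_fat",
      polygon = ellipsePolygon(c(8 * sc[1], -5 * sc[2]), 4 * sc[1], 2.5 * sc[2],
                               n = 24, rot = 0.5),
      conductivity = 0.08)))
  phantomSpec(outline, regions,
              backgroundConductivity = backgroundConductivity,
              nElectrodes = nElectrodes)
}

#' True per-element conductivity of a phantom mesh
#'
#' Maps each element's region label to the conductivity the generating
#' \code{\link{PhantomSpec}} assigned it -- the ground-truth field for
#' simulation studies.
#'
#' @param mesh a \code{\link{TriMesh}} built by \code{\link{buildPhantom}}
#' @return a \code{\link{ConductivityField}}
#' @export
trueConductivity <- function(mesh) {
  rc <- mesh@regionConductivity
  if (!length(rc))
    stop("mesh carries no region conductivities (imported without a phantom spec)",
         call. = FALSE)
  vals <- unname(rc[mesh@elementRegion])
  if (anyNA(vals)) stop("element region without a stored conductivity", call. = FALSE)
  conductivityField(vals, mesh)
}

#' Scale a phantom to a target waist circumference
#'
#' Isotropically scales the outline and all region polygons about the outline
#' centroid so the outline perimeter equals \code{waist} cm, and optionally
#' re-assigns the liver conductivity. Used to derive subject-specific
#' phantoms from cohort records.
#'
#' @param spec a \code{\link{PhantomSpec}} with a liver region
#' @param waist target outline perimeter (cm)
#' @param liverConductivity optional new liver conductivity (S/m)
#' @return a scaled \code{PhantomSpec}
#' @export
scalePhantom <- function(spec, waist, liverConductivity = NULL) {
  s <- waist / polygonPerimeter(spec@outline)
  ctr <- polygonCentroid(spec@outline)
  scalePoly <- function(p) sweep(sweep(p, 2, ctr) * s, 2, ctr, "+")
  regions <- lapply(spec@regions, function(r) {
    r$polygon <- scalePoly(r$polygon)
    if (!is.null(liverConductivity) && r$label == "liver")
      r$conductivity <- liverConductivity
    r
  })
  new("PhantomSpec", outline = scalePoly(spec@outline), regions = regions,
      backgroundConductivity = spec@backgroundConductivity,
      nElectrodes = spec@nElectrodes, electrodeWidth = spec@electrodeWidth)
}

#' Write / read a phantom specification as JSON
#'
#' The JSON schema has fields \code{outline} (k x 2 array), \code{regions}
#' (objects with \code{label}, \code{polygon}, \code{conductivity}),
#' \code{background_conductivity}, \code{n_electrodes},
#' \code{electrode_width}. Round-trips exactly at full double precision.
#'
#' @param spec a \code{\link{PhantomSpec}}
#' @param path file path
#' @return \code{readPhantomSpec} returns a \code{PhantomSpec};
#'   \code{writePhantomSpec} returns \code{path} invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  obj <- list(
    outline = spec@outline,
    regions = lapply(spec@regions, function(r)
      list(label = r$label, polygon = r$polygon, conductivity = r$conductivity)),
    background_conductivity = spec@backgroundConductivity,
    n_electrodes = spec@nElectrodes,
    electrode_width = spec@electrodeWidth)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- list()
  if (length(obj$regions)) {
    if (is.data.frame(obj$regions)) {
      regions <- lapply(seq_len(nrow(obj$regions)), function(i)
        list(label = obj$regions$label[i],
             polygon = as.matrix(obj$regions$polygon[[i]]),
             conductivity = obj$regions$conductivity[i]))
    } else {
      regions <- lapply(obj$regions, function(r)
        list(label = r$label, polygon = as.matrix(r$polygon),
             conductivity = r$conductivity))
    }
  }
  phantomSpec(as.matrix(obj$outline), regions,
              backgroundConductivity = obj$background_conductivity,
              nElectrodes = obj$n_electrodes,
              electrodeWidth = obj$electrode_width)
}

setMethod("nElectrodes", "PhantomSpec", function(x) x@nElectrodes)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: outline %d vertices, perimeter %.1f cm, area %.1f cm^2\n",
              nrow(object@outline), polygonPerimeter(object@outline),
              abs(polygonArea(object@outline))))
  for (r in object@regions)
    cat(sprintf("  region %-16s area %7.1f cm^2  sigma %.3f S/m\n",
                r$label, abs(polygonArea(r$polygon)), r$conductivity))
  cat(sprintf("  background sigma %.3f S/m; %d electrodes, width %.3f of perimeter\n",
              object@backgroundConductivity, object@nElectrodes,
              object@electrodeWidth))
})
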