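#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve diag
NULL

REGION_LABELS <- c("liver", "subcutaneous_fat", "spine", "background")

#' Parametric 2-D abdomen phantom specification
#'
#' A \code{PhantomSpec} describes a 2-D abdominal cross-section as a closed
#' outline polygon (cm) with labelled internal organ polygons, each carrying a
#' true electrical conductivity (S/m), plus an electrode belt layout. It is
#' the geometric input realized into a finite-element mesh by
#' \code{\link{buildPhantom}}.
#'
#' @slot outline numeric matrix (k x 2), vertices of a simple closed polygon
#'   in cm (the closing edge is implicit).
#' @slot regions list of internal regions; each element is a list with
#'   entries \code{label} (one of \code{"liver"}, \code{"subcutaneous_fat"},
#'   \code{"spine"}), \code{polygon} (matrix, cm) and \code{conductivity}
#'   (S/m).
#' @slot backgroundConductivity conductivity (S/m) of tissue outside every
#'   region polygon.
#' @slot nElectrodes number of belt electrodes (even, >= 8; default 32).
#' @slot electrodeWidth electrode width as a fraction of the outline
#'   perimeter (must satisfy \code{electrodeWidth < 1/nElectrodes} so
#'   electrodes do not touch).
#'
#' @seealso \code{\link{phantomSpec}}, \code{\link{referencePhantom}},
#'   \code{\link{buildPhantom}}
#' @export
setClass("PhantomSpec",
  representation(
    outline = "matrix",
    regions = "list",
    backgroundConductivity = "numeric",
    nElectrodes = "integer",
    electrodeWidth = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  o <- object@outline
  if (!is.numeric(o) || ncol(o) != 2 || nrow(o) < 3)
    msg <- c(msg, "outline must be a numeric matrix with >= 3 rows and 2 columns")
  else {
    if (anyNA(o)) msg <- c(msg, "outline contains NA")
    else if (!polygonIsSimple(o))
      msg <- c(msg, "outline polygon is self-intersecting")
  }
  labs <- vapply(object@regions, function(r) r$label %||% NA_character_, character(1))
  if (anyDuplicated(labs)) msg <- c(msg, "region labels must be unique")
  if (length(labs) && !all(labs %in% setdiff(REGION_LABELS, "background")))
    msg <- c(msg, sprintf("region labels must be in {%s}",
                          paste(setdiff(REGION_LABELS, "background"), collapse = ", ")))
  for (r in object@regions) {
    if (!is.matrix(r$polygon) || ncol(r$polygon) != 2 || nrow(r$polygon) < 3)
      msg <- c(msg, "each region polygon must be a k x 2 matrix with k >= 3")
    else if (is.matrix(o) && ncol(o) == 2 && nrow(o) >= 3 &&
             !all(pointInPolygon(r$polygon, o)))
      msg <- c(msg, sprintf("region '%s' is not inside the outline", r$label))
    if (!is.numeric(r$conductivity) || length(r$conductivity) != 1 || r$conductivity <= 0)
      msg <- c(msg, sprintf("region '%s' needs a single positive conductivity", r$label))
  }
  if (length(object@backgroundConductivity) != 1 || object@backgroundConductivity <= 0)
    msg <- c(msg, "backgroundConductivity must be a single positive value")
  ne <- object@nElectrodes
  if (length(ne) != 1 || ne < 8L || ne %% 2L != 0L)
    msg <- c(msg, "nElectrodes must be even and >= 8")
  w <- object@electrodeWidth
  if (length(w) != 1 || w <= 0 || w >= 1 / max(ne, 1L))
    msg <- c(msg, "electrodeWidth must be in (0, 1/nElectrodes)")
  if (length(msg)) msg else TRUE
})

#' Triangulated finite-element mesh of a phantom
#'
#' Linear-triangle mesh of a 2-D phantom domain. Nodes are in cm; every
#' element carries the anatomical label of the innermost region polygon
#' containing its centroid, which parameterizes the weighted Laplacian prior
#' of the inverse solver.
#'
#' @slot nodes numeric matrix (n x 2), node coordinates in cm.
#' @slot elements integer matrix (m x 3), node indices of each triangle,
#'   counter-clockwise.
#' @slot boundaryEdges integer matrix (k x 2), ordered node pairs tracing the
#'   outline counter-clockwise as a single closed loop.
#' @slot elementRegion character vector of length m, region label per element.
#' @slot electrodeNodes list (one entry per electrode, counter-clockwise) of
#'   boundary node indices under that electrode.
#' @slot electrodeCenters integer vector, the boundary node at each electrode
#'   centre (used by the point electrode model).
#' @slot electrodeArcs list of per-electrode edge coverage used by the
#'   complete electrode model: integer edge index, fractional interval
#'   \code{t0},\code{t1} along the edge.
#' @slot regionConductivity named numeric vector, the true conductivity (S/m)
#'   each label had in the generating \code{PhantomSpec} (empty for imported
#'   meshes without one).
#' @slot meshId character, identifier tying \code{\link{ConductivityField}}
#'   and \code{\link{MeasurementSet}} objects back to this mesh.
#' @export
setClass("TriMesh",
  representation(
    nodes = "matrix",
    elements = "matrix",
    boundaryEdges = "matrix",
    elementRegion = "character",
    electrodeNodes = "list",
    electrodeCenters = "integer",
    electrodeArcs = "list",
    regionConductivity = "numeric",
    meshId = "character"
  )
)

setValidity("TriMesh", function(object) {
  msg <- character()
  n <- nrow(object@nodes)
  el <- object@elements
  if (ncol(object@nodes) != 2) msg <- c(msg, "nodes must be n x 2")
  if (ncol(el) != 3) msg <- c(msg, "elements must be m x 3")
  idx <- c(el, object@boundaryEdges, unlist(object@electrodeNodes),
           object@electrodeCenters)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    msg <- c(msg, "node index out of range")
  ar <- triangleAreas(object@nodes, el)
  if (any(ar <= 0)) msg <- c(msg, "all elements must have positive signed area")
  if (length(object@elementRegion) != nrow(el))
    msg <- c(msg, "elementRegion must label every element")
  be <- object@boundaryEdges
  if (nrow(be) > 0 && !all(be[, 2] == c(be[-1, 1], be[1, 1])))
    msg <- c(msg, "boundary edges must form a single closed loop")
  en <- object@electrodeNodes
  if (any(vapply(en, length, integer(1)) < 1L))
    msg <- c(msg, "every electrode must own at least one boundary node")
  allEn <- unlist(en)
  if (anyDuplicated(allEn)) msg <- c(msg, "electrode node sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Per-element conductivity field
#'
#' The piecewise-constant conductivity sigma (S/m) on the elements of a
#' \code{\link{TriMesh}} -- the unknown of the EIT inverse problem and the
#' coefficient of the forward conductivity equation.
#'
#' @slot values numeric vector, one strictly positive conductivity (S/m) per
#'   mesh element.
#' @slot meshId identifier of the mesh the values index.
#' @export
setClass("ConductivityField",
  representation(values = "numeric", meshId = "character")
)

setValidity("ConductivityField", function(object) {
  if (length(object@values) < 1L) return("values must be non-empty")
  if (anyNA(object@values) || any(object@values <= 0))
    return("conductivity values must be strictly positive and finite")
  TRUE
})

#' Stimulation/measurement pattern
#'
#' Ordered current-injection frames. Each frame drives one electrode pair
#' with a stated current (mA) and records differential voltages on a list of
#' measurement electrode pairs, none of which touches a drive electrode.
#'
#' @slot nElectrodes number of belt electrodes the pattern addresses.
#' @slot skip number of electrodes skipped between the members of a pair
#'   (drive and measurement pairs are separated by \code{skip + 1} positions).
#' @slot frames list of frames, each a list with \code{drive} (integer pair,
#'   +I then -I), \code{current} (mA) and \code{measPairs} (integer matrix,
#'   one row per measurement pair, +V then -V).
#' @export
setClass("StimulationPattern",
  representation(nElectrodes = "integer", skip = "integer", frames = "list")
)

setValidity("StimulationPattern", function(object) {
  if (length(object@frames) < 1L) return("frame list must be non-empty")
  for (f in object@frames) {
    if (f$drive[1] == f$drive[2]) return("drive electrodes must be distinct")
    if (nrow(f$measPairs) && any(f$measPairs %in% f$drive))
      return("measurement pairs must not include a drive electrode")
  }
  TRUE
})

#' Boundary-voltage measurement set
#'
#' The voltages recorded (or simulated) under a \code{StimulationPattern}:
#' the data vector of the inverse problem. Voltages are stacked frame by
#' frame in pattern order.
#'
#' @slot pattern the \code{\link{StimulationPattern}} that produced the data.
#' @slot voltages numeric vector of differential voltages (V), one per
#'   frame/measurement-pair in pattern order.
#' @slot frequencyKHz metadata: acquisition frequency in kHz (the study used
#'   50 kHz data for reconstruction; 250 kHz was also acquired).
#' @slot noiseModel list describing applied noise: \code{type} one of
#'   \code{"none"}, \code{"additive"} (with \code{sd}, V), or
#'   \code{"multiplicative"} (with \code{fraction}).
#' @slot seed integer seed used when noise was applied (NA when none).
#' @slot meshId mesh identifier when simulated ("" for imported data).
#' @export
setClass("MeasurementSet",
  representation(
    pattern = "StimulationPattern",
    voltages = "numeric",
    frequencyKHz = "numeric",
    noiseModel = "list",
    seed = "integer",
    meshId = "character"
  )
)

setValidity("MeasurementSet", function(object) {
  nv <- sum(vapply(object@pattern@frames, function(f) nrow(f$measPairs), integer(1)))
  if (length(object@voltages) != nv)
    return(sprintf("voltage vector length %d does not match pattern (%d measurements)",
                   length(object@voltages), nv))
  if (anyNA(object@voltages)) return("voltages contain NA")
  TRUE
})

#' Tikhonov regularization settings
#'
#' Parameters of the regularized Gauss-Newton update: the Tikhonov weight
#' lambda and the edge weights of the anatomically weighted Laplacian prior
#' (full weight between neighbouring elements of the same region, reduced
#' weight across organ boundaries so conductivity may jump there).
#'
#' @slot lambda regularization parameter lambda >= 0; \code{NA} selects the
#'   scale-invariant default \code{alpha * tr(J'J) / tr(G'G)} at the first
#'   iteration.
#' @slot alpha scale factor for the automatic lambda (default 0.01).
#' @slot withinWeight Laplacian weight for element adjacencies within one
#'   region (> 0, default 1).
#' @slot crossWeight weight for adjacencies across region boundaries
#'   (0 <= crossWeight <= withinWeight, default 0.05).
#' @seealso \code{\link{buildGamma}}, \code{\link{reconstruct}}
#' @export
setClass("Regularization",
  representation(lambda = "numeric", alpha = "numeric",
                 withinWeight = "numeric", crossWeight = "numeric")
)

setValidity("Regularization", function(object) {
  if (!is.na(object@lambda) && object@lambda < 0) return("lambda must be >= 0")
  if (object@withinWeight <= 0) return("withinWeight must be > 0")
  if (object@crossWeight < 0 || object@crossWeight > object@withinWeight)
    return("crossWeight must satisfy 0 <= crossWeight <= withinWeight")
  TRUE
})

#' Jacobian of the forward map
#'
#' Sensitivity matrix J with one row per measurement and one column per mesh
#' element: entry (k, e) is the derivative of measurement k with respect to
#' the conductivity of element e at the linearization point, computed by the
#' adjoint method.
#'
#' @slot entries numeric matrix (measurements x elements).
#' @slot sigma0 the \code{\link{ConductivityField}} at which J was linearized.
#' @export
setClass("SensitivityMatrix",
  representation(entries = "matrix", sigma0 = "ConductivityField")
)

setValidity("SensitivityMatrix", function(object) {
  if (!all(is.finite(object@entries))) return("Jacobian entries must be finite")
  if (ncol(object@entries) != length(object@sigma0@values))
    return("column count must equal element count of the linearization point")
  TRUE
})

#' Result of an iterated Gauss-Newton reconstruction
#'
#' @slot sigma the converged absolute \code{\link{ConductivityField}} (S/m).
#' @slot objectiveTrace L2 data-misfit \code{||Vo - f(sigma_n)||} per
#'   iteration (index 1 = initial field); non-increasing after damping.
#' @slot iterations number of accepted Gauss-Newton iterations.
#' @slot converged whether the relative-change stopping rule was met.
#' @slot lambdaUsed the Tikhonov lambda actually applied.
#' @slot sigma0 the homogeneous starting/reference conductivity (S/m).
#' @slot residual final residual vector Vo - f(sigma_n) (V).
#' @export
setClass("ReconstructionResult",
  representation(
    sigma = "ConductivityField",
    objectiveTrace = "numeric",
    iterations = "integer",
    converged = "logical",
    lambdaUsed = "numeric",
    sigma0 = "numeric",
    residual = "numeric"
  )
)

#' Synthetic overweight-cohort specification
#'
#' Parameters of the synthetic cohort generator: subjects carry an MRI-style
#' liver fat fraction (PDFF, percent) drawn over a stated range, a liver
#' conductivity generated by a monotone-decreasing linear map
#' \code{sigma = intercept - slope * PDFF} plus Gaussian measurement noise,
#' and demographics drawn independently of PDFF.
#'
#' @slot nSubjects number of subjects.
#' @slot pdffRange numeric length-2, PDFF range in percent (default 1-28,
#'   the span of the packaged study table).
#' @slot mapIntercept intercept a of the conductivity map (S/m).
#' @slot mapSlope slope b > 0 (S/m per PDFF percent); conductivity decreases
#'   with fat fraction.
#' @slot noiseSD SD of additive conductivity noise (S/m).
#' @slot exclusionRate expected fraction of subjects flagged with a
#'   confounding condition (electrode malfunction, renal failure, leukemia).
#' @slot seed integer seed making generation reproducible.
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer", pdffRange = "numeric",
    mapIntercept = "numeric", mapSlope = "numeric", noiseSD = "numeric",
    exclusionRate = "numeric", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  pr <- object@pdffRange
  if (length(pr) != 2 || pr[1] < 0 || pr[2] > 100 || pr[1] >= pr[2])
    return("pdffRange must be an increasing pair within [0, 100]")
  if (object@mapSlope <= 0) return("mapSlope must be > 0 (decreasing map)")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@mapIntercept - object@mapSlope * pr[2] <= 0)
    return("conductivity map must stay positive over the PDFF range")
  if (object@exclusionRate < 0 || object@exclusionRate >= 1)
    return("exclusionRate must be in [0, 1)")
  TRUE
})

#' Cohort table with an exclusion policy
#'
#' Per-subject records (demographics, MRI PDFF, EIT liver conductivity,
#' exclusion flags) together with the exclusion policy under which analyses
#' are run: \code{"none"} keeps all subjects, \code{"study_n16"} removes
#' subjects flagged for electrode malfunction, renal failure and leukemia,
#' \code{"study_n18"} removes only the electrode-malfunction subject.
#'
#' @slot records data.frame with columns \code{subject, sex, bmi, age,
#'   waist, height, weight, pdff, eit_mean, eit_sd, injection_current,
#'   excluded, exclusion_reason}.
#' @slot exclusionPolicy one of \code{"none"}, \code{"study_n16"},
#'   \code{"study_n18"}.
#' @seealso \code{\link{loadStudyTables}}, \code{\link{generateCohort}},
#'   \code{\link{runStudyAnalysis}}
#' @export
setClass("EITCohort",
  representation(records = "data.frame", exclusionPolicy = "character")
)

setValidity("EITCohort", function(object) {
  need <- c("subject", "pdff", "eit_mean", "excluded")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(sprintf("records is missing column(s): %s", paste(miss, collapse = ", ")))
  if (!object@exclusionPolicy %in% c("none", "study_n16", "study_n18"))
    return("exclusionPolicy must be one of none, study_n16, study_n18")
  TRUE
})
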