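#' Number of mesh nodes
#' @param x a \code{\link{TriMesh}}
#' @return integer
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of mesh elements
#' @param x a \code{\link{TriMesh}} or object indexing one
#' @return integer
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' Number of electrodes
#' @param x a \code{\link{TriMesh}}, \code{\link{PhantomSpec}} or
#'   \code{\link{StimulationPattern}}
#' @return integer
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))

#' Element indices carrying a region label
#'
#' Returns exactly the elements labelled \code{label}; together with its
#' complement it partitions the element set.
#'
#' @param x a \code{\link{TriMesh}}
#' @param label a region label present in the mesh
#' @return integer vector of element indices
#' @examples
#' mesh <- buildPhantom(referencePhantom(), targetElementSize = 3)
#' liver <- regionMask(mesh, "liver")
#' @export
setGeneric("regionMask", function(x, label) standardGeneric("regionMask"))

#' Region labels present on a mesh
#' @param x a \code{\link{TriMesh}}
#' @return character vector of distinct labels
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Extract conductivity values
#' @param x a \code{\link{ConductivityField}} or
#'   \code{\link{ReconstructionResult}}
#' @return numeric vector of per-element conductivities (S/m)
#' @export
setGeneric("conductivity", function(x) standardGeneric("conductivity"))

#' Extract stacked measurement voltages
#' @param x a \code{\link{MeasurementSet}}
#' @return numeric vector of voltages (V) in pattern order
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' Cohort records after applying the exclusion policy
#' @param x an \code{\link{EITCohort}}
#' @param applyPolicy apply the object's exclusion policy (default TRUE)
#' @return data.frame of subject records
#' @export
setGeneric("cohortRecords", function(x, applyPolicy = TRUE)
  standardGeneric("cohortRecords"))
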