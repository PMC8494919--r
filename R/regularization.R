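#' Regularization settings constructor
#'
#' @param lambda Tikhonov parameter; \code{NA} (default) selects
#'   \code{alpha * tr(J'J) / tr(G'G)} automatically at the first iteration,
#'   a scale-invariant choice that tracks the sensitivity magnitude.
#' @param alpha factor for the automatic lambda (default 10; see the
#'   methods vignette for the robustness sweep behind this choice).
#' @param withinWeight Laplacian edge weight within a region (default 1).
#' @param crossWeight edge weight across region boundaries (default 0.05):
#'   small but positive, so conductivity is smoothed strongly inside each
#'   organ and only weakly tied across anatomical boundaries.
#' @return a \code{\link{Regularization}} object
#' @export
regularization <- function(lambda = NA_real_, alpha = 10,
                           withinWeight = 1, crossWeight = 0.05) {
  new("Regularization", lambda = as.numeric(lambda), alpha = alpha,
      withinWeight = withinWeight, crossWeight = crossWeight)
}

#' Anatomically weighted Laplacian operator
#'
#' Builds the graph-Laplacian smoothness operator on the element adjacency
#' graph (elements are neighbours when they share an edge). Adjacencies
#' within one region carry \code{withinWeight}; adjacencies across region
#' boundaries carry \code{crossWeight}. Rows sum to zero, so the operator
#' annihilates constant fields; with \code{crossWeight = 0} it annihilates
#' any field constant within each region.
#'
#' @param mesh a \code{\link{TriMesh}} with region labels
#' @param withinWeight weight for same-region adjacencies (> 0)
#' @param crossWeight weight for cross-region adjacencies
#'   (0 <= crossWeight <= withinWeight)
#' @return a sparse dgCMatrix (elements x elements)
#' @examples
#' mesh <- buildPhantom(referencePhantom(), targetElementSize = 4)
#' G <- buildGamma(mesh)
#' max(abs(G %*% rep(1, nElements(mesh))))   # zero: constants annihilated
#' @export
buildGamma <- function(mesh, withinWeight = 1, crossWeight = 0.05) {
  reg <- regularization(withinWeight = withinWeight, crossWeight = crossWeight)
  el <- mesh@elements
  m <- nrow(el)
  # shared-edge adjacency via sorted node-pair keys
  ePairs <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  key <- paste(pmin(ePairs[, 1], ePairs[, 2]), pmax(ePairs[, 1], ePairs[, 2]))
  owner <- rep(seq_len(m), 3L)
  ord <- order(key)
  key <- key[ord]; owner <- owner[ord]
  dup <- which(key[-1] == key[-length(key)])
  e1 <- owner[dup]; e2 <- owner[dup + 1L]
  w <- ifelse(mesh@elementRegion[e1] == mesh@elementRegion[e2],
              withinWeight, crossWeight)
  keep <- w > 0
  e1 <- e1[keep]; e2 <- e2[keep]; w <- w[keep]
  W <- Matrix::sparseMatrix(i = c(e1, e2), j = c(e2, e1), x = c(w, w),
                            dims = c(m, m))
  Matrix::Diagonal(m, Matrix::rowSums(W)) - W
}
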