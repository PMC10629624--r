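#' Number of mesh nodes
#' @param x a [TetMesh-class] or object with a node dimension.
#' @return integer count.
#' @aliases nNodes,TetMesh-method
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of mesh elements
#' @param x a [TetMesh-class].
#' @return integer count.
#' @aliases nElements,TetMesh-method
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' Node coordinates
#' @param x a [TetMesh-class].
#' @return m x 3 numeric matrix (mm).
#' @aliases meshNodes,TetMesh-method
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))

#' Element connectivity
#' @param x a [TetMesh-class].
#' @return t x 4 integer matrix of 1-based node indices.
#' @aliases meshElements,TetMesh-method
#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))

#' Per-node region labels
#' @param x a [TetMesh-class].
#' @return integer vector (length m) or \code{NULL} when absent.
#' @aliases nodeLabels,TetMesh-method
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Matrix of connectivity values
#' @param x a [ConnectivityMatrix-class].
#' @return the underlying n x m numeric matrix.
#' @aliases connValues,ConnectivityMatrix-method
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' Subject identifiers
#' @param x a [ConnectivityMatrix-class].
#' @return character vector of subject ids (row order).
#' @aliases subjectIds,ConnectivityMatrix-method
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Component node values
#' @param x a [SmoothPC-class].
#' @return length-m numeric vector f with unit 2-norm.
#' @aliases componentField,SmoothPC-method
#' @export
setGeneric("componentField", function(x) standardGeneric("componentField"))

#' Component subject scores
#' @param x a [SmoothPC-class].
#' @return length-n numeric score vector.
#' @aliases componentScores,SmoothPC-method
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))

setMethod("nNodes", "TetMesh", function(x) nrow(x@nodes))
setMethod("nElements", "TetMesh", function(x) nrow(x@elements))
setMethod("meshNodes", "TetMesh", function(x) x@nodes)
setMethod("meshElements", "TetMesh", function(x) x@elements)
setMethod("nodeLabels", "TetMesh",
  function(x) if (length(x@labels)) x@labels else NULL)
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)
setMethod("subjectIds", "ConnectivityMatrix", function(x) x@subjectIds)
setMethod("componentField", "SmoothPC", function(x) x@f)
setMethod("componentScores", "SmoothPC", function(x) x@s)

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("TetMesh: %d nodes, %d tetrahedra%s\n",
              nNodes(object), nElements(object),
              if (length(object@labels))
                sprintf(", %d labelled regions", length(unique(object@labels)))
              else ""))
  bb <- apply(object@nodes, 2L, range)
  cat(sprintf("  bounding box [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

setMethod("show", "FemOperators", function(object) {
  cat(sprintf("FemOperators on %d nodes (P1 tetrahedral elements)\n",
              length(object@massLumped)))
  cat(sprintf("  total volume %.6g mm^3 (lumped mass sum)\n",
              sum(object@massLumped)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d subjects x %d nodes (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@centered) "column-centered" else "uncentered"))
})

setMethod("show", "SmoothPC", function(object) {
  cat(sprintf(
    "SmoothPC: m = %d nodes, n = %d subjects, lambda = %.3g\n",
    length(object@f), length(object@s), object@lambda))
  cat(sprintf("  roughness %.4g; %d iteration(s), %sconverged",
              object@roughness, object@iterations,
              if (object@converged) "" else "NOT "))
  if (is.finite(object@evCumulative))
    cat(sprintf("; cumulative EV %.2f%%", 100 * object@evCumulative))
  cat("\n")
})

setMethod("show", "BoldRecording", function(object) {
  cat(sprintf("BoldRecording: %d nodes x %d volumes, TR = %.3g s\n",
              nrow(object@series), ncol(object@series), object@tr))
})

setMethod("show", "SeedRegion", function(object) {
  cat(sprintf("SeedRegion: label %d, m_seed = %d nodes\n",
              object@regionId, length(object@nodeIndices)))
})

setMethod("show", "GroupLabels", function(object) {
  tab <- table(object@group)
  cat(sprintf("GroupLabels: %s%s\n",
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              if (length(object@age)) " (+ sex/age covariates)" else ""))
})
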