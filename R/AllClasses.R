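#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric crossprod t solve rowSums
#' @importFrom stats rnorm sd cor median pnorm
NULL

#' Tetrahedral mesh of a volumetric domain
#'
#' Geometry and connectivity of the spatial domain on which fields are
#' observed: node coordinates in mm, 4-node tetrahedral elements, and an
#' optional per-node integer region label (e.g. an atlas parcellation).
#'
#' Element node indices are stored 1-based. On construction, elements with
#' negative orientation are silently reordered (and counted in a message),
#' degenerate (coplanar) elements are an error, and the mesh is required to
#' be edge-connected.
#'
#' @slot nodes numeric matrix, m x 3, node coordinates (mm).
#' @slot elements integer matrix, t x 4, node indices per tetrahedron.
#' @slot labels integer vector of length m (region id per node), or
#'   \code{integer(0)} when no labels are attached.
#'
#' @seealso [tetMesh()], [makeCubeMesh()], [readTetMesh()]
#' @export
setClass("TetMesh",
  representation(nodes = "matrix", elements = "matrix", labels = "integer"))

setValidity("TetMesh", function(object) {
  msgs <- character(0)
  if (ncol(object@nodes) != 3L) msgs <- c(msgs, "nodes must be m x 3")
  if (ncol(object@elements) != 4L) msgs <- c(msgs, "elements must be t x 4")
  m <- nrow(object@nodes)
  el <- object@elements
  if (nrow(el) < 1L) msgs <- c(msgs, "mesh has no elements")
  if (any(!is.finite(object@nodes))) msgs <- c(msgs, "non-finite node coordinates")
  if (any(el < 1L) || any(el > m))
    msgs <- c(msgs, sprintf("element node indices must lie in [1, %d]", m))
  if (length(object@labels) > 0L && length(object@labels) != m)
    msgs <- c(msgs, "labels must have one entry per node")
  if (length(msgs)) return(msgs)
  TRUE
})

#' Construct a TetMesh
#'
#' @param nodes m x 3 numeric matrix of node coordinates (mm).
#' @param elements t x 4 matrix of node indices; 1-based.
#' @param labels optional length-m integer region ids.
#' @return A validated [TetMesh-class] object.
#' @export
tetMesh <- function(nodes, elements, labels = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  obj <- new("TetMesh", nodes = nodes, elements = elements,
             labels = if (is.null(labels)) integer(0) else as.integer(labels))
  v <- signedTetVolumes(obj)
  flipped <- which(v < 0)
  if (length(flipped)) {
    elements[flipped, c(3L, 4L)] <- elements[flipped, c(4L, 3L)]
    obj@elements <- elements
    message(sprintf("reoriented %d negatively oriented element(s)", length(flipped)))
    v <- abs(v)
  }
  degen <- which(v <= .Machine$double.eps * max(abs(nodes)) ^ 3 * 10)
  if (length(degen))
    stop(sprintf("degenerate (coplanar) element(s): first at index %d (%d total)",
                 degen[1L], length(degen)))
  if (!meshIsConnected(obj))
    stop("mesh is not connected (more than one component)")
  obj
}

#' Linear finite-element operators on a tetrahedral mesh
#'
#' Holds the consistent mass matrix M, its lumped diagonal M_L (row sums),
#' and the stiffness matrix A of linear (P1) elements. The squared-Laplacian
#' roughness penalty is the quadratic form f' A M_L^{-1} A f (mixed
#' finite-element discretization of the integral of (Laplacian f)^2 under
#' natural boundary conditions); it is applied matrix-free via [roughness()]
#' and never materialized densely.
#'
#' @slot mass sparse symmetric m x m consistent mass matrix.
#' @slot massLumped length-m positive diagonal of the lumped mass.
#' @slot stiffness sparse symmetric positive semidefinite m x m stiffness
#'   matrix with A 1 = 0.
#'
#' @seealso [femOperators()], [roughness()], [smoothField()]
#' @export
setClass("FemOperators",
  representation(mass = "Matrix", massLumped = "numeric", stiffness = "Matrix"))

setValidity("FemOperators", function(object) {
  m <- length(object@massLumped)
  if (!all(dim(object@mass) == m) || !all(dim(object@stiffness) == m))
    return("operator dimensions disagree")
  if (any(object@massLumped <= 0)) return("lumped mass must be positive")
  TRUE
})

#' Subjects-by-nodes connectivity matrix
#'
#' The n x m matrix Z whose row i is subject i's (Fisher z-transformed)
#' seed-based connectivity map evaluated at the m mesh nodes.
#'
#' @slot values n x m numeric matrix, no non-finite entries.
#' @slot subjectIds length-n unique subject identifiers.
#' @slot centered logical; TRUE after column (node-wise) centering.
#' @slot centerMap the removed per-node mean map (length m; empty before
#'   centering), retained for reporting.
#'
#' @seealso [connectivityMatrix()], [centerColumns()], [buildZ()]
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", subjectIds = "character",
                 centered = "logical", centerMap = "numeric"))

setValidity("ConnectivityMatrix", function(object) {
  msgs <- character(0)
  if (any(!is.finite(object@values))) {
    bad <- unique(which(!is.finite(object@values), arr.ind = TRUE)[, 1L])
    msgs <- c(msgs, sprintf("non-finite entries for subject row(s): %s",
                            paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (length(object@subjectIds) != nrow(object@values))
    msgs <- c(msgs, "one subject id per row required")
  if (anyDuplicated(object@subjectIds))
    msgs <- c(msgs, "subject ids must be unique")
  if (length(msgs)) return(msgs)
  TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param values n x m numeric matrix (rows = subjects, columns = nodes).
#' @param subjectIds optional length-n ids; defaults to \code{"S1"..."Sn"}.
#' @return A [ConnectivityMatrix-class] object (uncentered).
#' @export
connectivityMatrix <- function(values, subjectIds = NULL) {
  values <- as.matrix(values)
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(nrow(values)))
  new("ConnectivityMatrix", values = values,
      subjectIds = as.character(subjectIds),
      centered = FALSE, centerMap = numeric(0))
}

#' One smooth principal component
#'
#' A single penalized principal component: the node values of the component
#' function f (unit Euclidean norm), the per-subject score vector s, the
#' smoothing parameter, the component's roughness f'Pf, and convergence
#' bookkeeping of the alternating minimization.
#'
#' @slot f length-m component node values, normalized to unit 2-norm with
#'   the sign fixed so the largest-magnitude entry is positive.
#' @slot s length-n subject scores (carry the component's magnitude).
#' @slot lambda smoothing parameter used in the fit.
#' @slot roughness penalty value f'Pf of the fitted component.
#' @slot iterations number of alternating sweeps to convergence.
#' @slot converged logical convergence flag.
#' @slot objective per-iteration values of the penalized functional
#'   (non-increasing).
#' @slot evCumulative cumulative explained-variance fraction after this
#'   component (NA for a component fitted in isolation).
#'
#' @seealso [fitComponent()], [sfpca()]
#' @export
setClass("SmoothPC",
  representation(f = "numeric", s = "numeric", lambda = "numeric",
                 roughness = "numeric", iterations = "integer",
                 converged = "logical", objective = "numeric",
                 evCumulative = "numeric"))

#' Node-level BOLD recording
#'
#' Per-node BOLD time series on a mesh: an m x T matrix (node j's series
#' along row j) plus the repetition time TR in seconds.
#'
#' @slot series m x T numeric matrix.
#' @slot tr repetition time in seconds.
#' @export
setClass("BoldRecording", representation(series = "matrix", tr = "numeric"))

setValidity("BoldRecording", function(object) {
  msgs <- character(0)
  if (ncol(object@series) < 8L) msgs <- c(msgs, "need at least 8 time points")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msgs <- c(msgs, "tr must be a single positive number (seconds)")
  if (any(!is.finite(object@series))) msgs <- c(msgs, "non-finite BOLD values")
  if (length(msgs)) return(msgs)
  TRUE
})

#' Construct a BoldRecording
#' @param series m x T matrix of node time series.
#' @param tr repetition time (seconds).
#' @return A [BoldRecording-class] object.
#' @export
boldRecording <- function(series, tr) {
  new("BoldRecording", series = as.matrix(series), tr = as.numeric(tr))
}

#' Seed region on a mesh
#'
#' The set of mesh nodes belonging to one atlas region, used to anchor a
#' seed-based connectivity map.
#'
#' @slot nodeIndices integer node indices (1-based) of the region.
#' @slot regionId the atlas label the region was selected by.
#' @seealso [selectSeed()], [seedMean()]
#' @export
setClass("SeedRegion",
  representation(nodeIndices = "integer", regionId = "integer"))

setValidity("SeedRegion", function(object) {
  if (length(object@nodeIndices) == 0L) return("seed region is empty")
  if (any(object@nodeIndices < 1L)) return("node indices must be positive")
  TRUE
})

#' Per-subject group labels and covariates
#'
#' @slot group factor with exactly two levels (e.g. CTRL/SCHZ), one entry
#'   per subject, aligned with the rows of the paired ConnectivityMatrix.
#' @slot sex optional two-level factor covariate (length 0 if absent).
#' @slot age optional numeric covariate in years (length 0 if absent).
#' @export
setClass("GroupLabels",
  representation(group = "factor", sex = "factor", age = "numeric"))

setValidity("GroupLabels", function(object) {
  msgs <- character(0)
  if (nlevels(object@group) != 2L)
    msgs <- c(msgs, "group must have exactly two levels")
  if (any(table(object@group) == 0L))
    msgs <- c(msgs, "both groups must be non-empty")
  if (length(object@sex) > 0L && length(object@sex) != length(object@group))
    msgs <- c(msgs, "sex must align with group")
  if (length(object@age) > 0L && length(object@age) != length(object@group))
    msgs <- c(msgs, "age must align with group")
  if (length(msgs)) return(msgs)
  TRUE
})

#' Construct GroupLabels
#' @param group vector coercible to a two-level factor.
#' @param sex optional two-level covariate.
#' @param age optional numeric ages (years).
#' @return A [GroupLabels-class] object.
#' @export
groupLabels <- function(group, sex = NULL, age = NULL) {
  new("GroupLabels", group = factor(group),
      sex = if (is.null(sex)) factor(character(0)) else factor(sex),
      age = if (is.null(age)) numeric(0) else as.numeric(age))
}

#' Ground truth of a synthetic study
#'
#' Records what [simulateMaps()] planted, so recovery can be scored: the
#' orthonormal smooth modes, the per-group score means, the score standard
#' deviations, and the node noise level.
#'
#' @slot modes m x K matrix of planted unit-norm modes (mutually
#'   orthogonal).
#' @slot scoreMeans 2 x K matrix of group score means (rows = groups).
#' @slot scoreSds length-K score standard deviations.
#' @slot noiseSd i.i.d. node noise standard deviation.
#' @slot seed integer seed of the random stream.
#' @export
setClass("SyntheticTruth",
  representation(modes = "matrix", scoreMeans = "matrix",
                 scoreSds = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  G <- crossprod(object@modes)
  if (max(abs(G - diag(ncol(object@modes)))) > 1e-8)
    return("planted modes must be orthonormal (tolerance 1e-8)")
  TRUE
})
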