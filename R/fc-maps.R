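# Seed-based functional-connectivity maps from node-level BOLD series:
# zero-phase highpass, seed mean, per-node Pearson correlation, Fisher z,
# and assembly of the subjects-by-nodes matrix Z.

#' Zero-phase highpass filtering of BOLD series
#'
#' Removes each node's mean, then applies a 4th-order Butterworth highpass
#' forward and backward (zero phase) along time. The default 0.01 Hz
#' cutoff removes linear drift and low-frequency noise while leaving the
#' hemodynamic band essentially untouched.
#'
#' @param bold a [BoldRecording-class].
#' @param cutoff highpass cutoff in Hz; must be below the Nyquist
#'   frequency 1/(2 TR).
#' @return a filtered [BoldRecording-class]; every node series has mean
#'   approximately zero.
#' @export
highpassFilter <- function(bold, cutoff = 0.01) {
  stopifnot(is(bold, "BoldRecording"))
  nyq <- 1 / (2 * bold@tr)
  if (cutoff >= nyq)
    stop(sprintf("cutoff %.4g Hz is not below Nyquist %.4g Hz", cutoff, nyq))
  if (cutoff <= 0) stop("cutoff must be positive")
  T <- ncol(bold@series)
  # forward-backward 4th order needs comfortable edge padding
  if (T < 27L)
    stop(sprintf("series too short (T = %d) for zero-phase filtering", T))
  bf <- signal::butter(4, cutoff / nyq, type = "high")
  x <- bold@series - rowMeans(bold@series)
  filt <- t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  boldRecording(filt, bold@tr)
}

#' Mean BOLD series over a seed region
#'
#' @param bold a [BoldRecording-class].
#' @param seed a [SeedRegion-class] whose indices are valid for the
#'   recording.
#' @return length-T numeric series, the unweighted across-node mean.
#' @export
seedMean <- function(bold, seed) {
  stopifnot(is(bold, "BoldRecording"), is(seed, "SeedRegion"))
  idx <- seed@nodeIndices
  if (any(idx > nrow(bold@series)))
    stop("seed node indices exceed the recording's node count")
  colMeans(bold@series[idx, , drop = FALSE])
}

#' Per-node correlation with a reference series
#'
#' Pearson correlation between each node's BOLD series and the seed mean
#' series. Nodes with zero temporal variance get correlation 0 and are
#' flagged in the attached QC attribute rather than dropped, so downstream
#' maps keep one value per node.
#'
#' @param bold a [BoldRecording-class].
#' @param reference length-T series, typically from [seedMean()]; must
#'   have nonzero variance.
#' @return length-m correlations in \[-1, 1\], with attribute
#'   \code{"zeroVarianceNodes"} (integer indices, possibly empty).
#' @export
correlationMap <- function(bold, reference) {
  stopifnot(is(bold, "BoldRecording"))
  if (length(reference) != ncol(bold@series))
    stop("reference series length does not match the recording")
  if (stats::sd(reference) == 0)
    stop("reference (seed mean) series has zero variance: degenerate seed")
  sds <- apply(bold@series, 1L, stats::sd)
  flat <- which(sds == 0)
  rho <- rep(0, nrow(bold@series))
  ok <- sds > 0
  if (any(ok))
    rho[ok] <- as.numeric(stats::cor(t(bold@series[ok, , drop = FALSE]),
                                     reference))
  rho <- pmin(1, pmax(-1, rho))
  attr(rho, "zeroVarianceNodes") <- as.integer(flat)
  rho
}

#' Fisher z-transform of correlations
#'
#' Variance-stabilizing transform \eqn{z = \mathrm{atanh}(\rho)};
#' correlations are clipped to \eqn{\pm(1 - 10^{-7})} first so exact
#' \eqn{\pm 1} maps to a large finite value rather than infinity.
#'
#' @param rho correlations in \[-1, 1\].
#' @return z values; odd and strictly increasing in \code{rho}.
#' @export
fisherMap <- function(rho) {
  if (any(!is.finite(rho))) stop("non-finite correlations")
  if (any(abs(rho) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), rho)))
}

#' Map mesh nodes to voxel indices
#'
#' World (mm) coordinates to voxel indices through the inverse of the
#' volume's 4x4 affine, rounded to the nearest voxel (no interpolation:
#' each node corresponds to one BOLD series). Returned triples are 0-based
#' per the NIfTI convention.
#'
#' @param mesh a [TetMesh-class].
#' @param affine 4x4 voxel-to-world transform (invertible).
#' @param dims length-3 volume shape.
#' @return m x 3 integer matrix of 0-based voxel indices.
#' @export
mapNodesToVoxels <- function(mesh, affine, dims) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)), length(dims) == 3L)
  inv <- tryCatch(solve(affine),
                  error = function(e) stop("affine is not invertible"))
  P <- cbind(mesh@nodes, 1)
  vox <- round(P %*% t(inv))[, 1:3, drop = FALSE]
  out <- which(vox[, 1L] < 0 | vox[, 1L] >= dims[1L] |
               vox[, 2L] < 0 | vox[, 2L] >= dims[2L] |
               vox[, 3L] < 0 | vox[, 3L] >= dims[3L])
  if (length(out))
    stop(sprintf("%d node(s) fall outside the %s volume; first: node %d at (%g, %g, %g)",
                 length(out), paste(dims, collapse = "x"), out[1L],
                 mesh@nodes[out[1L], 1L], mesh@nodes[out[1L], 2L],
                 mesh@nodes[out[1L], 3L]))
  storage.mode(vox) <- "integer"
  vox
}

#' Select a seed region by atlas label
#'
#' @param labels length-m per-node region ids (e.g. [nodeLabels()] of the
#'   mesh).
#' @param regionId the atlas label of the seed (e.g. 24, the anterior
#'   cingulate in the Hammers atlas).
#' @return a [SeedRegion-class].
#' @export
selectSeed <- function(labels, regionId) {
  idx <- which(labels == regionId)
  if (length(idx) == 0L)
    stop(sprintf("region id %d not present in the node labels", regionId))
  new("SeedRegion", nodeIndices = as.integer(idx),
      regionId = as.integer(regionId))
}

#' Assemble the subjects-by-nodes connectivity matrix
#'
#' @param maps list of per-subject length-m z maps, in subject order.
#' @param subjectIds optional unique ids (default names of \code{maps} or
#'   \code{"S1"..."Sn"}).
#' @return a [ConnectivityMatrix-class] with one row per subject,
#'   preserving input order.
#' @export
buildZ <- function(maps, subjectIds = NULL) {
  if (length(maps) == 0L) stop("no maps supplied")
  lens <- lengths(maps)
  if (length(unique(lens)) != 1L)
    stop(sprintf("maps differ in length (%s)",
                 paste(unique(lens), collapse = ", ")))
  if (is.null(subjectIds))
    subjectIds <- if (!is.null(names(maps))) names(maps)
                  else paste0("S", seq_along(maps))
  if (anyDuplicated(subjectIds)) stop("duplicate subject ids")
  connectivityMatrix(do.call(rbind, lapply(maps, as.numeric)), subjectIds)
}

#' Seed-based connectivity map for one subject
#'
#' Convenience chain: highpass the recording, average the seed, correlate
#' every node with the seed mean, Fisher-transform. Returns the z map with
#' the QC attribute of [correlationMap()] carried over.
#'
#' @param bold a [BoldRecording-class].
#' @param seed a [SeedRegion-class].
#' @param cutoff highpass cutoff in Hz (default 0.01).
#' @return length-m z map with attribute \code{"zeroVarianceNodes"}.
#' @export
connectivityMap <- function(bold, seed, cutoff = 0.01) {
  filtered <- highpassFilter(bold, cutoff)
  rho <- correlationMap(filtered, seedMean(filtered, seed))
  z <- fisherMap(as.numeric(rho))
  attr(z, "zeroVarianceNodes") <- attr(rho, "zeroVarianceNodes")
  z
}
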