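# Stage drivers behind the command-line surface: simulate fixtures, build
# connectivity maps, run the smooth PCA, compare groups. Each writes
# plain-text artifacts plus a JSON manifest and returns its outputs
# invisibly, so a pipeline can equally be driven from R.

#' Simulate a synthetic study to disk
#'
#' Generates a cube mesh, planted-mode connectivity maps for two groups,
#' and writes mesh (.node/.ele/.labels), Z matrix, true modes/scores, and
#' group labels under \code{outDir}.
#'
#' @param outDir output directory (created if needed).
#' @param cellsPerSide mesh resolution (default 10, i.e. m = 1331 nodes).
#' @param nPerGroup two group sizes (default c(30, 30)).
#' @param K planted modes (default 3).
#' @param seed integer seed.
#' @param ... further arguments to [simulateMaps()].
#' @return invisibly, a list of written paths.
#' @export
runSimulate <- function(outDir, cellsPerSide = 10L, nPerGroup = c(30L, 30L),
                        K = 3L, seed = 1L, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mesh <- makeCubeMesh(cellsPerSide)
  sim <- simulateMaps(mesh, nPerGroup = nPerGroup, K = K, seed = seed, ...)
  paths <- list(
    mesh = writeTetMesh(mesh, file.path(outDir, "mesh")),
    Z = writeMatrixTable(connValues(sim$Z), file.path(outDir, "Z.tsv")),
    modes = writeMatrixTable(sim$truth@modes, file.path(outDir, "true_modes.tsv")),
    scores = writeMatrixTable(sim$scores, file.path(outDir, "true_scores.tsv")),
    labels = writeGroupLabels(sim$labels, file.path(outDir, "labels.tsv"),
                              subjectIds = subjectIds(sim$Z)))
  writeManifest(file.path(outDir, "simulate_manifest.json"),
                stage = "simulate", seed = seed, cellsPerSide = cellsPerSide,
                nPerGroup = nPerGroup, K = K)
  invisible(paths)
}

#' Build per-subject connectivity maps and the Z matrix
#'
#' @param boldPaths character vector of per-subject 4D NIfTI paths (or a
#'   list of [BoldRecording-class] objects).
#' @param meshPrefix mesh file prefix for [readTetMesh()] (or a
#'   [TetMesh-class]).
#' @param seedRegionId atlas label of the seed region.
#' @param outDir output directory.
#' @param cutoff highpass cutoff in Hz (default 0.01).
#' @param tr optional TR override.
#' @return invisibly, list with the [ConnectivityMatrix-class] and paths.
#' @export
runFcmap <- function(boldPaths, meshPrefix, seedRegionId, outDir,
                     cutoff = 0.01, tr = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mesh <- if (is(meshPrefix, "TetMesh")) meshPrefix else readTetMesh(meshPrefix)
  if (is.null(nodeLabels(mesh))) stop("mesh has no node labels; cannot select seed")
  seed <- selectSeed(nodeLabels(mesh), seedRegionId)
  maps <- list()
  nZeroVar <- integer(0)
  for (i in seq_along(boldPaths)) {
    bold <- if (is(boldPaths[[i]], "BoldRecording")) boldPaths[[i]]
            else readBoldNifti(boldPaths[[i]], mesh, tr = tr)
    z <- connectivityMap(bold, seed, cutoff = cutoff)
    nZeroVar[i] <- length(attr(z, "zeroVarianceNodes"))
    maps[[i]] <- as.numeric(z)
  }
  Z <- buildZ(maps)
  writeMatrixTable(connValues(Z), file.path(outDir, "Z.tsv"))
  writeLines(c(sprintf("subjects: %d", length(maps)),
               sprintf("nodes: %d", nNodes(mesh)),
               sprintf("seed region: %d (m_seed = %d)",
                       seedRegionId, length(seed@nodeIndices)),
               sprintf("highpass cutoff: %g Hz", cutoff),
               sprintf("zero-variance nodes per subject: %s",
                       paste(nZeroVar, collapse = " "))),
             file.path(outDir, "qc_report.txt"))
  writeManifest(file.path(outDir, "fcmap_manifest.json"),
                stage = "fcmap", seedRegionId = seedRegionId,
                mSeed = length(seed@nodeIndices), cutoff = cutoff)
  invisible(list(Z = Z, seed = seed,
                 paths = file.path(outDir, c("Z.tsv", "qc_report.txt"))))
}

#' Run smooth functional PCA on a saved Z matrix
#'
#' @param zPath path to a Z matrix from [writeMatrixTable()] (or a
#'   [ConnectivityMatrix-class]).
#' @param meshPrefix mesh prefix (or a [TetMesh-class]).
#' @param outDir output directory.
#' @param lambda smoothing parameter (default 1e-1).
#' @param K number of components (default 4).
#' @return invisibly, list with components, scores matrix and paths.
#' @export
runPca <- function(zPath, meshPrefix, outDir, lambda = 1e-1, K = 4L) {
  if (K < 1L) stop("usage error: K must be at least 1")
  if (lambda < 0) stop("usage error: lambda must be nonnegative")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mesh <- if (is(meshPrefix, "TetMesh")) meshPrefix else readTetMesh(meshPrefix)
  Z <- if (is(zPath, "ConnectivityMatrix")) zPath
       else connectivityMatrix(readMatrixTable(zPath))
  ops <- femOperators(mesh)
  comps <- sfpca(Z, ops, lambda = lambda, K = K)
  F <- do.call(cbind, lapply(comps, componentField))
  S <- do.call(cbind, lapply(comps, componentScores))
  ev <- vapply(comps, function(p) p@evCumulative, numeric(1))
  writeMatrixTable(F, file.path(outDir, "components.tsv"))
  writeMatrixTable(S, file.path(outDir, "scores.tsv"))
  writeVTK(mesh, file.path(outDir, "components.vtk"),
           pointData = stats::setNames(
             lapply(seq_len(K), function(k) F[, k]),
             paste0("SFPC", seq_len(K))))
  writeManifest(file.path(outDir, "pca_manifest.json"),
                stage = "pca", lambda = lambda, K = K,
                iterations = vapply(comps, function(p) p@iterations, integer(1)),
                converged = vapply(comps, function(p) p@converged, logical(1)),
                evCumulative = ev)
  invisible(list(components = comps, scores = S, evCumulative = ev,
                 paths = file.path(outDir,
                   c("components.tsv", "scores.tsv", "pca_manifest.json"))))
}

#' Compare component scores between groups and write the report
#'
#' @param scoresPath path to a scores matrix (or an n x K matrix).
#' @param labelsPath path to a labels table (or a [GroupLabels-class]).
#' @param outDir output directory.
#' @param alpha significance threshold (default 0.01).
#' @return invisibly, the [groupComparison()] result plus the report path.
#' @export
runCompare <- function(scoresPath, labelsPath, outDir, alpha = 0.01) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  S <- if (is.matrix(scoresPath)) scoresPath else readMatrixTable(scoresPath)
  labels <- if (is(labelsPath, "GroupLabels")) labelsPath
            else readGroupLabels(labelsPath)
  res <- groupComparison(list(scores = S), labels, alpha = alpha)
  rpt <- file.path(outDir, "group_report.tsv")
  utils::write.table(res$perComponent, rpt, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  lines <- c(sprintf("LOO-LDA AUC\t%.6f", res$auc))
  if (!is.null(res$covariates)) {
    covPath <- file.path(outDir, "covariate_report.tsv")
    utils::write.table(res$covariates, covPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  writeLines(lines, file.path(outDir, "auc.txt"))
  writeManifest(file.path(outDir, "compare_manifest.json"),
                stage = "compare", alpha = alpha, auc = res$auc)
  invisible(c(res, list(reportPath = rpt)))
}
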