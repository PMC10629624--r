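# File formats: TetGen-style .node/.ele meshes, legacy ASCII VTK export,
# tab-separated matrices with a dimension header, NIfTI BOLD volumes, and
# label tables. Internal indices are 1-based; 0/1-based file dialects are
# auto-detected from the minimum id and normalized on read.

readTokenLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
}

#' Read a tetrahedral mesh from .node/.ele files
#'
#' TetGen-style plain text: the .node file has a header
#' \code{"<m> 3 <nAttr> <nMarker>"} followed by \code{id x y z} lines; the
#' .ele file has a header \code{"<t> 4 <nAttr>"} followed by
#' \code{id n1 n2 n3 n4}. Both 0- and 1-based id dialects are detected
#' from the minimum id and normalized. An optional labels file (one
#' integer per node) attaches a parcellation.
#'
#' @param prefix path prefix; \code{<prefix>.node} and \code{<prefix>.ele}
#'   are read (and \code{<prefix>.labels} if present or given).
#' @param labelsPath optional explicit labels file path.
#' @return a [TetMesh-class].
#' @export
readTetMesh <- function(prefix, labelsPath = NULL) {
  nodePath <- paste0(prefix, ".node")
  elePath <- paste0(prefix, ".ele")
  for (p in c(nodePath, elePath))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  ntok <- readTokenLines(nodePath)
  hdr <- suppressWarnings(as.numeric(ntok[[1L]]))
  if (length(hdr) < 2L || is.na(hdr[1L]) || hdr[2L] != 3)
    stop(sprintf("malformed .node header at %s line 1", nodePath))
  m <- as.integer(hdr[1L])
  if (length(ntok) - 1L != m)
    stop(sprintf("%s: header promises %d nodes, found %d",
                 nodePath, m, length(ntok) - 1L))
  nodeRows <- do.call(rbind, lapply(ntok[-1L], function(tk) {
    v <- suppressWarnings(as.numeric(tk))
    if (length(v) < 4L || any(is.na(v[1:4])))
      stop(sprintf("malformed node line in %s", nodePath))
    v[1:4]
  }))
  nodeIds <- as.integer(nodeRows[, 1L])
  etok <- readTokenLines(elePath)
  ehdr <- suppressWarnings(as.numeric(etok[[1L]]))
  if (length(ehdr) < 2L || is.na(ehdr[1L]) || ehdr[2L] != 4)
    stop(sprintf("malformed .ele header at %s line 1", elePath))
  t <- as.integer(ehdr[1L])
  if (length(etok) - 1L != t)
    stop(sprintf("%s: header promises %d elements, found %d",
                 elePath, t, length(etok) - 1L))
  eleRows <- do.call(rbind, lapply(seq_len(t), function(i) {
    v <- suppressWarnings(as.integer(etok[[i + 1L]]))
    if (length(v) < 5L || any(is.na(v[1:5])))
      stop(sprintf("malformed element line %d in %s", i + 1L, elePath))
    v[1:5]
  }))
  base <- min(nodeIds)  # 0 or 1 dialect
  if (!(base %in% c(0L, 1L)))
    stop(sprintf("cannot detect id dialect in %s (min id %d)", nodePath, base))
  ord <- order(nodeIds)
  nodes <- nodeRows[ord, 2:4, drop = FALSE]
  elements <- eleRows[, 2:5, drop = FALSE] - base + 1L
  if (any(elements < 1L) || any(elements > m)) {
    bad <- which(apply(elements, 1L, function(r) any(r < 1L | r > m)))[1L]
    stop(sprintf("%s line %d: element references a node outside [%d, %d]",
                 elePath, bad + 1L, base, m + base - 1L))
  }
  labels <- NULL
  lp <- if (!is.null(labelsPath)) labelsPath else paste0(prefix, ".labels")
  if (file.exists(lp)) {
    labels <- as.integer(unlist(readTokenLines(lp)))
    if (length(labels) != m)
      stop(sprintf("%s: expected %d labels, found %d", lp, m, length(labels)))
  }
  tetMesh(nodes, elements, labels)
}

#' Write a tetrahedral mesh to .node/.ele files
#'
#' 1-based TetGen dialect; labels, if present, go to
#' \code{<prefix>.labels}. Round-trips through [readTetMesh()] losslessly.
#'
#' @param mesh a [TetMesh-class].
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
writeTetMesh <- function(mesh, prefix) {
  nd <- meshNodes(mesh)
  el <- meshElements(mesh)
  nodePath <- paste0(prefix, ".node")
  elePath <- paste0(prefix, ".ele")
  con <- file(nodePath, "w")
  writeLines(sprintf("%d 3 0 0", nrow(nd)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g",
                     seq_len(nrow(nd)), nd[, 1L], nd[, 2L], nd[, 3L]), con)
  close(con)
  con <- file(elePath, "w")
  writeLines(sprintf("%d 4 0", nrow(el)), con)
  writeLines(sprintf("%d %d %d %d %d",
                     seq_len(nrow(el)), el[, 1L], el[, 2L], el[, 3L], el[, 4L]), con)
  close(con)
  paths <- c(nodePath, elePath)
  if (length(mesh@labels)) {
    lp <- paste0(prefix, ".labels")
    writeLines(as.character(mesh@labels), lp)
    paths <- c(paths, lp)
  }
  invisible(paths)
}

#' Export a mesh (with optional node fields) as legacy ASCII VTK
#'
#' Unstructured-grid VTK for visualization in ParaView and friends; each
#' entry of \code{pointData} becomes a named scalar POINT_DATA array.
#'
#' @param mesh a [TetMesh-class].
#' @param path output .vtk path.
#' @param pointData named list of length-m numeric vectors.
#' @return invisibly, \code{path}.
#' @export
writeVTK <- function(mesh, path, pointData = list()) {
  nd <- meshNodes(mesh)
  el <- meshElements(mesh) - 1L  # VTK is 0-based
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%.9g %.9g %.9g", nd[, 1L], nd[, 2L], nd[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), 5L * nrow(el)), con)
  writeLines(sprintf("4 %d %d %d %d", el[, 1L], el[, 2L], el[, 3L], el[, 4L]), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(rep("10", nrow(el)), con)
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nd)), con)
    for (nm in names(pointData)) {
      v <- pointData[[nm]]
      stopifnot(length(v) == nrow(nd))
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", v), con)
    }
  }
  invisible(path)
}

#' Write a numeric matrix as tab-separated text
#'
#' First line: \code{nrow <TAB> ncol}; then one row per line, full double
#' precision.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMatrixTable <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d", nrow(x), ncol(x)), con)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a tab-separated matrix written by [writeMatrixTable()]
#' @param path input path.
#' @return numeric matrix.
#' @export
readMatrixTable <- function(path) {
  hdr <- scan(path, what = integer(), n = 2L, quiet = TRUE)
  vals <- scan(path, what = double(), skip = 1L, quiet = TRUE)
  if (length(vals) != hdr[1L] * hdr[2L])
    stop(sprintf("%s: header promises %d x %d values, found %d",
                 path, hdr[1L], hdr[2L], length(vals)))
  matrix(vals, nrow = hdr[1L], ncol = hdr[2L], byrow = TRUE)
}

#' Write group labels (and covariates) as a TSV table
#' @param labels a [GroupLabels-class].
#' @param path output path.
#' @param subjectIds optional ids column.
#' @return invisibly, \code{path}.
#' @export
writeGroupLabels <- function(labels, path, subjectIds = NULL) {
  n <- length(labels@group)
  df <- data.frame(subject = if (is.null(subjectIds)) paste0("S", seq_len(n))
                             else subjectIds,
                   group = as.character(labels@group))
  if (length(labels@sex)) df$sex <- as.character(labels@sex)
  if (length(labels@age)) df$age <- labels@age
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read group labels written by [writeGroupLabels()]
#' @param path input path.
#' @return a [GroupLabels-class]; subject ids in attribute
#'   \code{"subjectIds"}.
#' @export
readGroupLabels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gl <- groupLabels(df$group,
                    sex = if ("sex" %in% names(df)) df$sex else NULL,
                    age = if ("age" %in% names(df)) df$age else NULL)
  attr(gl, "subjectIds") <- as.character(df$subject)
  gl
}

# Grid layout of a mesh whose nodes sit on a rectilinear grid (the
# synthetic meshes): unique sorted coordinates per axis + each node's
# 1-based grid index. Errors if nodes are off-grid.
meshGridLayout <- function(mesh, tolFactor = 1e-8) {
  nd <- meshNodes(mesh)
  ax <- lapply(1:3, function(d) sort(unique(nd[, d])))
  tolAx <- vapply(ax, function(g)
    max(diff(range(g)), 1) * tolFactor, numeric(1))
  idx <- vapply(1:3, function(d) {
    i <- findInterval(nd[, d], ax[[d]] - tolAx[d])
    if (any(abs(ax[[d]][i] - nd[, d]) > tolAx[d]))
      stop("mesh nodes do not lie on a rectilinear grid")
    i
  }, integer(nrow(nd)))
  list(axes = ax, index = idx)
}

#' Write a node-level BOLD recording as a 4D NIfTI volume
#'
#' For meshes whose nodes lie on a rectilinear grid (the synthetic
#' meshes), each node's series is placed at its grid voxel; voxels not
#' covered by the mesh are zero. The affine is diagonal (grid spacing,
#' origin at the grid minimum) and TR is stored in the time pixdim.
#'
#' @param bold a [BoldRecording-class] paired with \code{mesh}.
#' @param mesh a [TetMesh-class] with grid-aligned nodes.
#' @param path output .nii or .nii.gz path.
#' @return invisibly, \code{path}.
#' @export
writeBoldNifti <- function(bold, mesh, path) {
  stopifnot(is(bold, "BoldRecording"), nrow(bold@series) == nNodes(mesh))
  gl <- meshGridLayout(mesh)
  dims <- vapply(gl$axes, length, integer(1))
  sp <- vapply(gl$axes, function(g)
    if (length(g) > 1L) min(diff(g)) else 1, numeric(1))
  T <- ncol(bold@series)
  arr <- array(0, dim = c(dims, T))
  flat <- gl$index[, 1L] + dims[1L] * (gl$index[, 2L] - 1L) +
    dims[1L] * dims[2L] * (gl$index[, 3L] - 1L)
  vol <- prod(dims)
  for (tt in seq_len(T)) arr[flat + (tt - 1L) * vol] <- bold@series[, tt]
  affine <- diag(c(sp, 1))
  affine[1:3, 4L] <- vapply(gl$axes, min, numeric(1))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img$pixdim[5L] <- bold@tr
  img$xyzt_units <- 10L  # mm + seconds
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read node-level BOLD series from a 4D NIfTI volume
#'
#' Extracts one series per mesh node via [mapNodesToVoxels()] with the
#' volume's affine (sform preferred). TR is taken from the header time
#' step unless overridden.
#'
#' @param path 4D NIfTI file.
#' @param mesh a [TetMesh-class]; all nodes must fall inside the volume.
#' @param tr optional TR override in seconds.
#' @return a [BoldRecording-class].
#' @export
readBoldNifti <- function(path, mesh, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D volume, got %d dimension(s)", length(d)))
  affine <- RNifti::xform(img, useQuaternionFirst = FALSE)
  vox <- mapNodesToVoxels(mesh, affine, d[1:3]) + 1L
  flat <- vox[, 1L] + d[1L] * (vox[, 2L] - 1L) + d[1L] * d[2L] * (vox[, 3L] - 1L)
  vol <- prod(d[1:3])
  series <- vapply(seq_len(d[4L]), function(tt)
    img[flat + (tt - 1L) * vol], numeric(nrow(vox)))
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4L]
    if (!is.finite(tr) || tr <= 0)
      stop("no usable TR in the NIfTI header; pass tr explicitly")
  }
  boldRecording(series, tr)
}

#' Write a run manifest
#'
#' JSON record of an analysis run: parameters, seeds, iteration counts,
#' convergence flags and explained variance, for provenance.
#'
#' @param path output .json path.
#' @param ... named fields to record.
#' @return invisibly, \code{path}.
#' @export
writeManifest <- function(path, ...) {
  fields <- list(...)
  fields$rVersion <- as.character(getRversion())
  fields$package <- as.character(utils::packageVersion("SmoothFPCA"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
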