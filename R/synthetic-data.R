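# Synthetic meshes, planted smooth modes, two-group score models, and
# band-limited BOLD with a prescribed seed-correlation field. Everything
# is deterministic given the explicit integer seed of each call; no global
# RNG state is consumed or left behind.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# 6-tet Kuhn/Freudenthal split of one grid cell: every tetrahedron shares
# the main diagonal, so adjacent cells triangulate their shared face
# identically and the mesh is conforming.
kuhnTets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  odd <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)  # permutation parity
  do.call(rbind, lapply(seq_len(6L), function(r) {
    p <- perms[r, ]
    e <- diag(3)
    v0 <- c(0, 0, 0)
    v1 <- v0 + e[p[1L], ]
    v2 <- v1 + e[p[2L], ]
    if (odd[r]) rbind(v0, v2, v1, c(1, 1, 1))
    else rbind(v0, v1, v2, c(1, 1, 1))
  }))
}

cubeGridMesh <- function(k, keepCell = NULL, labels = NULL) {
  stopifnot(k >= 1L)
  g <- seq(0, 1, length.out = k + 1L)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  dimnames(nodes) <- NULL
  idx <- function(i, j, l) 1L + i + (k + 1L) * j + (k + 1L) ^ 2 * l
  cells <- expand.grid(i = 0:(k - 1L), j = 0:(k - 1L), l = 0:(k - 1L))
  if (!is.null(keepCell)) {
    keep <- keepCell((cells$i + 0.5) / k, (cells$j + 0.5) / k,
                     (cells$l + 0.5) / k)
    cells <- cells[keep, , drop = FALSE]
    if (nrow(cells) == 0L) stop("no cells left in the domain")
  }
  corner <- function(di, dj, dl) idx(cells$i + di, cells$j + dj, cells$l + dl)
  tets <- kuhnTets()  # 6 blocks of 4 rows, each row an offset in {0,1}^3
  el <- vector("list", 6L)
  for (tt in 1:6) {
    block <- tets[(4L * (tt - 1L) + 1L):(4L * tt), , drop = FALSE]
    el[[tt]] <- cbind(corner(block[1L, 1L], block[1L, 2L], block[1L, 3L]),
                      corner(block[2L, 1L], block[2L, 2L], block[2L, 3L]),
                      corner(block[3L, 1L], block[3L, 2L], block[3L, 3L]),
                      corner(block[4L, 1L], block[4L, 2L], block[4L, 3L]))
  }
  elements <- do.call(rbind, el)
  used <- sort(unique(as.vector(elements)))
  renum <- integer(nrow(nodes))
  renum[used] <- seq_along(used)
  elements <- matrix(renum[elements], ncol = 4L)
  nodes <- nodes[used, , drop = FALSE]
  lab <- if (is.null(labels)) NULL else labels(nodes)
  tetMesh(nodes, elements, lab)
}

#' Regular tetrahedral mesh of the unit cube
#'
#' A k x k x k grid of cells, each split into 6 tetrahedra (Kuhn
#' subdivision along the main diagonal, conforming across cells):
#' \eqn{(k+1)^3} nodes, \eqn{6 k^3} elements, total volume 1. Nodes carry
#' octant labels 1..8 (useful as a toy parcellation for seed selection).
#'
#' @param cellsPerSide number of cells per axis, k >= 1.
#' @return a [TetMesh-class].
#' @export
makeCubeMesh <- function(cellsPerSide) {
  cubeGridMesh(cellsPerSide, labels = function(nd)
    1L + (nd[, 1L] > 0.5) + 2L * (nd[, 2L] > 0.5) + 4L * (nd[, 3L] > 0.5))
}

#' C-shaped test mesh (cube with a slit)
#'
#' The unit cube with a rectangular slit removed: cells whose centers have
#' \eqn{x > 0.25} and y within a band of \code{gapCells} cell layers
#' around y = 0.5 are deleted. Node pairs facing each other across the
#' slit are close in Euclidean distance but far apart within the domain,
#' the geometry that makes domain-compliant smoothing visible. Nodes are
#' labelled 1 (arm below the slit), 2 (arm above), 3 (connector,
#' \eqn{x \le 0.25}).
#'
#' @param cellsPerSide grid resolution k (even values keep the slit
#'   symmetric); default 8.
#' @param gapCells slit thickness in cell layers (default 2); must leave
#'   the domain connected.
#' @return a connected [TetMesh-class].
#' @export
makeCShapeMesh <- function(cellsPerSide = 8L, gapCells = 2L) {
  k <- as.integer(cellsPerSide)
  half <- gapCells / (2 * k)
  if (half >= 0.5) stop("gap removes the whole cross-section: domain disconnected")
  mesh <- cubeGridMesh(k, keepCell = function(x, y, z)
    !(x > 0.25 & abs(y - 0.5) < half + 1e-12))
  nd <- meshNodes(mesh)
  lab <- ifelse(nd[, 1L] <= 0.25 + 1e-12, 3L,
                ifelse(nd[, 2L] >= 0.5, 2L, 1L))
  mesh@labels <- as.integer(lab)
  validObject(mesh)
  mesh
}

#' Planted orthonormal smooth modes
#'
#' Low-order cosine products \eqn{\cos(a\pi x)\cos(b\pi y)\cos(c\pi z)}
#' (Neumann-compatible on a box) evaluated at the mesh nodes (coordinates
#' rescaled to the unit box), orthonormalized by Gram-Schmidt on the node
#' values. The seed randomizes the modes' signs only; fields are
#' deterministic given seed and mesh.
#'
#' @param mesh a [TetMesh-class].
#' @param K number of modes, at most 8.
#' @param seed integer seed.
#' @return m x K matrix with orthonormal columns.
#' @export
plantedModes <- function(mesh, K, seed = 1L) {
  if (K < 1L || K > 8L) stop("K must lie in [1, 8]")
  freqs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                 c(1, 0, 1), c(0, 1, 1), c(2, 0, 0), c(0, 2, 0))
  nd <- meshNodes(mesh)
  lo <- apply(nd, 2L, min); hi <- apply(nd, 2L, max)
  u <- sweep(sweep(nd, 2L, lo), 2L, pmax(hi - lo, .Machine$double.eps), "/")
  B <- vapply(seq_len(K), function(k)
    cos(freqs[k, 1L] * pi * u[, 1L]) *
    cos(freqs[k, 2L] * pi * u[, 2L]) *
    cos(freqs[k, 3L] * pi * u[, 3L]), numeric(nrow(nd)))
  Q <- qr.Q(qr(B))
  # qr.Q can flip columns relative to B; align, then apply seeded signs
  for (k in seq_len(K)) if (sum(Q[, k] * B[, k]) < 0) Q[, k] <- -Q[, k]
  sgn <- withSeed(seed, sample(c(-1, 1), K, replace = TRUE))
  sweep(Q, 2L, sgn, "*")
}

#' Simulate two-group connectivity maps with planted modes
#'
#' Each subject's map is \eqn{\sum_k s_{ik} \cdot mode_k + \epsilon_i}
#' with scores \eqn{s_{ik} \sim N(\mu_{gk}, sd_k^2)} and i.i.d. node noise
#' \eqn{\epsilon \sim N(0, \sigma^2)}. By default K = 3 modes with score
#' sds (3, 1.5, 1) (strictly ordered in variance, also after the group
#' shift), a between-group mean shift of \code{shift} times sd on mode 2
#' only (groups at \eqn{\mp \delta/2}), and \eqn{\sigma = 0.2}.
#'
#' @param mesh a [TetMesh-class].
#' @param nPerGroup length-2 subject counts (default c(30, 30)).
#' @param K number of planted modes (default 3).
#' @param scoreSds length-K score standard deviations (default
#'   \code{c(3, 1.5, 1)[1:K]}).
#' @param shiftMode which mode carries the group shift (default 2; 0 for
#'   none).
#' @param shift group mean difference in units of that mode's sd
#'   (default 1.5).
#' @param noiseSd i.i.d. node noise sd (default 0.2).
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return list with \code{Z} ([ConnectivityMatrix-class]), \code{labels}
#'   ([GroupLabels-class], levels CTRL/SCHZ), \code{truth}
#'   ([SyntheticTruth-class]), and \code{scores} (n x K true scores).
#' @export
simulateMaps <- function(mesh, nPerGroup = c(30L, 30L), K = 3L,
                         scoreSds = NULL, shiftMode = 2L, shift = 1.5,
                         noiseSd = 0.2, seed = 1L) {
  if (any(nPerGroup < 1L) || length(nPerGroup) != 2L)
    stop("nPerGroup must be two positive counts")
  if (is.null(scoreSds)) scoreSds <- c(3, 1.5, 1, 0.75, 0.6, 0.5, 0.4, 0.3)[seq_len(K)]
  stopifnot(length(scoreSds) == K)
  modes <- plantedModes(mesh, K, seed = seed)
  m <- nNodes(mesh)
  n <- sum(nPerGroup)
  grp <- factor(rep(c("CTRL", "SCHZ"), nPerGroup), levels = c("CTRL", "SCHZ"))
  means <- matrix(0, 2L, K)
  if (shiftMode >= 1L && shiftMode <= K) {
    delta <- shift * scoreSds[shiftMode]
    means[, shiftMode] <- c(-delta / 2, delta / 2)
  }
  out <- withSeed(seed, {
    scores <- vapply(seq_len(K), function(k)
      stats::rnorm(n, mean = means[as.integer(grp), k], sd = scoreSds[k]),
      numeric(n))
    noise <- matrix(stats::rnorm(n * m, sd = noiseSd), n, m)
    list(scores = scores, noise = noise)
  })
  Z <- out$scores %*% t(modes) + out$noise
  list(Z = connectivityMatrix(Z),
       labels = groupLabels(grp),
       truth = new("SyntheticTruth", modes = modes, scoreMeans = means,
                   scoreSds = as.numeric(scoreSds),
                   noiseSd = as.numeric(noiseSd), seed = as.integer(seed)),
       scores = out$scores)
}

# Band-limited standardized noise: random cos/sin coefficients on Fourier
# frequencies in [fLow, fHigh], one series per row. No filter transients;
# the spectrum is flat inside the band and empty outside.
bandLimitedNoise <- function(nSeries, T, tr, fLow = 0.02, fHigh = NULL) {
  nyq <- 1 / (2 * tr)
  if (is.null(fHigh)) fHigh <- 0.98 * nyq
  freqs <- seq_len(floor(T / 2) - 1L) / (T * tr)
  band <- which(freqs >= fLow & freqs <= fHigh)
  if (length(band) < 4L) stop("series too short for band-limited synthesis")
  tt <- seq_len(T) - 1L
  arg <- 2 * pi * outer(freqs[band] * tr, tt)      # B x T
  basis <- rbind(cos(arg), sin(arg))               # 2B x T
  C <- matrix(stats::rnorm(nSeries * 2L * length(band)), nSeries)
  S <- C %*% basis
  S <- S - rowMeans(S)
  S / apply(S, 1L, stats::sd)
}

#' Simulate BOLD with a prescribed seed-correlation field
#'
#' A standardized latent seed signal is drawn as band-limited noise
#' (0.02 Hz to just below Nyquist, so the 0.01 Hz analysis highpass passes
#' it essentially unchanged). Seed nodes receive the latent signal plus
#' small independent jitter; every other node j receives
#' \eqn{\rho_j \sigma(t) + \sqrt{1 - \rho_j^2}\, \eta_j(t)} with
#' independent standardized band-limited noise \eqn{\eta_j}, so its
#' population correlation with the seed signal is exactly \eqn{\rho_j}.
#'
#' @param mesh a [TetMesh-class].
#' @param seedRegion a [SeedRegion-class] on the mesh.
#' @param rhoField length-m target correlations in \[-0.99, 0.99\]
#'   (values at seed nodes are ignored; those nodes carry the signal).
#' @param T number of volumes (>= 50; default 150).
#' @param tr repetition time in seconds (default 2).
#' @param seed integer seed.
#' @param jitterSd sd of the seed nodes' independent jitter (default 0.05).
#' @return a [BoldRecording-class].
#' @export
simulateBold <- function(mesh, seedRegion, rhoField, T = 150L, tr = 2,
                         seed = 1L, jitterSd = 0.05) {
  stopifnot(is(seedRegion, "SeedRegion"))
  m <- nNodes(mesh)
  if (length(rhoField) != m) stop("rhoField must have one value per node")
  if (any(abs(rhoField) > 0.99 + 1e-12))
    stop("target correlations must lie in [-0.99, 0.99]")
  if (T < 50L) stop("need at least 50 volumes")
  withSeed(seed, {
    latent <- bandLimitedNoise(1L, T, tr)[1L, ]
    eta <- bandLimitedNoise(m, T, tr)
    series <- rhoField * matrix(latent, m, T, byrow = TRUE) +
      sqrt(1 - rhoField ^ 2) * eta
    idx <- seedRegion@nodeIndices
    series[idx, ] <- matrix(latent, length(idx), T, byrow = TRUE) +
      jitterSd * bandLimitedNoise(length(idx), T, tr)
    boldRecording(series, tr)
  })
}
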