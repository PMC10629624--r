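# Smooth functional PCA: rank-1 alternating minimization of
#   sum_ij (z_ij - s_i f_j)^2 + lambda * (s's) * f'Pf
# with P the mixed-FEM squared-Laplacian penalty, plus the multivariate
# PCA baseline (the lambda -> 0 limit) and sequential deflation.

# Sign convention: flip so the largest-|.| entry of f is positive
# (ties broken by lowest index, which.max's behavior).
fixSign <- function(f, s) {
  if (f[which.max(abs(f))] < 0) list(f = -f, s = -s) else list(f = f, s = s)
}

#' Center a connectivity matrix node-wise
#'
#' Removes the across-subject mean map, so that every node (column) has
#' mean zero; the removed mean map is retained in the returned object for
#' reporting.
#'
#' @param Z a [ConnectivityMatrix-class] with n >= 2 subjects.
#' @return a centered [ConnectivityMatrix-class].
#' @export
centerColumns <- function(Z) {
  stopifnot(is(Z, "ConnectivityMatrix"))
  if (nrow(Z@values) < 2L) stop("need at least 2 subjects to center")
  if (Z@centered) return(Z)
  mu <- colMeans(Z@values)
  Z@values <- sweep(Z@values, 2L, mu)
  Z@centered <- TRUE
  Z@centerMap <- mu
  Z
}

#' Multivariate PCA baseline
#'
#' Truncated SVD of the centered data matrix: loadings are the leading
#' right singular vectors (unit norm, same sign convention as smooth
#' components), scores their projections. This is exactly the
#' \eqn{\lambda = 0} limit of the smooth fit.
#'
#' @param Zc centered [ConnectivityMatrix-class] or plain centered matrix.
#' @param K number of components, \code{K <= min(n, m)}.
#' @return list with \code{loadings} (m x K), \code{scores} (n x K),
#'   \code{evCumulative} (length K).
#' @export
mvPCA <- function(Zc, K) {
  X <- if (is(Zc, "ConnectivityMatrix")) Zc@values else as.matrix(Zc)
  if (K < 1L || K > min(dim(X)))
    stop(sprintf("K must lie in [1, %d]", min(dim(X))))
  sv <- svd(X, nu = K, nv = K)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(K)], K)
  for (k in seq_len(K)) {
    fs <- fixSign(loadings[, k], scores[, k])
    loadings[, k] <- fs$f
    scores[, k] <- fs$s
  }
  ev <- cumsum(sv$d[seq_len(K)] ^ 2) / sum(sv$d ^ 2)
  list(loadings = loadings, scores = scores, evCumulative = ev)
}

# Value of the penalized functional at (f, s).
sfpcaObjective <- function(X, ops, lambda, f, s) {
  R <- X - tcrossprod(s, f)
  sum(R * R) + lambda * sum(s * s) * roughness(ops, f)
}

#' Fit one smooth principal component
#'
#' Alternating minimization of the penalized rank-1 functional. With f
#' fixed, the optimal scores are \eqn{s_i = (Zf)_i / (f'f + \lambda f'Pf)};
#' with s fixed, the optimal component solves the penalized smoothing
#' problem \eqn{(I + \lambda P) f = Z's / (s's)} (both obtained by setting
#' the respective gradients of the functional to zero). After each sweep f
#' is renormalized to unit 2-norm with its magnitude folded into s — a
#' reparametrization the functional is invariant to. Iteration stops when
#' the relative change of both f and s falls below \code{tol}, or at
#' \code{maxIter} sweeps (with a warning).
#'
#' @param Zc centered [ConnectivityMatrix-class] or plain centered matrix.
#' @param ops a [FemOperators-class] for the mesh the columns live on.
#' @param lambda smoothing parameter (>= 0); the study default is 1e-1.
#' @param init length-m nonzero start vector; default: first multivariate
#'   principal component of \code{Zc}.
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param maxIter maximum alternating sweeps (default 50).
#' @param factor optional prefactorized smoother from [smootherFactor()]
#'   (reused across components when fitting several at the same lambda).
#' @return a [SmoothPC-class].
#' @export
fitComponent <- function(Zc, ops, lambda, init = NULL,
                         tol = 1e-6, maxIter = 50L, factor = NULL) {
  X <- if (is(Zc, "ConnectivityMatrix")) Zc@values else as.matrix(Zc)
  m <- ncol(X)
  if (m != length(ops@massLumped))
    stop("matrix column count does not match mesh node count")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (is.null(init)) init <- svd(X, nu = 0L, nv = 1L)$v[, 1L]
  if (length(init) != m || all(init == 0)) stop("init must be a nonzero length-m vector")
  if (is.null(factor) && lambda > 0) factor <- smootherFactor(ops, lambda)

  f <- init / sqrt(sum(init ^ 2))
  s <- rep(0, nrow(X))
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # score step (f fixed)
    denom <- sum(f ^ 2) + lambda * roughness(ops, f)
    sNew <- as.numeric(X %*% f) / denom
    if (all(sNew == 0))
      stop("score vector collapsed to zero (data orthogonal to the ",
           "component); try a different init")
    # component step (s fixed)
    fNew <- applySmoother(factor, as.numeric(crossprod(X, sNew)) / sum(sNew ^ 2))
    nrm <- sqrt(sum(fNew ^ 2))
    sNew <- sNew * nrm
    fNew <- fNew / nrm
    obj <- c(obj, sfpcaObjective(X, ops, lambda, fNew, sNew))
    df <- sqrt(sum((fNew - f) ^ 2))
    ds <- if (iter == 1L) Inf else
      sqrt(sum((sNew - sPrev) ^ 2)) / max(sqrt(sum(sPrev ^ 2)), .Machine$double.eps)
    sPrev <- sNew
    f <- fNew
    s <- sNew
    if (df < tol && ds < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  if (!converged)
    warning(sprintf("component did not converge in %d iterations", maxIter))
  fs <- fixSign(f, s)
  new("SmoothPC", f = fs$f, s = fs$s, lambda = lambda,
      roughness = roughness(ops, fs$f), iterations = iter,
      converged = converged, objective = obj, evCumulative = NA_real_)
}

#' Smooth functional PCA with sequential deflation
#'
#' Centers the data once, then fits K components sequentially: each
#' component is estimated on the current residual by [fitComponent()]
#' (initialized from the residual's first multivariate PC), and the fitted
#' rank-1 term \eqn{s_k f_k'} is subtracted before the next. Cumulative
#' explained variance (residual Frobenius definition, see
#' [explainedVariance()]) is attached to every component.
#'
#' @param Z a [ConnectivityMatrix-class] (centered or not).
#' @param ops a [FemOperators-class].
#' @param lambda smoothing parameter; default 1e-1.
#' @param K number of components, \code{1 <= K <= min(n, m)}.
#' @param tol,maxIter convergence controls passed to [fitComponent()].
#' @return list of K [SmoothPC-class] objects.
#' @export
sfpca <- function(Z, ops, lambda = 1e-1, K = 4L, tol = 1e-6, maxIter = 50L) {
  stopifnot(is(Z, "ConnectivityMatrix"))
  Zc <- centerColumns(Z)
  X <- Zc@values
  if (K < 1L || K > min(dim(X)))
    stop(sprintf("K must lie in [1, %d]", min(dim(X))))
  total <- sum(X ^ 2)
  factor <- smootherFactor(ops, lambda)
  R <- X
  comps <- vector("list", K)
  for (k in seq_len(K)) {
    init <- svd(R, nu = 0L, nv = 1L)$v[, 1L]
    pc <- fitComponent(R, ops, lambda, init = init,
                       tol = tol, maxIter = maxIter, factor = factor)
    R <- R - tcrossprod(pc@s, pc@f)
    pc@evCumulative <- 1 - sum(R ^ 2) / total
    comps[[k]] <- pc
  }
  comps
}

#' Cumulative explained variance of fitted components
#'
#' Residual Frobenius definition: after k components,
#' \eqn{EV_k = 1 - \|Z_c - \sum_{j \le k} s_j f_j'\|_F^2 / \|Z_c\|_F^2}.
#' Non-decreasing in k for sequentially deflated fits.
#'
#' @param Zc the centered [ConnectivityMatrix-class] (or matrix) the
#'   components were fitted on.
#' @param comps list of [SmoothPC-class] objects (or a list with
#'   \code{loadings}/\code{scores} from [mvPCA()]).
#' @return numeric vector of cumulative fractions.
#' @export
explainedVariance <- function(Zc, comps) {
  X <- if (is(Zc, "ConnectivityMatrix")) Zc@values else as.matrix(Zc)
  if (!is.null(comps$loadings)) {
    K <- ncol(comps$loadings)
    comps <- lapply(seq_len(K), function(k)
      list(f = comps$loadings[, k], s = comps$scores[, k]))
  }
  total <- sum(X ^ 2)
  R <- X
  vapply(comps, function(pc) {
    f <- if (is(pc, "SmoothPC")) pc@f else pc$f
    s <- if (is(pc, "SmoothPC")) pc@s else pc$s
    if (length(f) != ncol(R) || length(s) != nrow(R))
      stop("component dimensions do not match the data matrix")
    R <<- R - tcrossprod(s, f)
    1 - sum(R ^ 2) / total
  }, numeric(1))
}
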