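# Linear (P1) finite elements on tetrahedra: volumes, mass, stiffness,
# the mixed-FEM squared-Laplacian roughness penalty, and the penalized
# nodal smoother that the alternating PCA minimization calls repeatedly.

# Signed volumes det([p2-p1, p3-p1, p4-p1])/6, vectorized over elements.
signedTetVolumes <- function(mesh) {
  nd <- mesh@nodes
  el <- mesh@elements
  a <- nd[el[, 2L], , drop = FALSE] - nd[el[, 1L], , drop = FALSE]
  b <- nd[el[, 3L], , drop = FALSE] - nd[el[, 1L], , drop = FALSE]
  c3 <- nd[el[, 4L], , drop = FALSE] - nd[el[, 1L], , drop = FALSE]
  (a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
   a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
   a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
}

meshIsConnected <- function(mesh) {
  m <- nrow(mesh@nodes)
  el <- mesh@elements
  pairs <- rbind(el[, c(1L, 2L)], el[, c(1L, 3L)], el[, c(1L, 4L)],
                 el[, c(2L, 3L)], el[, c(2L, 4L)], el[, c(3L, 4L)])
  adj <- Matrix::sparseMatrix(i = c(pairs[, 1L], pairs[, 2L]),
                              j = c(pairs[, 2L], pairs[, 1L]),
                              x = 1, dims = c(m, m))
  visited <- logical(m)
  frontier <- 1L
  visited[1L] <- TRUE
  while (length(frontier)) {
    nxt <- unique(adj@i[unlist(lapply(frontier, function(j)
      seq.int(adj@p[j] + 1L, length.out = adj@p[j + 1L] - adj@p[j])))] + 1L)
    frontier <- nxt[!visited[nxt]]
    visited[frontier] <- TRUE
  }
  all(visited)
}

#' Element volumes
#'
#' Volume of each tetrahedron, \eqn{|\det[p_2-p_1, p_3-p_1, p_4-p_1]|/6}.
#'
#' @param mesh a [TetMesh-class].
#' @return length-t vector of strictly positive volumes; their sum is the
#'   total domain volume.
#' @examples
#' mesh <- makeCubeMesh(2)
#' sum(tetVolumes(mesh))  # 1, the unit cube
#' @export
tetVolumes <- function(mesh) {
  v <- signedTetVolumes(mesh)
  bad <- which(abs(v) <= .Machine$double.eps * 10)
  if (length(bad))
    stop(sprintf("degenerate (coplanar) element at index %d", bad[1L]))
  abs(v)
}

# Per-element gradients of the four barycentric basis functions.
# Returns list(g = t x 4 x 3 array, vol = length-t volumes).
# Rows of inv(E) (E = [e1 e2 e3] columns) are the gradients of phi_2..4;
# computed via cross products: inv(E) = [e2 x e3; e3 x e1; e1 x e2] / det.
tetBasisGradients <- function(mesh) {
  nd <- mesh@nodes
  el <- mesh@elements
  e1 <- nd[el[, 2L], , drop = FALSE] - nd[el[, 1L], , drop = FALSE]
  e2 <- nd[el[, 3L], , drop = FALSE] - nd[el[, 1L], , drop = FALSE]
  e3 <- nd[el[, 4L], , drop = FALSE] - nd[el[, 1L], , drop = FALSE]
  crossRows <- function(u, v)
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  c23 <- crossRows(e2, e3)
  c31 <- crossRows(e3, e1)
  c12 <- crossRows(e1, e2)
  det6 <- rowSums(e1 * c23)  # 6 * signed volume
  if (any(abs(det6) <= .Machine$double.eps * 10))
    stop(sprintf("degenerate (coplanar) element at index %d",
                 which(abs(det6) <= .Machine$double.eps * 10)[1L]))
  g <- array(0, dim = c(nrow(el), 4L, 3L))
  g[, 2L, ] <- c23 / det6
  g[, 3L, ] <- c31 / det6
  g[, 4L, ] <- c12 / det6
  g[, 1L, ] <- -(g[, 2L, ] + g[, 3L, ] + g[, 4L, ])
  list(g = g, vol = abs(det6) / 6)
}

#' Assemble the P1 mass matrix
#'
#' Consistent element mass \eqn{(V_e/20)(1+\delta_{ij})} on each element's
#' 4x4 block, assembled by summation; the lumped variant is the row sums
#' (equivalently, V_e/4 per element vertex). The total entry sum equals the
#' domain volume in either case.
#'
#' @param mesh a [TetMesh-class].
#' @param lumped if TRUE return the length-m positive diagonal instead of
#'   the sparse consistent matrix.
#' @return sparse symmetric m x m matrix, or a numeric diagonal.
#' @export
assembleMass <- function(mesh, lumped = FALSE) {
  vol <- tetVolumes(mesh)
  el <- mesh@elements
  m <- nrow(mesh@nodes)
  if (lumped)
    return(as.numeric(Matrix::sparseMatrix(
      i = as.vector(el), j = rep(1L, length(el)),
      x = rep(vol / 4, 4L), dims = c(m, 1L))))
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- el[, a]
    jj[[k]] <- el[, b]
    xx[[k]] <- vol / 20 * (1 + (a == b))
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(m, m))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Assemble the P1 stiffness matrix
#'
#' Element stiffness \eqn{K_{ij} = V_e \nabla\phi_i \cdot \nabla\phi_j}
#' with the constant per-element gradients of the linear basis. Natural
#' (Neumann) boundary conditions: nothing is imposed on the boundary, so
#' the assembled matrix is symmetric positive semidefinite with A 1 = 0.
#'
#' @param mesh a [TetMesh-class].
#' @return sparse symmetric m x m matrix.
#' @export
assembleStiffness <- function(mesh) {
  bg <- tetBasisGradients(mesh)
  el <- mesh@elements
  m <- nrow(mesh@nodes)
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- el[, a]
    jj[[k]] <- el[, b]
    xx[[k]] <- bg$vol * rowSums(bg$g[, a, , drop = FALSE] *
                                bg$g[, b, , drop = FALSE], dims = 1L)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(m, m))
  Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
}

#' Build the finite-element operators of a mesh
#'
#' @param mesh a [TetMesh-class].
#' @return A [FemOperators-class] holding the consistent mass, lumped mass
#'   diagonal and stiffness matrix.
#' @export
femOperators <- function(mesh) {
  M <- assembleMass(mesh)
  new("FemOperators", mass = M,
      massLumped = as.numeric(Matrix::rowSums(M)),
      stiffness = assembleStiffness(mesh))
}

#' Squared-Laplacian roughness of a nodal field
#'
#' The mixed finite-element discretization of \eqn{\int_D (\Delta f)^2},
#' evaluated as \eqn{f' A M_L^{-1} A f} with the lumped mass: zero exactly
#' for constant fields, large for oscillatory ones.
#'
#' @param ops a [FemOperators-class].
#' @param f length-m node values.
#' @return nonnegative scalar.
#' @export
roughness <- function(ops, f) {
  if (length(f) != length(ops@massLumped))
    stop(sprintf("field length %d does not match mesh node count %d",
                 length(f), length(ops@massLumped)))
  af <- as.numeric(ops@stiffness %*% f)
  sum(af * af / ops@massLumped)
}

#' Factorized penalized smoother
#'
#' Cholesky factorization of \eqn{I + \lambda P}, \eqn{P = A M_L^{-1} A},
#' reusable across many right-hand sides (every iteration of the PCA
#' alternation solves with the same matrix).
#'
#' @param ops a [FemOperators-class].
#' @param lambda smoothing parameter, \eqn{\lambda \ge 0}.
#' @return an opaque factor object consumed by [applySmoother()], or NULL
#'   when \code{lambda == 0} (identity smoother).
#' @export
smootherFactor <- function(ops, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0) return(NULL)
  m <- length(ops@massLumped)
  P <- Matrix::crossprod(ops@stiffness,
                         (1 / ops@massLumped) * ops@stiffness)
  Matrix::Cholesky(Matrix::forceSymmetric(Matrix::Diagonal(m) + lambda * P),
                   LDL = FALSE)
}

#' Apply a factorized smoother
#' @param factor object from [smootherFactor()] (NULL means identity).
#' @param u length-m data vector.
#' @return smoothed length-m field.
#' @export
applySmoother <- function(factor, u) {
  if (is.null(factor)) return(as.numeric(u))
  as.numeric(Matrix::solve(factor, u))
}

#' Penalized nodal smoothing
#'
#' Minimizes \eqn{\sum_j (u_j - f_j)^2 + \lambda f' P f} over nodal fields
#' f, i.e. the inner f-step of the smooth-PCA alternation. Two routes are
#' provided: the sparse normal equations \eqn{(I + \lambda P) f = u} with
#' the lumped-mass penalty (default), and the equivalent 2x2 block mixed
#' system \eqn{\{f + \lambda A g = u;\; M g = A f\}} solved monolithically.
#' With the lumped mass in both, the routes agree to solver tolerance; the
#' block route can also use the consistent mass, a slightly different
#' discretization of the same penalty.
#'
#' @param ops a [FemOperators-class].
#' @param u length-m data vector (one value per node).
#' @param lambda smoothing parameter, \eqn{\lambda \ge 0}; 0 returns u.
#' @param method "normal" (default) or "mixed".
#' @param mass for \code{method = "mixed"}: "lumped" or "consistent".
#' @return length-m smoothed field.
#' @export
smoothField <- function(ops, u, lambda,
                        method = c("normal", "mixed"),
                        mass = c("lumped", "consistent")) {
  method <- match.arg(method)
  mass <- match.arg(mass)
  m <- length(ops@massLumped)
  if (length(u) != m)
    stop(sprintf("data length %d does not match mesh node count %d",
                 length(u), m))
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0) return(as.numeric(u))
  if (method == "normal")
    return(applySmoother(smootherFactor(ops, lambda), u))
  A <- ops@stiffness
  Mm <- if (mass == "lumped") Matrix::Diagonal(m, ops@massLumped) else ops@mass
  # [ I   lambda*A ] [f]   [u]
  # [ A     -M     ] [g] = [0]
  K <- rbind(cbind(Matrix::Diagonal(m), lambda * A), cbind(A, -Mm))
  sol <- tryCatch(Matrix::solve(K, c(u, rep(0, m))),
                  error = function(e)
                    stop("mixed-system solve failed (singular or ",
                         "ill-conditioned): ", conditionMessage(e)))
  as.numeric(sol[seq_len(m)])
}
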