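# The penalized rank-1 alternation, its multivariate limit, deflation and
# explained variance.

test_that("centerColumns zeroes node means and keeps the removed map", {
  Z <- connectivityMatrix(rbind(c(1, 3), c(3, 5)))
  Zc <- centerColumns(Z)
  expect_equal(connValues(Zc), rbind(c(-1, -1), c(1, 1)))
  expect_equal(Zc@centerMap, c(2, 4))
  Zi <- connectivityMatrix(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(max(abs(connValues(centerColumns(Zi)))), 0)
  set.seed(1)
  Zr <- centerColumns(connectivityMatrix(matrix(rnorm(50), 5)))
  expect_lt(max(abs(colMeans(connValues(Zr)))), 1e-14)
  expect_error(connectivityMatrix(rbind(c(1, NA), c(0, 1))), "non-finite")
})

test_that("mvPCA matches a dense SVD oracle", {
  set.seed(4)
  X <- matrix(rnorm(10 * 30), 10, 30)
  X <- sweep(X, 2, colMeans(X))
  res <- mvPCA(X, 3)
  sv <- svd(X)
  for (k in 1:3)
    expect_gt(abs(sum(res$loadings[, k] * sv$v[, k])), 1 - 1e-8)
  expect_equal(crossprod(res$loadings), diag(3), tolerance = 1e-10)
  expect_equal(res$evCumulative, cumsum(sv$d[1:3] ^ 2) / sum(sv$d ^ 2),
               tolerance = 1e-12)
  # exact rank-1 input: loading is the planted direction up to sign
  f0 <- rnorm(30); s0 <- rnorm(10)
  r1 <- mvPCA(tcrossprod(s0, f0), 1)
  expect_gt(abs(sum(r1$loadings[, 1] * f0 / sqrt(sum(f0 ^ 2)))), 1 - 1e-10)
  expect_error(mvPCA(X, 11), "K must lie")
})

test_that("lambda = 0 component equals the first multivariate PC", {
  ops <- cubeOps(6)
  m <- nNodes(cubeMesh(6))
  set.seed(3)
  X <- matrix(rnorm(20 * m), 20)
  X <- sweep(X, 2, colMeans(X))
  pc <- fitComponent(X, ops, 0)
  sv <- svd(X, nu = 1, nv = 1)
  expect_gt(abs(sum(pc@f * sv$v[, 1])), 1 - 1e-8)
  expect_equal(abs(pc@s), abs(sv$u[, 1] * sv$d[1]), tolerance = 1e-6)
})

test_that("update formulas agree with a numerical optimizer on a tiny instance", {
  mesh <- cubeMesh(1)  # 8 nodes
  ops <- femOperators(mesh)
  set.seed(5)
  X <- matrix(rnorm(5 * 8), 5, 8)
  X <- sweep(X, 2, colMeans(X))
  lam <- 0.1
  pc <- fitComponent(X, ops, lam, tol = 1e-10, maxIter = 200)
  A <- as.matrix(ops@stiffness)
  P <- t(A) %*% (A / ops@massLumped)
  objective <- function(theta) {
    f <- theta[1:8]; s <- theta[9:13]
    sum((X - tcrossprod(s, f)) ^ 2) + lam * sum(s ^ 2) * drop(f %*% P %*% f)
  }
  opt <- optim(c(pc@f * 1.05 + 0.01, pc@s * 0.95), objective,
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  ours <- objective(c(pc@f, pc@s))
  expect_lte(ours, opt$value + 1e-6 * abs(opt$value))
  # and the optimizer does not find a meaningfully better minimum
  expect_equal(ours, opt$value, tolerance = 1e-4)
})

test_that("noiseless planted rank-1 signal is recovered", {
  ops <- cubeOps(6)
  f0 <- plantedModes(cubeMesh(6), 1, seed = 2)[, 1]
  set.seed(6)
  s0 <- rnorm(20, sd = 2)
  Z <- tcrossprod(s0, f0)
  Zc <- sweep(Z, 2, colMeans(Z))
  pc <- fitComponent(Zc, ops, 1e-3)
  expect_gt(abs(cor(pc@f, f0)), 0.999)
})

test_that("fitted roughness is non-increasing in lambda", {
  ops <- cubeOps(6)
  f0 <- plantedModes(cubeMesh(6), 1, seed = 2)[, 1]
  set.seed(4)
  Z <- tcrossprod(rnorm(20, sd = 2), f0) +
    matrix(rnorm(20 * nNodes(cubeMesh(6)), sd = 0.3), 20)
  Zc <- sweep(Z, 2, colMeans(Z))
  rr <- vapply(c(1e-3, 1e-1, 10), function(l)
    fitComponent(Zc, ops, l)@roughness, numeric(1))
  expect_true(all(diff(rr) <= 0))
})

test_that("objective is non-increasing across iterations", {
  ops <- cubeOps(6)
  set.seed(8)
  for (lam in c(0, 1e-2, 1)) {
    X <- matrix(rnorm(15 * nNodes(cubeMesh(6))), 15)
    X <- sweep(X, 2, colMeans(X))
    pc <- suppressWarnings(fitComponent(X, ops, lam))
    expect_true(all(diff(pc@objective) <= 1e-8 * pc@objective[1]))
  }
})

test_that("scale and sign reparametrizations leave the fit invariant", {
  ops <- cubeOps(4)
  m <- nNodes(cubeMesh(4))
  set.seed(9)
  f0 <- plantedModes(cubeMesh(4), 1, seed = 9)[, 1]
  X <- tcrossprod(rnorm(12, sd = 2), f0) + matrix(rnorm(12 * m, sd = 0.3), 12)
  X <- sweep(X, 2, colMeans(X))
  init <- svd(X, nu = 0, nv = 1)$v[, 1]
  base <- fitComponent(X, ops, 0.1, init = init, tol = 1e-9, maxIter = 500)
  for (pert in list(-init, 3 * init, -0.2 * init + 1e-3)) {
    alt <- fitComponent(X, ops, 0.1, init = pert, tol = 1e-9, maxIter = 500)
    expect_equal(alt@f, base@f, tolerance = 1e-6)
    expect_equal(alt@s, base@s, tolerance = 1e-6)
  }
  # sign convention: the largest-|.| entry of f is positive
  expect_gt(base@f[which.max(abs(base@f))], 0)
})

test_that("deflation: rank-1 data explained fully by one component", {
  ops <- cubeOps(4)
  f0 <- plantedModes(cubeMesh(4), 1, seed = 3)[, 1]
  set.seed(10)
  Z <- connectivityMatrix(tcrossprod(rnorm(12, sd = 2), f0))
  comps <- suppressWarnings(sfpca(Z, ops, lambda = 0, K = 2))
  expect_equal(comps[[1]]@evCumulative, 1, tolerance = 1e-10)
  expect_lt(comps[[2]]@evCumulative - comps[[1]]@evCumulative, 1e-8)
})

test_that("sfpca recovers planted modes and is deterministic", {
  mesh <- cached("cube10", makeCubeMesh(10))
  ops <- cached("ops10", femOperators(mesh))
  sim <- simulateMaps(mesh, seed = 11)
  comps <- suppressWarnings(sfpca(sim$Z, ops, lambda = 0.1, K = 4))
  for (k in 1:3)
    expect_gt(abs(sum(componentField(comps[[k]]) * sim$truth@modes[, k])), 0.9)
  ev <- vapply(comps, function(p) p@evCumulative, numeric(1))
  expect_true(all(diff(ev) >= 0))
  again <- suppressWarnings(sfpca(sim$Z, ops, lambda = 0.1, K = 4))
  expect_identical(lapply(comps, componentField), lapply(again, componentField))
  expect_identical(lapply(comps, componentScores), lapply(again, componentScores))
  expect_error(sfpca(sim$Z, ops, K = 10000), "K must lie")
})

test_that("explained variance matches the singular-value identity for mvPCA", {
  set.seed(12)
  X <- matrix(rnorm(20 * 100), 20)
  X <- sweep(X, 2, colMeans(X))
  K <- 5
  res <- mvPCA(X, K)
  ev <- explainedVariance(X, res)
  d <- svd(X)$d
  expect_equal(ev, cumsum(d[1:K] ^ 2) / sum(d ^ 2), tolerance = 1e-8)
  expect_equal(explainedVariance(X, list()), numeric(0))
})
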