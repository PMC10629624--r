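# Shared fixtures, built in code and cached per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# The reference tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1): volume 1/6,
# closed-form mass and stiffness entries.
refTet <- function() {
  tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(1:4))
}

cubeMesh <- function(k) cached(paste0("cube", k), makeCubeMesh(k))

cubeOps <- function(k)
  cached(paste0("ops", k), femOperators(cubeMesh(k)))

# Planted ±1 cross-slit contrast on the C-shaped mesh, smoothed through
# the connector only; returns the fraction of the planted mean cross-slit
# contrast lost after smooth-PCA at the given lambda, plus the alignment.
cshapeLeakage <- function(seed = 2L, lambda = 0.1, n = 40L, noiseSd = 0.2) {
  cs <- cached("cshape", makeCShapeMesh(8L, 2L))
  ops <- cached("cshapeOps", femOperators(cs))
  nd <- meshNodes(cs)
  lab <- nodeLabels(cs)
  w <- 0.06 + 0.6 * pmax(0, 0.35 - nd[, 1L])  # steep in arms, gentle in connector
  f0 <- tanh((nd[, 2L] - 0.5) / w)
  f0 <- f0 / sqrt(sum(f0 ^ 2))
  set.seed(seed)
  s0 <- rnorm(n, sd = 2)
  Z <- connectivityMatrix(tcrossprod(s0, f0) +
                            matrix(rnorm(n * nNodes(cs), sd = noiseSd), n))
  fh <- componentField(suppressWarnings(sfpca(Z, ops, lambda = lambda,
                                              K = 1L))[[1L]])
  align <- sum(fh * f0)
  fhs <- fh / align
  gap <- 2 / 8
  bot <- which(lab == 1L & abs(nd[, 2L] - (0.5 - gap / 2)) < 1e-9 & nd[, 1L] > 0.3)
  top <- which(lab == 2L & abs(nd[, 2L] - (0.5 + gap / 2)) < 1e-9 & nd[, 1L] > 0.3)
  contrast0 <- mean(f0[top]) - mean(f0[bot])
  contrast <- mean(fhs[top]) - mean(fhs[bot])
  list(leakage = max(0, (contrast0 - contrast) / contrast0),
       align = abs(align) / sqrt(sum(fhs ^ 2) * sum(f0 ^ 2)) * sqrt(sum(fhs ^ 2)),
       absCos = abs(sum(fh * f0)))
}

# Regression-based amplitude gain of the highpass filter at one frequency.
filterGain <- function(freqHz, tr = 2, T = 300, cutoff = 0.01) {
  t <- (seq_len(T) - 1L) * tr
  x <- sin(2 * pi * freqHz * t)
  y <- highpassFilter(boldRecording(rbind(x), tr), cutoff)@series[1L, ]
  sqrt(sum(coef(lm(y ~ sin(2 * pi * freqHz * t) + cos(2 * pi * freqHz * t) - 1)) ^ 2))
}
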