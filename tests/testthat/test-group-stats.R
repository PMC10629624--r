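# Rank-sum tests, LOO-LDA, AUC, covariate checks, median maps.

test_that("exact rank-sum enumeration: separated samples, ties, cross-check", {
  res <- rankSumTest(c(1, 2, 3), c(10, 11, 12))
  expect_identical(res$method, "exact")
  expect_equal(res$p.value, 0.1)  # 2 of the 20 rank assignments as extreme
  expect_equal(res$p.value, wilcox.test(c(1, 2, 3), c(10, 11, 12))$p.value)
  same <- rankSumTest(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_gte(same$p.value, 0.99)
  expect_error(rankSumTest(numeric(0), 1), "non-empty")
  expect_error(rankSumTest(1, numeric(0)), "non-empty")
})

test_that("exact and normal routes agree within 0.01 where both are sound", {
  # all untied configurations with >= 3 per group and N in 9..12:
  # compare the exact enumeration p with the Edgeworth-corrected normal p
  # at every achievable U (ranks as data, so no ties)
  for (n1 in 3:6) for (n2 in n1:(12 - n1)) {
    if (n1 + n2 < 9) next
    N <- n1 + n2; mu <- n1 * n2 / 2
    sets <- combn(N, n1)
    Uall <- colSums(matrix(seq_len(N)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    s2 <- n1 * n2 * (N + 1) / 12
    e4 <- -(6 / 5) * (n1 ^ 2 + n2 ^ 2 + n1 * n2 + N) / (n1 * n2 * (N + 1))
    for (u in 0:(n1 * n2)) {
      pExact <- mean(abs(Uall - mu) >= abs(u - mu) - 1e-9)
      z <- (min(u, n1 * n2 - u) + 0.5 - mu) / sqrt(s2)
      pNorm <- min(1, 2 * (pnorm(z) - e4 / 24 * (z ^ 3 - 3 * z) * dnorm(z)))
      expect_lt(abs(pExact - pNorm), 0.01)
    }
  }
  # and the implementation's normal route reproduces that approximation
  set.seed(2)
  x <- rnorm(20); y <- rnorm(25)
  got <- rankSumTest(x, y)
  expect_identical(got$method, "normal")
  expect_equal(got$p.value, wilcox.test(x, y, correct = TRUE)$p.value,
               tolerance = 0.005)
})

test_that("rank-sum type-I error at alpha = 0.01 stays near nominal", {
  set.seed(1)
  rej <- mean(replicate(1000,
    rankSumTest(rnorm(30), rnorm(30))$p.value < 0.01))
  expect_gte(rej, 0.004)
  expect_lte(rej, 0.02)
})

test_that("rank-sum p is invariant to common monotone transforms", {
  set.seed(5)
  x <- rexp(8); y <- rexp(9) + 0.5
  p0 <- rankSumTest(x, y)$p.value
  expect_equal(rankSumTest(log(x), log(y))$p.value, p0)
  expect_equal(rankSumTest(x ^ 3, y ^ 3)$p.value, p0)
})

test_that("LOO-LDA separates well-separated clusters and is sign-symmetric", {
  set.seed(6)
  S <- rbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 4, mean = 10), 20))
  gl <- groupLabels(rep(c("g1", "g2"), each = 20))
  loo <- ldaLooScores(S, gl)
  expect_equal(aucStatistic(loo, gl), 1)
  flipped <- groupLabels(factor(rep(c("g1", "g2"), each = 20),
                                levels = c("g2", "g1")))
  expect_equal(ldaLooScores(S, flipped), -loo, tolerance = 1e-10)
})

test_that("K = 1 LOO-LDA matches the pooled-variance closed form", {
  set.seed(7)
  S1 <- matrix(c(rnorm(20), rnorm(20, 2)), ncol = 1)
  gl <- groupLabels(rep(c("a", "b"), each = 20))
  loo <- ldaLooScores(S1, gl)
  oracle <- vapply(1:40, function(i) {
    x <- S1[-i, 1]; g <- gl@group[-i]
    m1 <- mean(x[g == "a"]); m2 <- mean(x[g == "b"])
    s2p <- ((sum(g == "a") - 1) * var(x[g == "a"]) +
            (sum(g == "b") - 1) * var(x[g == "b"])) / (length(x) - 2)
    (S1[i, 1] - (m1 + m2) / 2) * (m2 - m1) / s2p +
      log(sum(g == "b") / sum(g == "a"))
  }, numeric(1))
  expect_equal(loo, oracle, tolerance = 1e-8)
})

test_that("LOO-LDA ranks subjects like the MASS posterior ratio", {
  skip_if_not_installed("MASS")
  set.seed(8)
  S <- rbind(matrix(rnorm(15 * 3), 15), matrix(rnorm(15 * 3, 1), 15))
  gl <- groupLabels(rep(c("a", "b"), each = 15))
  loo <- ldaLooScores(S, gl)
  looM <- vapply(1:30, function(i) {
    fit <- MASS::lda(S[-i, , drop = FALSE], grouping = gl@group[-i])
    pr <- predict(fit, S[i, , drop = FALSE])
    log(pr$posterior[, "b"] / pr$posterior[, "a"])
  }, numeric(1))
  expect_equal(loo, looM, tolerance = 1e-6)
})

test_that("AUC: pair counting, ties, complement and monotone invariance", {
  gl <- groupLabels(c("neg", "neg", "pos", "pos"))
  vals <- c(0.5, 0.1, 0.9, 0.4)
  expect_equal(aucStatistic(vals, gl), 0.75)
  skip_if_not_installed("pROC")
  expect_equal(aucStatistic(vals, gl),
               as.numeric(pROC::auc(pROC::roc(
                 response = gl@group, predictor = vals, levels = c("neg", "pos"),
                 direction = "<", quiet = TRUE))))
  expect_equal(aucStatistic(rep(1, 4), gl), 0.5)
  flipped <- groupLabels(factor(c("neg", "neg", "pos", "pos"),
                                levels = c("pos", "neg")))
  expect_equal(aucStatistic(vals, gl) + aucStatistic(vals, flipped), 1)
  expect_equal(aucStatistic(exp(10 * vals), gl), aucStatistic(vals, gl))
})

test_that("median expression maps scale the component by the group median", {
  pc <- new("SmoothPC", f = c(0.6, 0.8), s = c(-1, 0, 1, 2), lambda = 0.1,
            roughness = 0, iterations = 1L, converged = TRUE,
            objective = 1, evCumulative = NA_real_)
  gl <- groupLabels(c("A", "A", "A", "B"))
  expect_equal(medianExpressionMap(pc, gl, "A"), c(0, 0))
  expect_equal(medianExpressionMap(pc, gl, "B"), 2 * c(0.6, 0.8))
  expect_error(medianExpressionMap(pc, gl, "C"), "empty or absent")
})

test_that("pearsonR: affine, sign, the 4-point value, and degenerate input", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearsonR(a, 3 * a + 1), 1)
  expect_equal(pearsonR(a, -a), -1)
  expect_equal(round(pearsonR(a, c(1, 2, 3, 5)), 3), 0.983)
  expect_error(pearsonR(a, rep(1, 4)), "constant")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("groupComparison assembles the per-component report", {
  set.seed(9)
  S <- cbind(c(rnorm(15), rnorm(15, 3)), rnorm(30))
  gl <- groupLabels(rep(c("CTRL", "SCHZ"), each = 15),
                    sex = rep(c("F", "M"), 15), age = runif(30, 20, 50))
  res <- groupComparison(list(scores = S), gl, alpha = 0.01)
  expect_equal(nrow(res$perComponent), 2)
  expect_true(res$perComponent$significant[1])
  expect_false(res$perComponent$significant[2])
  expect_gt(res$auc, 0.9)
  expect_equal(nrow(res$covariates), 2)
})
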