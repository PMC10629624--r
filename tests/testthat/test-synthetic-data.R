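# Generators: meshes, planted modes, group score models, synthetic BOLD.

test_that("cube meshes have the predicted node/element counts and unit volume", {
  m1 <- cubeMesh(1)
  expect_identical(nNodes(m1), 8L)
  expect_identical(nElements(m1), 6L)
  m2 <- cubeMesh(2)
  expect_identical(nNodes(m2), 27L)
  expect_identical(nElements(m2), 48L)
  for (k in c(1, 2, 5))
    expect_equal(sum(tetVolumes(cubeMesh(k))), 1, tolerance = 1e-12)
})

test_that("C-shaped mesh: connected, slit removed, Euclid-near but path-far", {
  skip_if_not_installed("igraph")
  cs <- makeCShapeMesh(8, 2)
  nd <- meshNodes(cs)
  # no nodes inside the removed band
  gap <- 2 / 8
  inSlit <- nd[, 1] > 0.25 + 1e-9 & abs(nd[, 2] - 0.5) < gap / 2 - 1e-9
  expect_identical(sum(inSlit), 0L)
  # a node pair facing each other across the slit at the far end
  bot <- which(abs(nd[, 1] - 1) < 1e-9 & abs(nd[, 2] - (0.5 - gap / 2)) < 1e-9 &
               abs(nd[, 3] - 0.5) < 1e-9)[1]
  top <- which(abs(nd[, 1] - 1) < 1e-9 & abs(nd[, 2] - (0.5 + gap / 2)) < 1e-9 &
               abs(nd[, 3] - 0.5) < 1e-9)[1]
  euclid <- sqrt(sum((nd[bot, ] - nd[top, ]) ^ 2))
  expect_lt(euclid, 2 * gap)
  el <- meshElements(cs)
  edges <- unique(rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                        el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- sqrt(rowSums(
    (nd[edges[, 1], ] - nd[edges[, 2], ]) ^ 2))
  expect_equal(igraph::components(g)$no, 1)
  pathLen <- igraph::distances(g, v = bot, to = top)[1, 1]
  expect_gt(pathLen, 5 * euclid)
  expect_error(makeCShapeMesh(4, 4), "disconnected")
})

test_that("planted modes are orthonormal, smooth, and seed-deterministic", {
  mesh <- cubeMesh(6)
  modes <- plantedModes(mesh, 4, seed = 3)
  expect_equal(crossprod(modes), diag(4), tolerance = 1e-8)
  ops <- cubeOps(6)
  set.seed(3)
  noise <- rnorm(nNodes(mesh))
  noise <- noise / sqrt(sum(noise ^ 2))
  for (k in 1:4)
    expect_lt(roughness(ops, modes[, k]), roughness(ops, noise))
  expect_identical(plantedModes(mesh, 4, seed = 3), modes)
  expect_error(plantedModes(mesh, 9), "\\[1, 8\\]")
})

test_that("simulateMaps plants the requested structure reproducibly", {
  mesh <- cubeMesh(5)
  # noiseless, shiftless: rows lie in the mode span
  sim0 <- simulateMaps(mesh, nPerGroup = c(5, 5), noiseSd = 0,
                       shiftMode = 0, seed = 2)
  Zc <- connValues(centerColumns(sim0$Z))
  proj <- Zc %*% sim0$truth@modes %*% t(sim0$truth@modes)
  expect_lt(max(abs(Zc - proj)), 1e-10)
  # group shift recovered at large n
  simN <- simulateMaps(mesh, nPerGroup = c(200, 200), seed = 3)
  g <- simN$labels@group
  delta <- diff(simN$truth@scoreMeans[, 2])
  diffHat <- mean(simN$scores[g == "SCHZ", 2]) -
    mean(simN$scores[g == "CTRL", 2])
  se <- simN$truth@scoreSds[2] * sqrt(2 / 200)
  expect_lt(abs(diffHat - delta), 3 * se)
  # determinism
  simA <- simulateMaps(mesh, seed = 7)
  simB <- simulateMaps(mesh, seed = 7)
  expect_identical(connValues(simA$Z), connValues(simB$Z))
  expect_error(simulateMaps(mesh, nPerGroup = c(0, 10)), "positive")
})

test_that("simulateBold realizes the prescribed correlation field", {
  mesh <- cubeMesh(6)
  seedr <- selectSeed(nodeLabels(mesh), 1L)
  m <- nNodes(mesh)
  ns <- setdiff(seq_len(m), seedr@nodeIndices)
  nd <- meshNodes(mesh)
  rho <- 0.5 + 0.4 * cos(pi * nd[, 1])
  bold <- simulateBold(mesh, seedr, rho, T = 300, tr = 2, seed = 4)
  sm <- seedMean(bold, seedr)
  emp <- as.numeric(correlationMap(bold, sm))
  expect_gte(mean(abs(emp[ns] - rho[ns]) <= 0.1), 0.95)
  # rho = 1 nodes carry the latent signal itself (up to the seed jitter)
  rho1 <- rep(0, m); rho1[ns[1]] <- 0.99
  b1 <- simulateBold(mesh, seedr, pmin(rho1, 0.99), T = 150, tr = 2, seed = 5)
  expect_gt(cor(b1@series[ns[1], ], seedMean(b1, seedr)), 0.97)
  # rho = 0 nodes stay within the null sampling band almost everywhere
  b0 <- simulateBold(mesh, seedr, rep(0, m), T = 300, tr = 2, seed = 6)
  emp0 <- as.numeric(correlationMap(b0, seedMean(b0, seedr)))
  expect_gte(mean(abs(emp0[ns]) <= 3 / sqrt(300)), 0.98)
  expect_error(simulateBold(mesh, seedr, rep(1, m)), "0.99")
  expect_error(simulateBold(mesh, seedr, rep(0, m), T = 20), "50")
  # determinism
  bA <- simulateBold(mesh, seedr, rho, T = 100, tr = 2, seed = 9)
  bB <- simulateBold(mesh, seedr, rho, T = 100, tr = 2, seed = 9)
  expect_identical(bA@series, bB@series)
})
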