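test_that("correlationMatrix matches the textbook Pearson formula", {
  set.seed(1)
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cc <- correlationMatrix(v)
  # direct formula evaluation, independent of stats::cor
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(cc[i, j], pearson(v[i, ], v[j, ]), tolerance = 1e-12)
  expect_equal(diag(cc), c(g1 = 1, g2 = 1, g3 = 1))

  dup <- rbind(v, g4 = v[1, ], g5 = -v[1, ])
  cc2 <- correlationMatrix(dup)
  expect_equal(cc2["g1", "g4"], 1)
  expect_equal(cc2["g1", "g5"], -1)
})

test_that("correlationMatrix rejects degenerate inputs", {
  v <- matrix(rnorm(4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(correlationMatrix(v), "3 samples")
  v2 <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  expect_error(correlationMatrix(v2), "zero-variance")
})

test_that("soft adjacency is the powered correlation with monotone order", {
  set.seed(2)
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  cc <- correlationMatrix(v)
  a1 <- softAdjacency(cc, networkParams(softPower = 1))
  expect_equal(a1[1, 2], abs(cc[1, 2]))
  expect_equal(diag(a1), setNames(rep(0, 5), rownames(cc)))
  cc2 <- cc; cc2[1, 2] <- cc2[2, 1] <- 0.5
  a9 <- softAdjacency(cc2, networkParams(softPower = 9))
  expect_equal(a9[1, 2], 0.5^9)
  # |corr_ij| >= |corr_kl| implies a_ij >= a_kl at fixed power
  ord <- order(abs(cc[upper.tri(cc)]))
  a <- softAdjacency(cc, networkParams(softPower = 6))
  expect_false(is.unsorted(a[upper.tri(a)][ord]))
  expect_error(networkParams(softPower = 0), "softPower")
})

test_that("scale-free fit recognises a planted power-law degree sequence", {
  kvals <- seq(4, 40, length.out = 10)
  kdes <- rep(kvals, times = round(300 * kvals^-1.5))
  S <- sum(kdes)
  a <- outer(kdes, kdes) / S
  diag(a) <- 0
  a <- pmin(a, 1)
  r2 <- scaleFreeFit(a, nBins = 10)
  expect_gte(r2, 0.95)
  expect_identical(r2, scaleFreeFit(a, nBins = 10))  # reproducible
  # constant-connectivity network: undefined fit reported as 0
  ac <- matrix(0.5, 12, 12); diag(ac) <- 0
  expect_warning(r0 <- scaleFreeFit(ac), "constant")
  expect_equal(r0, 0)
  expect_error(scaleFreeFit(matrix(0, 12, 12)), "all-zero")
})

test_that("TOM matches hand evaluation on small graphs", {
  # two genes joined by a_12 = 1 and no other edges
  a <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  expect_equal(tomSimilarity(a)["g1", "g2"], 1)
  # triangle with all a = 0.5: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  dimnames(a3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom <- tomSimilarity(a3)
  expect_equal(tom[1, 2], 0.5)
  # isolated gene: zero TOM to everyone
  a4 <- rbind(cbind(a3, 0), 0)
  dimnames(a4) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(unname(tomSimilarity(a4)[4, 1:3]), rep(0, 3))
})

test_that("TOM is a similarity: bounded, symmetric, unit diagonal", {
  set.seed(3)
  v <- matrix(rnorm(600), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  a <- softAdjacency(correlationMatrix(v), networkParams(softPower = 6))
  tom <- tomSimilarity(a)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(tom, t(tom))
  expect_equal(unname(diag(tom)), rep(1, 30))
  expect_true(all(tom[upper.tri(tom)] >= a[upper.tri(a)] /
                    (pmin(outer(rowSums(a), rowSums(a), pmin))[upper.tri(a)] + 1)))
})

test_that("branch cut recovers planted TOM blocks and respects minModuleSize", {
  tom <- blockTom(c(20, 20), within = 0.9, between = 0.05)
  # blocks join at dissimilarity 1 - 0.05 = 0.95; cut below that height
  p <- networkParams(minModuleSize = 15L, deepSplit = 0L, cutHeight = 0.9)
  ms <- clusterAndCut(tom, p)
  expect_length(moduleLabels(ms), 2L)
  expect_equal(unname(moduleSizes(ms)), c(20L, 20L))
  expect_length(unique(ms@assignment[paste0("g", 1:20)]), 1L)
  expect_length(unique(ms@assignment[paste0("g", 21:40)]), 1L)

  # a 10-gene block cannot reach minModuleSize 15
  tom2 <- blockTom(c(20, 10), within = 0.9, between = 0.05)
  ms2 <- clusterAndCut(tom2, p)
  expect_length(moduleLabels(ms2), 1L)
  expect_setequal(unassignedGenes(ms2), paste0("g", 21:30))

  expect_warning(
    clusterAndCut(blockTom(c(5), nNoise = 2),
                  networkParams(minModuleSize = 15L)),
    "all unassigned")
})

test_that("deepSplit never reduces the module count", {
  # nested structure: two tight 15-gene halves inside one 30-gene block
  tom <- blockTom(c(30, 20), within = 0.75, between = 0.05)
  tom[1:15, 1:15] <- 0.95
  tom[16:30, 16:30] <- 0.95
  diag(tom) <- 1
  p0 <- networkParams(minModuleSize = 10L, deepSplit = 0L, cutHeight = 0.97)
  p2 <- networkParams(minModuleSize = 10L, deepSplit = 2L, cutHeight = 0.97)
  n0 <- length(moduleLabels(clusterAndCut(tom, p0)))
  n2 <- length(moduleLabels(clusterAndCut(tom, p2)))
  expect_lte(n0, n2)
  expect_gte(n2, 3L)
})

test_that("module eigengene is the dominant unit projection, stably oriented", {
  set.seed(4)
  n <- 25L
  f <- rnorm(n)
  X <- matrix(rep(f, each = 10), 10, n) + rnorm(10 * n, sd = 0.01)
  dimnames(X) <- list(paste0("g", 1:10), paste0("s", 1:n))
  e <- moduleEigengene(X, rownames(X))
  expect_equal(sum(e^2), 1, tolerance = 1e-10)
  expect_gt(abs(cor(e, f)), 0.999)
  expect_gte(cor(e, colMeans(X)), 0)
  # flipping all gene rows leaves the orientation contract intact
  e2 <- moduleEigengene(-X, rownames(X))
  expect_gte(cor(e2, colMeans(-X)), 0)

  # variance explained beats random unit projections (Monte-Carlo oracle)
  set.seed(5)
  X5 <- matrix(rnorm(5 * n), 5, n,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  z <- t(scale(t(X5)))
  e5 <- moduleEigengene(X5, rownames(X5))
  vE <- sum((z %*% e5)^2)
  for (i in 1:200) {
    u <- rnorm(n); u <- u / sqrt(sum(u^2))
    expect_lte(sum((z %*% u)^2), vE + 1e-8)
  }
})

test_that("eigengene merging joins artificially split modules and is idempotent", {
  set.seed(6)
  n <- 30L
  f <- rnorm(n)
  X <- matrix(rep(f, each = 20), 20, n) + rnorm(20 * n, sd = 0.3)
  g2 <- rnorm(n)
  X <- rbind(X, matrix(rep(g2, each = 10), 10, n) + rnorm(10 * n, sd = 0.3))
  dimnames(X) <- list(paste0("g", 1:30), paste0("s", 1:n))
  split <- moduleSet(setNames(
    c(rep("a", 10), rep("b", 10), rep("c", 10)), rownames(X)))
  merged <- mergeModules(X, split, 0.30)
  expect_length(moduleLabels(merged), 2L)
  expect_length(unique(merged@assignment[paste0("g", 1:20)]), 1L)
  # MEDissThres = 0: identity
  same <- mergeModules(X, split, 0)
  expect_equal(sort(unname(table(same@assignment))),
               sort(unname(table(split@assignment))))
  # near-zero threshold on dissimilar modules: no merging
  tiny <- mergeModules(X, split, 0.0001)
  expect_length(moduleLabels(tiny), 3L)
  # idempotent
  again <- mergeModules(X, merged, 0.30)
  expect_identical(again@assignment, merged@assignment)
})

test_that("module-trait correlation matches the exact t-distribution p-value", {
  set.seed(7)
  n <- 20L
  f <- rnorm(n)
  X <- matrix(rep(f, each = 5), 5, n) + rnorm(5 * n, sd = 1e-6)
  dimnames(X) <- list(paste0("g", 1:5), paste0("s", 1:n))
  e <- moduleEigengene(X, rownames(X))
  tr <- data.frame(same = as.numeric(e) * 3 + 1,
                   lin = seq_len(n) * 2,
                   other = rnorm(n),
                   row.names = colnames(X))
  te <- tissueExpression(X, tr)
  ms <- moduleSet(setNames(rep("M1", 5), rownames(X)))
  res <- moduleTraitCorrelation(te, ms)
  expect_equal(res@r["M1", "same"], 1, tolerance = 1e-6)
  expect_lt(res@p["M1", "same"], 1e-10)
  # closed-form oracle for a fixed 10-sample pair
  x <- e[1:10]; y <- tr$other[1:10]
  ct <- cor.test(x, y)
  r <- res@r["M1", "other"]
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res@p["M1", "other"], 2 * pt(-abs(tt), n - 2))
  expect_equal(unname(cor(x, y)), unname(ct$estimate), tolerance = 1e-12)
  expect_true(res@associated[["M1"]])

  # a perfectly linear pair of vectors has correlation exactly 1
  expect_equal(cor(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10)), 1)

  trc <- tr; trc$flat <- 5
  tec <- tissueExpression(X, trc)
  expect_warning(resc <- moduleTraitCorrelation(tec, ms), "constant trait")
  expect_equal(resc@p["M1", "flat"], 1)
  expect_true(is.na(resc@r["M1", "flat"]))
})

test_that("detected modules recover the planted partition", {
  sc <- strongScenario(seed = 7)
  out <- generateExpression(sc$config, "blood")
  ms <- detectModules(out$data, sc$netParams)
  det <- ms@assignment[names(out$truth@assignment)]
  ari <- mclust::adjustedRandIndex(out$truth@assignment, det)
  expect_gte(ari, 0.9)
})
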