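test_that("annotation overlap counts shared concepts within one category", {
  top <- sprintf("c%02d", 1:20)
  expect_equal(annotationOverlap(top, top), 20L)
  expect_equal(annotationOverlap(top, paste0("x", 1:20)), 0L)
  expect_equal(annotationOverlap(c("c1", "c3", "c5", "c9", "c11"),
                                 c("c1", "c5", "c9", "c20")), 3L)
  expect_error(annotationOverlap(top, top, "biological_process",
                                 "molecular_function"), "categories")
})

test_that("gene overlap respects the identifier mapping", {
  expect_equal(geneOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 2L)
  expect_equal(geneOverlap(c("g1", "g2"), c("g1", "g2")), 2L)
  expect_equal(geneOverlap("g1", "g2"), 0L)
  idMap <- c(b1 = "E1", b2 = "E2", n1 = "E1")
  expect_equal(geneOverlap(c("b1", "b2"), "n1", idMap), 1L)
  expect_warning(z <- geneOverlap("b1", "n1", character(0)), "empty")
  expect_equal(z, 0L)
})

test_that("random module sets replicate the partition structure exactly", {
  uni <- paste0("g", 1:10)
  sets <- randomModuleSets(uni, c(A = 3L, B = 2L), K = 1000L, seed = 20L)
  expect_length(sets, 1000L)
  for (s in sets[1:50]) {
    expect_equal(lengths(s), c(A = 3L, B = 2L))
    expect_length(intersect(s$A, s$B), 0)
    expect_true(all(c(s$A, s$B) %in% uni))
  }
  expect_identical(sets, randomModuleSets(uni, c(A = 3L, B = 2L),
                                          K = 1000L, seed = 20L))
  # inclusion frequency of each gene in the size-3 module: ~ 3/10
  freq <- sapply(uni, function(g)
    mean(vapply(sets, function(s) g %in% s$A, logical(1))))
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_true(all(abs(freq - 0.3) < 3 * se))
  expect_error(randomModuleSets(uni, c(8L, 8L)), "exceed")
})

test_that("the null carries nA x nB replicates per pair and is exchangeable", {
  prof <- corpusProfiles(handCorpus(), minDocs = 3L)
  uni <- c("g1", "g2", "g3")
  rA <- randomModuleSets(uni, c(M1 = 2L), K = 3L, seed = 1)
  rB <- randomModuleSets(uni, c(M1 = 1L, M2 = 2L), K = 3L, seed = 2)
  null <- buildNullAnnotation(prof, c("a1", "a2"), rA, rB, K = 2L)
  expect_equal(dim(null@scores), c(2L, 9L))
  obs <- matrix(c(1L, 2L), 1, 2, dimnames = list("M1", c("M1", "M2")))
  sig <- minpAdjust(obs, null)
  # shuffling replicate order leaves every p-value unchanged
  set.seed(11)
  null2 <- null
  null2@scores <- null2@scores[, sample(ncol(null2@scores)), drop = FALSE]
  sig2 <- minpAdjust(obs, null2)
  expect_equal(sig@rawP, sig2@rawP)
  expect_equal(sig@adjP, sig2@adjP)
})

test_that("minP adjustment matches brute-force enumeration", {
  set.seed(12)
  for (trial in 1:25) {
    n <- sample(1:3, 1); m <- sample(1:3, 1)
    KA <- sample(2:10, 1); KB <- sample(2:10, 1)
    inst <- randomNullInstance(n, m, KA, KB)
    got <- minpAdjust(inst$obs, inst$null)
    want <- bruteMinP(as.vector(inst$obs), inst$null@scores)
    expect_equal(as.vector(got@adjP), want, tolerance = 1e-12)
    expect_true(all(got@adjP >= got@rawP))
    expect_true(all(got@rawP > 0 & got@rawP <= 1))
    ord <- order(got@rawP)
    expect_false(is.unsorted(as.vector(got@adjP)[ord]))
  }
})

test_that("permutation p-values follow the conservative counting rule", {
  # a single pair: adjusted equals raw
  inst <- randomNullInstance(1, 1, 5, 5)
  got <- minpAdjust(inst$obs, inst$null)
  expect_equal(got@adjP[1, 1], got@rawP[1, 1])
  # observed beats every null score: raw p = 1 / (R + 1)
  null <- methods::new("PermutationNull",
    scores = matrix(sample(0:5, 2 * 100, TRUE), 2, 100),
    n = 1L, m = 2L, nA = 10L, nB = 10L, category = "x")
  obs <- matrix(c(10L, 11L), 1, 2, dimnames = list("A1", c("B1", "B2")))
  got <- minpAdjust(obs, null)
  expect_equal(as.vector(got@rawP), c(1 / 101, 1 / 101))
  # ties with the null count as extreme
  nullT <- methods::new("PermutationNull",
    scores = matrix(c(rep(3L, 10), rep(0L, 90)), 1, 100),
    n = 1L, m = 1L, nA = 10L, nB = 10L, category = "x")
  obsT <- matrix(3L, 1, 1, dimnames = list("A1", "B1"))
  expect_equal(minpAdjust(obsT, nullT)@rawP[1, 1], 11 / 101)
})

test_that("signature classification applies both criteria", {
  mkSig <- function(adjP) {
    methods::new("PairSignificance", category = "biological_process",
      observed = matrix(5L, 1, 1, dimnames = list("M1", "M1")),
      rawP = matrix(min(adjP, 0.01), 1, 1, dimnames = list("M1", "M1")),
      adjP = matrix(adjP, 1, 1, dimnames = list("M1", "M1")),
      strict = matrix(adjP <= 0.10, 1, 1),
      marginal = matrix(adjP > 0.10 & adjP <= 0.50, 1, 1),
      levels = c(0.10, 0.50))
  }
  mkTraits <- function(p) {
    methods::new("ModuleTraitResult",
      eigengenes = matrix(0, 1, 4, dimnames = list("M1", NULL)),
      r = matrix(0.5, 1, 1, dimnames = list("M1", "carrier")),
      p = matrix(p, 1, 1, dimnames = list("M1", "carrier")),
      associated = c(M1 = p < 0.05))
  }
  ann <- methods::new("ModuleAnnotationSet", K = 20L,
    table = data.frame(module = "M1", category = "biological_process",
                       rank = 1:2, concept = c("c1", "c2"),
                       score = c(2, 1), stringsAsFactors = FALSE))
  strict <- classifySignatures(mkSig(0.05), mkTraits(0.01), mkTraits(0.01),
                               ann, ann)
  expect_equal(nrow(strict), 1L)
  expect_equal(strict$flag, "strict")
  expect_equal(strict$sharedConcepts, "c1,c2")
  # one module not trait-associated: no signature
  none <- classifySignatures(mkSig(0.05), mkTraits(0.01), mkTraits(0.2),
                             ann, ann)
  expect_equal(nrow(none), 0L)
  # gray-zone significance with both modules associated: marginal
  marg <- classifySignatures(mkSig(0.30), mkTraits(0.01), mkTraits(0.01),
                             ann, ann)
  expect_equal(marg$flag, "marginal")
})

test_that("gene- and annotation-overlap nulls share the random module sets", {
  sc <- globalNullScenario(seed = 3)
  st <- simulateStudy(sc$config)
  uni <- names(st$tissues$blood$truth@assignment)
  rA1 <- randomModuleSets(uni, c(M1 = 5L, M2 = 4L), K = 10L, seed = 77L)
  rA2 <- randomModuleSets(uni, c(M1 = 5L, M2 = 4L), K = 10L, seed = 77L)
  expect_identical(rA1, rA2)
  gnull <- buildNullGene(rA1, rA2)
  expect_equal(dim(gnull@scores), c(4L, 100L))
  # identical replicate pairs score the full module size
  expect_equal(gnull@scores[1, 1], 5)
})
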