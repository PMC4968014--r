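test_that("co-occurrence counts are exact and order-invariant", {
  docs <- list(d1 = c("A", "B"), d2 = "A", d3 = c("B", "C"))
  vocab <- data.frame(concept = c("A", "B", "C"),
                      category = rep("gene", 3))
  cc <- cooccurrenceCounts(conceptCorpus(docs, vocab))
  expect_equal(cc@nDocs, 3L)
  expect_equal(cc@docFreq[["A"]], 2L)
  expect_equal(cc@docFreq[["B"]], 2L)
  expect_equal(as.numeric(cc@joint["A", "B"]), 1)
  expect_equal(as.numeric(cc@joint["A", "C"]), 0)
  # concept in every doc
  docs2 <- lapply(docs, function(d) c(d, "Z"))
  vocab2 <- rbind(vocab, data.frame(concept = "Z", category = "gene"))
  cc2 <- cooccurrenceCounts(conceptCorpus(docs2, vocab2))
  expect_equal(cc2@docFreq[["Z"]], 3L)
  # reordering documents changes nothing
  cc3 <- cooccurrenceCounts(conceptCorpus(rev(docs), vocab))
  expect_equal(cc3@docFreq[names(cc@docFreq)], cc@docFreq)
  expect_equal(as.matrix(cc3@joint)[names(cc@docFreq), names(cc@docFreq)],
               as.matrix(cc@joint))
  expect_error(cooccurrenceCounts(conceptCorpus(list(), vocab)), "empty")
})

test_that("symmetric uncertainty hits its closed-form anchors", {
  # identical occurrence: U = 1
  expect_equal(symmetricUncertainty(5, 5, 5, 10), 1)
  expect_equal(symmetricUncertainty(3, 3, 3, 100), 1)
  # exact independence: U = 0
  expect_equal(symmetricUncertainty(5, 4, 2, 10), 0)
  expect_equal(symmetricUncertainty(50, 10, 5, 100), 0)
  # degenerate margins: U = 0 by convention
  expect_equal(symmetricUncertainty(0, 4, 0, 10), 0)
  expect_equal(symmetricUncertainty(10, 10, 10, 10), 0)
})

test_that("symmetric uncertainty matches a brute-force entropy oracle", {
  # 2x2 table cells (4, 1, 0, 5) from N=10, nX=5, nY=4, nXY=4
  cells <- c(4, 1, 0, 5) / 10
  px <- cells[1] + cells[2]; py <- cells[1] + cells[3]
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  HX <- H(c(px, 1 - px)); HY <- H(c(py, 1 - py))
  HXY <- H(cells)
  I <- HX + HY - HXY
  expect_equal(symmetricUncertainty(5, 4, 4, 10), 2 * I / (HX + HY),
               tolerance = 1e-12)
})

test_that("symmetric uncertainty is symmetric and monotone above independence", {
  set.seed(8)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    nX <- sample(1:(N - 1), 1)
    nY <- sample(1:(N - 1), 1)
    lo <- max(0, nX + nY - N)
    nXY <- sample(lo:min(nX, nY), 1)
    expect_equal(symmetricUncertainty(nX, nY, nXY, N),
                 symmetricUncertainty(nY, nX, nXY, N))
  }
  # monotone in nXY for fixed margins above the independence point
  N <- 100; nX <- 40; nY <- 30
  indep <- nX * nY / N
  u <- sapply(ceiling(indep):min(nX, nY),
              function(j) symmetricUncertainty(nX, nY, j, N))
  expect_false(is.unsorted(u))
  expect_error(symmetricUncertainty(5, 4, 5, 10), "inconsistent")
  expect_error(symmetricUncertainty(8, 8, 2, 10), "inconsistent")
})

test_that("profile eligibility requires five documents; owner is excluded", {
  corpus <- handCorpus()
  counts <- cooccurrenceCounts(corpus)
  prof <- buildProfiles(counts, minDocs = 5L)
  # g1 occurs in 4 documents: no profile
  expect_equal(counts@docFreq[["g1"]], 4L)
  expect_false(hasProfile(prof, "g1"))
  expect_null(conceptProfile(prof, "g1"))
  # a1 occurs in 5 documents: profile exists, owner excluded, weights in (0,1]
  expect_true(hasProfile(prof, "a1"))
  w <- conceptProfile(prof, "a1")
  expect_false("a1" %in% names(w))
  expect_true(all(w > 0 & w <= 1))
  # a concept co-occurring with nothing: eligible but empty profile
  docs <- c(corpus@docs, list(e1 = "solo", e2 = "solo", e3 = "solo",
                              e4 = "solo", e5 = "solo"))
  vocab <- rbind(corpus@vocabulary,
                 data.frame(concept = "solo", category = "gene"))
  prof2 <- corpusProfiles(conceptCorpus(docs, vocab), minDocs = 5L)
  expect_true(hasProfile(prof2, "solo"))
  expect_length(conceptProfile(prof2, "solo"), 0)
})

test_that("profiles are invariant under corpus shuffling", {
  corpus <- handCorpus()
  p1 <- corpusProfiles(corpus, minDocs = 3L)
  set.seed(9)
  shuffled <- conceptCorpus(sample(corpus@docs), corpus@vocabulary)
  p2 <- corpusProfiles(shuffled, minDocs = 3L)
  expect_equal(as.matrix(p1@weights), as.matrix(p2@weights))
  expect_setequal(p1@eligible, p2@eligible)
})

test_that("profile matching is the inner product over shared concepts", {
  expect_equal(profileMatch(c(a = 0.5, b = 0.2), c(b = 0.4, c = 0.9)), 0.08)
  expect_equal(profileMatch(c(a = 0.5), c(b = 0.4)), 0)
  p <- c(a = 0.5, b = 0.2)
  expect_equal(profileMatch(p, p), sum(p^2))
  expect_gt(profileMatch(p, p), 0)
  # symmetry and Cauchy-Schwarz on real profiles
  prof <- corpusProfiles(handCorpus(), minDocs = 3L)
  for (x in c("a1", "a2")) for (y in c("x1", "g2")) {
    m <- profileMatch(x, y, profiles = prof)
    expect_equal(m, profileMatch(y, x, profiles = prof))
    expect_lte(m, sqrt(profileMatch(x, x, profiles = prof) *
                         profileMatch(y, y, profiles = prof)) + 1e-12)
  }
})

test_that("planted gene-annotation pairs get larger weights than background", {
  sc <- strongScenario(seed = 13)
  cfg <- sc$config
  cfg@corpusNDocs <- 5000L
  st <- simulateStudy(cfg)
  prof <- corpusProfiles(st$corpus)
  truth <- st$tissues$blood$truth
  genes <- names(truth@assignment)[truth@assignment == "A1"]
  planted <- st$functionConcepts[[truth@functionIds[["A1"]]]]$biological_process
  bg <- grep("^BP_BG", st$corpus@vocabulary$concept, value = TRUE)
  W <- prof@weights
  plantedW <- as.vector(as.matrix(W[genes, planted]))
  bgW <- as.vector(as.matrix(W[genes, bg]))
  expect_gt(mean(plantedW), mean(bgW))
  expect_gt(min(plantedW), median(bgW))
})
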