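#' Annotation overlap between two modules
#'
#' Number of annotation concepts shared by the two ranked lists (scores
#' ignored). When categories are supplied they must agree.
#'
#' @param a,b character vectors of annotation concept ids.
#' @param categoryA,categoryB optional categories; mismatch is an error.
#' @return integer overlap count.
#' @export
annotationOverlap <- function(a, b, categoryA = NULL, categoryB = NULL) {
  if (!is.null(categoryA) && !is.null(categoryB) &&
      !identical(categoryA, categoryB))
    stop("annotation overlap across different semantic categories")
  length(intersect(a, b))
}

#' Gene overlap between two modules
#'
#' Counts genes shared after mapping both modules into a common
#' identifier namespace. `idMap` maps tissue-specific gene ids to the
#' common namespace; unmapped genes are dropped. With `idMap = NULL`
#' identifiers are compared as-is.
#'
#' @param genesA,genesB character vectors of gene ids.
#' @param idMap named character vector (from -> to), or NULL.
#' @return integer overlap count.
#' @export
geneOverlap <- function(genesA, genesB, idMap = NULL) {
  if (!is.null(idMap)) {
    if (!length(idMap)) {
      warning("empty gene-id mapping; all overlaps are 0")
      return(0L)
    }
    genesA <- unname(idMap[genesA[genesA %in% names(idMap)]])
    genesB <- unname(idMap[genesB[genesB %in% names(idMap)]])
  }
  length(intersect(genesA, genesB))
}

#' Observed pair-score matrix for one semantic category
#'
#' @param annotA,annotB [ModuleAnnotationSet-class] objects for the two
#'   tissues (annotated with the same K and concept sets).
#' @param modulesA,modulesB the corresponding [ModuleSet-class] objects
#'   (fix the module ordering).
#' @param category semantic category to score.
#' @return integer matrix, blood modules x brain modules.
#' @export
pairScores <- function(annotA, annotB, modulesA, modulesB, category) {
  labA <- moduleLabels(modulesA); labB <- moduleLabels(modulesB)
  S <- matrix(0L, length(labA), length(labB),
              dimnames = list(labA, labB))
  for (i in seq_along(labA)) {
    ca <- annotationConcepts(annotA, labA[i], category)
    for (j in seq_along(labB)) {
      cb <- annotationConcepts(annotB, labB[j], category)
      S[i, j] <- annotationOverlap(ca, cb, category, category)
    }
  }
  S
}

#' Observed gene-overlap pair-score matrix
#'
#' @inheritParams pairScores
#' @param idMap see [geneOverlap()].
#' @return integer matrix, blood modules x brain modules.
#' @export
genePairScores <- function(modulesA, modulesB, idMap = NULL) {
  labA <- moduleLabels(modulesA); labB <- moduleLabels(modulesB)
  S <- matrix(0L, length(labA), length(labB),
              dimnames = list(labA, labB))
  for (i in seq_along(labA))
    for (j in seq_along(labB))
      S[i, j] <- geneOverlap(moduleGenes(modulesA, labA[i]),
                             moduleGenes(modulesB, labB[j]), idMap)
  S
}

#' Random module sets matching the original partition sizes
#'
#' Each replicate permutes the gene universe and slices consecutive
#' blocks of the original module sizes, so random modules are disjoint
#' and match the original sizes exactly. The universe is every gene that
#' entered module detection (assigned and unassigned).
#'
#' @param universe character vector of gene ids.
#' @param sizes integer vector of module sizes (sum <= |universe|).
#' @param K number of replicates (100).
#' @param seed integer RNG seed.
#' @return list of K replicates; each is a list of gene-id vectors named
#'   after `names(sizes)`.
#' @export
randomModuleSets <- function(universe, sizes, K = 100L, seed = 1L) {
  if (sum(sizes) > length(universe))
    stop("module sizes exceed the gene universe")
  set.seed(as.integer(seed))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(K), function(k) {
    perm <- sample(universe)
    out <- lapply(seq_along(sizes),
                  function(s) perm[starts[s]:ends[s]])
    names(out) <- names(sizes)
    out
  })
}

nullFromIndicators <- function(IA, IB, n, m, KA, KB, category) {
  # IA: (KA*n) x P indicator, rows ordered replicate-major (k, then i)
  S <- as.matrix(Matrix::tcrossprod(IA, IB))
  arr <- array(S, dim = c(n, KA, m, KB))
  arr <- aperm(arr, c(1L, 3L, 2L, 4L))
  scores <- matrix(arr, nrow = n * m, ncol = KA * KB)
  methods::new("PermutationNull", scores = scores, n = as.integer(n),
               m = as.integer(m), nA = as.integer(KA),
               nB = as.integer(KB), category = category)
}

#' Permutation null of annotation-overlap scores
#'
#' Annotates every random module exactly as the real modules (same K,
#' same scoring, same concept set) and computes the overlap score
#' `S_ijkl` for every module pair (i, j) and every replicate pair
#' (k, l): `nA * nB` null scores per pair (10,000 at the defaults).
#'
#' @param profiles a [ConceptProfiles-class].
#' @param conceptSet annotation concept ids of one semantic category.
#' @param randomA,randomB outputs of [randomModuleSets()] for the two
#'   tissues.
#' @param K annotation list cap (20).
#' @param category category label carried through to the result.
#' @return A [PermutationNull-class].
#' @export
buildNullAnnotation <- function(profiles, conceptSet, randomA, randomB,
                                K = 20L, category = "annotation") {
  n <- length(randomA[[1L]]); m <- length(randomB[[1L]])
  KA <- length(randomA); KB <- length(randomB)
  universe <- unique(c(unlist(randomA, use.names = FALSE),
                       unlist(randomB, use.names = FALSE)))
  SIM <- geneAnnotationSimilarity(profiles, universe,
                                  conceptSet[conceptSet %in%
                                             rownames(profiles@weights)])
  IA <- topKIndicator(SIM, unlist(randomA, recursive = FALSE), K)
  IB <- topKIndicator(SIM, unlist(randomB, recursive = FALSE), K)
  nullFromIndicators(IA, IB, n, m, KA, KB, category)
}

#' Permutation null of gene-overlap scores
#'
#' Same permutation machinery as [buildNullAnnotation()] (identical
#' random module sets given identical seeds), but scoring pairs by
#' mapped gene overlap.
#'
#' @param randomA,randomB outputs of [randomModuleSets()].
#' @param idMap see [geneOverlap()].
#' @return A [PermutationNull-class] with category `"gene"`.
#' @export
buildNullGene <- function(randomA, randomB, idMap = NULL) {
  n <- length(randomA[[1L]]); m <- length(randomB[[1L]])
  KA <- length(randomA); KB <- length(randomB)
  mapSets <- function(sets) {
    lapply(unlist(sets, recursive = FALSE), function(g) {
      if (is.null(idMap)) g else unname(idMap[g[g %in% names(idMap)]])
    })
  }
  gA <- mapSets(randomA); gB <- mapSets(randomB)
  common <- unique(c(unlist(gA), unlist(gB)))
  ind <- function(sets) {
    ii <- rep.int(seq_along(sets), lengths(sets))
    jj <- match(unlist(sets, use.names = FALSE), common)
    Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                         dims = c(length(sets), length(common)))
  }
  nullFromIndicators(ind(gA), ind(gB), n, m, KA, KB, "gene")
}

permPValue <- function(scores, null, R) {
  # (1 + #{null >= s}) / (1 + R), applied to observed and null scores alike
  vapply(scores, function(s) (1 + sum(null >= s)) / (1 + R), numeric(1))
}

#' Westfall-Young step-down minP adjustment
#'
#' Raw permutation p-values use the conservative counting rule
#' `p = (1 + #\{S_null >= S_obs\}) / (1 + R)` (ties count as extreme), so
#' reaching e.g. p < 1/R requires the observed score to be the most
#' extreme among all permutations. Per-replicate p-values are computed
#' from within-null ranks with the same rule; hypotheses are ordered by
#' raw p ascending and the adjusted p of the h-th is the fraction of
#' replicates whose minimum per-replicate p over hypotheses h..last is
#' at most its raw p (with the same +1 smoothing), made monotone by a
#' running maximum.
#'
#' @param observed n x m observed score matrix (dimnames = module
#'   labels).
#' @param null a [PermutationNull-class] built for the same pairs.
#' @param levels numeric c(strict, marginal) significance thresholds.
#' @return A [PairSignificance-class].
#' @export
minpAdjust <- function(observed, null, levels = c(0.10, 0.50)) {
  n <- null@n; m <- null@m
  if (!all(dim(observed) == c(n, m)))
    stop("observed score matrix does not match the null dimensions")
  R <- ncol(null@scores)
  if (R == 0L) stop("empty permutation null")
  S <- as.vector(observed)
  H <- length(S)
  rawP <- numeric(H)
  repP <- matrix(0, H, R)
  for (h in seq_len(H)) {
    v <- null@scores[h, ]
    rawP[h] <- (1 + sum(v >= S[h])) / (1 + R)
    cntGE <- length(v) - rank(v, ties.method = "min") + 1
    repP[h, ] <- (1 + cntGE) / (1 + R)
  }
  ord <- order(rawP, seq_len(H))
  adjOrd <- numeric(H)
  qmin <- rep(Inf, R)
  for (pos in rev(seq_len(H))) {
    h <- ord[pos]
    qmin <- pmin(qmin, repP[h, ])
    adjOrd[pos] <- (1 + sum(qmin <= rawP[h])) / (1 + R)
  }
  adjOrd <- cummax(adjOrd)
  adj <- numeric(H)
  adj[ord] <- adjOrd
  adj <- pmax(adj, rawP)
  dimn <- dimnames(observed)
  shape <- function(x) matrix(x, n, m, dimnames = dimn)
  methods::new("PairSignificance",
    category = null@category,
    observed = shape(S), rawP = shape(rawP), adjP = shape(adj),
    strict = shape(adj <= levels[1L]),
    marginal = shape(adj > levels[1L] & adj <= levels[2L]),
    levels = levels)
}

#' Classify common cross-tissue signatures
#'
#' A strict signature is a module pair with FWER-adjusted p at or below
#' the strict level whose two modules are each associated with at least
#' one trait (min trait p < `traitPThreshold`); a marginal signature
#' satisfies the same trait condition with adjusted p in the (strict,
#' marginal\] gray zone. Each signature reports the annotation concepts
#' the pair shares.
#'
#' @param sig a [PairSignificance-class] for one category.
#' @param traitsA,traitsB [ModuleTraitResult-class] objects for the two
#'   tissues (rows aligned with the module labels of `sig`).
#' @param annotA,annotB [ModuleAnnotationSet-class] objects.
#' @param traitPThreshold per-module trait association threshold (0.05).
#' @return data.frame with one row per signature (possibly empty).
#' @export
classifySignatures <- function(sig, traitsA, traitsB, annotA, annotB,
                               traitPThreshold = 0.05) {
  labA <- rownames(sig@observed); labB <- colnames(sig@observed)
  assocA <- apply(traitsA@p, 1L,
                  function(z) any(z < traitPThreshold, na.rm = TRUE))
  assocB <- apply(traitsB@p, 1L,
                  function(z) any(z < traitPThreshold, na.rm = TRUE))
  rows <- list()
  for (i in seq_along(labA)) for (j in seq_along(labB)) {
    flag <- if (sig@strict[i, j]) "strict"
            else if (sig@marginal[i, j]) "marginal" else NA_character_
    if (is.na(flag)) next
    if (!labA[i] %in% names(assocA) || !labB[j] %in% names(assocB))
      stop("missing trait results for a module in a significant pair")
    if (!(assocA[labA[i]] && assocB[labB[j]])) next
    shared <- intersect(
      annotationConcepts(annotA, labA[i], sig@category),
      annotationConcepts(annotB, labB[j], sig@category))
    rows[[length(rows) + 1L]] <- data.frame(
      blood = labA[i], brain = labB[j], category = sig@category,
      score = sig@observed[i, j], rawP = sig@rawP[i, j],
      adjP = sig@adjP[i, j], flag = flag,
      sharedConcepts = paste(shared, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(blood = character(0), brain = character(0),
               category = character(0), score = integer(0),
               rawP = numeric(0), adjP = numeric(0), flag = character(0),
               sharedConcepts = character(0), stringsAsFactors = FALSE)
}
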