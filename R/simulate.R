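#' Describe one planted module
#'
#' @param id module id (unique within a tissue).
#' @param nGenes number of genes in the module.
#' @param traitEffects named numeric vector of target eigengene-trait
#'   correlations in \[-1, 1\] for a subset of the traits (`carrier`,
#'   `CAG`, `motor`, `TFC`); unnamed traits are left unconstrained.
#' @param functionId optional label linking this module to a biological
#'   function; modules in different tissues with the same functionId
#'   form a planted shared-function pair. `NA` gives the module a
#'   private function of its own.
#' @return list spec consumed by [simulationConfig()].
#' @export
moduleSpec <- function(id, nGenes, traitEffects = numeric(0),
                       functionId = NA_character_) {
  list(id = as.character(id), nGenes = as.integer(nGenes),
       traitEffects = traitEffects, functionId = as.character(functionId))
}

#' Configure a two-tissue synthetic study
#'
#' Defines the study conditions under which the pipeline is exercised: a
#' latent-factor expression model (one unobserved factor per module,
#' unit loadings, Gaussian gene noise) whose factors are constructed to
#' hit the configured factor-trait correlations, plus a document corpus
#' in which the genes of each module co-occur with their function's
#' annotation concepts at `enrichment` times the background rate.
#' Shared-function module pairs across the two tissues involve disjoint
#' gene concepts linked to the same annotation concepts.
#'
#' @param moduleSpecs named list (one element per tissue, e.g. `blood`,
#'   `brain`) of lists of [moduleSpec()] entries.
#' @param nSamples samples per tissue.
#' @param nBackgroundGenes pure-noise genes added per tissue.
#' @param noiseSd standard deviation of the per-gene expression noise.
#' @param corpusNDocs number of documents in the synthetic corpus.
#' @param docsPerConcept minimum document frequency guaranteed for every
#'   concept (>= 5 so every planted concept earns a profile).
#' @param enrichment planted gene-annotation co-occurrence rate
#'   multiplier (>= 1; 1 = no planted signal).
#' @param baseRate background per-document concept occurrence
#'   probability.
#' @param conceptsPerFunction annotation concepts per function per
#'   semantic category.
#' @param nBackgroundConcepts background annotation concepts per
#'   semantic category.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(moduleSpecs, nSamples = 100L,
                             nBackgroundGenes = 30L, noiseSd = 0.5,
                             corpusNDocs = 5000L, docsPerConcept = 5L,
                             enrichment = 5, baseRate = 0.02,
                             conceptsPerFunction = 10L,
                             nBackgroundConcepts = 80L, seed = 1L) {
  methods::new("SimulationConfig",
    nSamples = as.integer(nSamples), moduleSpecs = moduleSpecs,
    nBackgroundGenes = as.integer(nBackgroundGenes),
    noiseSd = as.numeric(noiseSd),
    corpusNDocs = as.integer(corpusNDocs),
    docsPerConcept = as.integer(docsPerConcept),
    enrichment = as.numeric(enrichment),
    baseRate = as.numeric(baseRate),
    conceptsPerFunction = as.integer(conceptsPerFunction),
    nBackgroundConcepts = as.integer(nBackgroundConcepts),
    seed = as.integer(seed))
}

semanticCategories <- function() {
  c(biological_process = "BP", cellular_component = "CC",
    molecular_function = "MF", disease_or_syndrome = "DS")
}

## HD-flavoured trait table: binary carrier status, CAG repeat length,
## motor score increasing with CAG, TFC decreasing with motor severity.
generateTraitTable <- function(n) {
  carrier <- sample(rep(c(0, 1), length.out = n))
  cag <- ifelse(carrier == 1, round(stats::runif(n, 40, 53)),
                round(stats::runif(n, 17, 28)))
  motor <- ifelse(carrier == 1,
                  20 + 2.5 * (cag - 38) + stats::rnorm(n, 0, 10),
                  stats::runif(n, 0, 11))
  motor <- pmin(pmax(motor, 0), 107)
  tfc <- pmin(pmax(13 - 0.12 * motor + stats::rnorm(n, 0, 1), 0), 13)
  data.frame(carrier = carrier, CAG = cag, motor = motor, TFC = tfc)
}

## factor with exact empirical correlations `rho` to the named traits
plantedFactor <- function(Zs, rho, noiseSd) {
  if (any(abs(rho) > 1)) stop("trait correlation targets must lie in [-1, 1]")
  if (any(abs(rho) == 1) && noiseSd > 0)
    stop("a correlation target of magnitude 1 is incompatible with nonzero noise")
  n <- nrow(Zs)
  if (!length(rho)) {
    f <- stats::rnorm(n)
    return((f - mean(f)) / stats::sd(f))
  }
  Zsub <- Zs[, names(rho), drop = FALSE]
  R <- stats::cor(Zsub)
  w <- solve(R, rho)
  q <- as.numeric(rho %*% w)
  if (q > 1 + 1e-10)
    stop("trait correlation targets are jointly infeasible (rho' R^-1 rho > 1)")
  q <- min(q, 1)
  u <- as.vector(Zsub %*% w)
  eps <- stats::rnorm(n)
  r <- stats::residuals(stats::lm.fit(cbind(1, Zsub), eps))
  r <- r / stats::sd(r)
  u + sqrt(1 - q) * r
}

#' Generate synthetic expression data for one tissue
#'
#' Draws an unobserved factor per planted module, constructs the trait
#' table so the empirical factor-trait correlations equal the configured
#' targets, and emits each module gene as `factor + N(0, noiseSd)` (unit
#' loading); background genes are pure noise. Fully determined by the
#' configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @param tissue tissue name (must index `moduleSpecs`).
#' @return list with elements `data` ([TissueExpression-class]), `truth`
#'   ([GroundTruth-class]) and `factors` (modules x samples matrix of
#'   the planted factors).
#' @export
generateExpression <- function(config, tissue) {
  specs <- config@moduleSpecs[[tissue]]
  if (is.null(specs)) stop("no module specs for tissue: ", tissue)
  idx <- match(tissue, names(config@moduleSpecs))
  set.seed((config@seed + 101L * idx) %% .Machine$integer.max)
  n <- config@nSamples
  total <- sum(vapply(specs, function(s) s$nGenes, integer(1))) +
    config@nBackgroundGenes
  if (total == 0L) stop("zero genes configured")
  traits <- generateTraitTable(n)
  Zs <- scale(as.matrix(traits))
  prefix <- toupper(tissue)
  sampleIds <- sprintf("%s_S%03d", prefix, seq_len(n))
  rownames(traits) <- sampleIds

  X <- matrix(0, total, n)
  assignment <- character(0)
  geneIds <- character(0)
  factors <- matrix(0, length(specs), n,
                    dimnames = list(vapply(specs, `[[`, "", "id"), NULL))
  functionIds <- character(0)
  traitEffects <- list()
  row <- 0L; g <- 0L
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    f <- plantedFactor(Zs, sp$traitEffects, config@noiseSd)
    factors[s, ] <- f
    ids <- sprintf("%s_G%04d", prefix, g + seq_len(sp$nGenes))
    g <- g + sp$nGenes
    X[row + seq_len(sp$nGenes), ] <-
      matrix(rep(f, each = sp$nGenes), sp$nGenes, n) +
      stats::rnorm(sp$nGenes * n, 0, config@noiseSd)
    row <- row + sp$nGenes
    geneIds <- c(geneIds, ids)
    assignment <- c(assignment, stats::setNames(rep(sp$id, sp$nGenes), ids))
    fid <- if (is.na(sp$functionId))
      paste0("PRIV_", prefix, "_", sp$id) else sp$functionId
    functionIds[sp$id] <- fid
    traitEffects[[sp$id]] <- sp$traitEffects
  }
  if (config@nBackgroundGenes > 0L) {
    ids <- sprintf("%s_G%04d", prefix, g + seq_len(config@nBackgroundGenes))
    X[row + seq_len(config@nBackgroundGenes), ] <-
      stats::rnorm(config@nBackgroundGenes * n)
    geneIds <- c(geneIds, ids)
    assignment <- c(assignment,
                    stats::setNames(rep("background", length(ids)), ids))
  }
  dimnames(X) <- list(geneIds, sampleIds)
  colnames(factors) <- sampleIds
  truth <- methods::new("GroundTruth", tissue = tissue,
                        assignment = assignment,
                        functionIds = functionIds,
                        traitEffects = traitEffects)
  list(data = tissueExpression(X, traits), truth = truth,
       factors = factors)
}

#' Generate the synthetic document corpus
#'
#' Documents are bags of concept ids drawn independently at the
#' background rate; for every planted function a small set of "theme"
#' documents additionally mentions the function's member genes and its
#' annotation concepts, lifting each planted gene-annotation pair's
#' co-occurrence rate to `enrichment` times the background rate. Every
#' concept is guaranteed to occur in at least `docsPerConcept`
#' documents. Module pairs sharing a functionId across tissues involve
#' different gene concepts but the same annotation concepts.
#'
#' @param config a [SimulationConfig-class].
#' @param truths named list of [GroundTruth-class] objects, one per
#'   tissue.
#' @return list with elements `corpus` ([ConceptCorpus-class]),
#'   `conceptSets` (named list category -> annotation concept ids),
#'   `functionConcepts` (functionId -> category -> concepts) and
#'   `sharedPairs` (data.frame of planted cross-tissue pairs).
#' @export
generateCorpus <- function(config, truths) {
  if (config@enrichment < 1) stop("enrichment must be >= 1")
  set.seed((config@seed + 9973L) %% .Machine$integer.max)
  cats <- semanticCategories()
  geneConcepts <- unlist(lapply(truths, function(tr) names(tr@assignment)),
                         use.names = FALSE)

  fids <- unique(unlist(lapply(truths, function(tr) tr@functionIds),
                        use.names = FALSE))
  functionConcepts <- lapply(fids, function(fid) {
    out <- lapply(names(cats), function(cat)
      sprintf("%s_%s_C%02d", cats[[cat]], fid,
              seq_len(config@conceptsPerFunction)))
    names(out) <- names(cats)
    out
  })
  names(functionConcepts) <- fids
  bgConcepts <- lapply(names(cats), function(cat)
    sprintf("%s_BG_C%03d", cats[[cat]], seq_len(config@nBackgroundConcepts)))
  names(bgConcepts) <- names(cats)

  vocabConcept <- c(geneConcepts,
                    unlist(functionConcepts, use.names = FALSE),
                    unlist(bgConcepts, use.names = FALSE))
  vocabCat <- c(rep("gene", length(geneConcepts)),
                rep(rep(names(cats), each = config@conceptsPerFunction),
                    times = length(fids)),
                rep(names(cats), each = config@nBackgroundConcepts))
  vocabulary <- data.frame(concept = vocabConcept, category = vocabCat,
                           stringsAsFactors = FALSE)
  V <- length(vocabConcept)
  N <- config@corpusNDocs
  p0 <- config@baseRate

  M <- matrix(stats::runif(N * V) < p0, N, V)
  colnames(M) <- vocabConcept

  if (config@enrichment > 1) {
    gamma <- 0.3
    nTheme <- ceiling((config@enrichment - 1) * p0^2 * N / gamma^2)
    nTheme <- min(nTheme, N)
    for (fid in fids) {
      members <- unlist(lapply(truths, function(tr) {
        mods <- names(tr@functionIds)[tr@functionIds == fid]
        names(tr@assignment)[tr@assignment %in% mods]
      }), use.names = FALSE)
      themeCols <- c(members,
                     unlist(functionConcepts[[fid]], use.names = FALSE))
      docs <- sample.int(N, nTheme)
      hit <- matrix(stats::runif(nTheme * length(themeCols)) < gamma,
                    nTheme, length(themeCols))
      M[docs, themeCols] <- M[docs, themeCols] | hit
    }
  }

  freq <- colSums(M)
  for (cidx in which(freq < config@docsPerConcept)) {
    absent <- which(!M[, cidx])
    add <- sample(absent, config@docsPerConcept - freq[cidx])
    M[add, cidx] <- TRUE
  }

  docIds <- sprintf("D%05d", seq_len(N))
  docs <- apply(M, 1L, function(r) vocabConcept[r], simplify = FALSE)
  names(docs) <- docIds
  corpus <- conceptCorpus(docs, vocabulary)

  conceptSets <- lapply(names(cats), function(cat) {
    vocabulary$concept[vocabulary$category == cat]
  })
  names(conceptSets) <- names(cats)

  sharedPairs <- sharedFunctionPairs(truths)
  list(corpus = corpus, conceptSets = conceptSets,
       functionConcepts = functionConcepts, sharedPairs = sharedPairs)
}

#' Planted shared-function module pairs across two tissues
#'
#' @param truths named list of exactly two [GroundTruth-class] objects.
#' @return data.frame with columns `functionId`, and one module-label
#'   column per tissue, one row per planted cross-tissue pair.
#' @export
sharedFunctionPairs <- function(truths) {
  stopifnot(length(truths) == 2L)
  tA <- truths[[1L]]; tB <- truths[[2L]]
  shared <- intersect(tA@functionIds, tB@functionIds)
  rows <- list()
  for (fid in shared) {
    for (ma in names(tA@functionIds)[tA@functionIds == fid])
      for (mb in names(tB@functionIds)[tB@functionIds == fid])
        rows[[length(rows) + 1L]] <-
          data.frame(functionId = fid, a = ma, b = mb,
                     stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(functionId = character(0), a = character(0),
               b = character(0), stringsAsFactors = FALSE)
  names(out)[2:3] <- names(truths)
  out
}

#' Generate a complete synthetic study
#'
#' Expression plus traits for every configured tissue and a single
#' shared document corpus with its concept sets.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `tissues` (per-tissue list of `data`, `truth`,
#'   `factors`), `corpus`, `conceptSets`, `functionConcepts`,
#'   `sharedPairs`.
#' @export
simulateStudy <- function(config) {
  tissues <- lapply(names(config@moduleSpecs),
                    function(t) generateExpression(config, t))
  names(tissues) <- names(config@moduleSpecs)
  truths <- lapply(tissues, `[[`, "truth")
  corp <- generateCorpus(config, truths)
  c(list(tissues = tissues), corp)
}
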