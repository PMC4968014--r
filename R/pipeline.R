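#' Pipeline configuration
#'
#' Bundles the analysis parameters shared across stages. Defaults
#' reproduce the reference HD blood-brain study design: top-20 annotations per concept
#' set, concept-profile eligibility at 5 documents, 100 x 100 random
#' module sets (10,000 permutation scores per pair), strict significance
#' level 10 %, marginal gray zone up to 50 %, per-cell module-trait
#' threshold 0.05.
#'
#' @param K annotation list cap per semantic category.
#' @param minDocs concept-profile eligibility threshold.
#' @param nPermA,nPermB random module sets for the two tissues.
#' @param strictLevel,marginalLevel FWER significance thresholds.
#' @param traitPThreshold per-module trait association threshold.
#' @param seed integer seed driving the permutation machinery.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(K = 20L, minDocs = 5L, nPermA = 100L,
                           nPermB = 100L, strictLevel = 0.10,
                           marginalLevel = 0.50, traitPThreshold = 0.05,
                           seed = 1L) {
  methods::new("PipelineConfig", K = as.integer(K),
               minDocs = as.integer(minDocs), nPermA = as.integer(nPermA),
               nPermB = as.integer(nPermB), strictLevel = strictLevel,
               marginalLevel = marginalLevel,
               traitPThreshold = traitPThreshold, seed = as.integer(seed))
}

#' Run the full cross-tissue signature pipeline
#'
#' Module detection and module-trait association per tissue, concept
#' profiles from the corpus, per-category module annotation, observed
#' pair scores, the random-module permutation null (random sets shared
#' across categories and with the gene-overlap baseline), Westfall-Young
#' minP adjustment, and signature classification. Fully reproducible
#' from the inputs plus `config@seed`.
#'
#' @param tissueData named list of exactly two [TissueExpression-class]
#'   objects (first = blood side, second = brain side).
#' @param netParams a [NetworkParams-class], or a named list of one per
#'   tissue.
#' @param corpus a [ConceptCorpus-class].
#' @param conceptSets named list category -> annotation concept ids.
#' @param config a [PipelineConfig-class].
#' @param idMap optional named character gene-id mapping into a common
#'   namespace for the gene-overlap baseline; `NULL` compares ids
#'   as-is.
#' @return A [SignatureReport-class].
#' @export
runPipeline <- function(tissueData, netParams, corpus, conceptSets,
                        config = pipelineConfig(), idMap = NULL) {
  stopifnot(length(tissueData) == 2L)
  tn <- names(tissueData)
  if (is.null(tn)) stop("tissueData must be a named list")
  if (methods::is(netParams, "NetworkParams"))
    netParams <- stats::setNames(list(netParams, netParams), tn)

  modules <- list(); traitRes <- list()
  for (t in tn) {
    ms <- detectModules(tissueData[[t]], netParams[[t]])
    modules[[t]] <- ms
    traitRes[[t]] <- moduleTraitCorrelation(tissueData[[t]], ms,
                                            config@traitPThreshold)
  }

  profiles <- corpusProfiles(corpus, config@minDocs)
  annotations <- lapply(tn, function(t)
    annotateModules(profiles, modules[[t]], conceptSets, K = config@K))
  names(annotations) <- tn

  msA <- modules[[1L]]; msB <- modules[[2L]]
  labA <- moduleLabels(msA); labB <- moduleLabels(msB)
  significance <- list()
  geneSig <- NULL
  signatures <- data.frame()
  if (length(labA) && length(labB)) {
    sizesA <- vapply(labA, function(l) length(moduleGenes(msA, l)),
                     integer(1))
    sizesB <- vapply(labB, function(l) length(moduleGenes(msB, l)),
                     integer(1))
    randomA <- randomModuleSets(geneUniverse(msA), sizesA,
                                K = config@nPermA, seed = config@seed + 1L)
    randomB <- randomModuleSets(geneUniverse(msB), sizesB,
                                K = config@nPermB, seed = config@seed + 2L)
    lev <- c(config@strictLevel, config@marginalLevel)
    for (cat in names(conceptSets)) {
      S <- pairScores(annotations[[1L]], annotations[[2L]], msA, msB, cat)
      null <- buildNullAnnotation(profiles, conceptSets[[cat]],
                                  randomA, randomB, K = config@K,
                                  category = cat)
      sig <- minpAdjust(S, null, levels = lev)
      significance[[cat]] <- sig
      signatures <- rbind(signatures,
        classifySignatures(sig, traitRes[[1L]], traitRes[[2L]],
                           annotations[[1L]], annotations[[2L]],
                           config@traitPThreshold))
    }
    Sg <- genePairScores(msA, msB, idMap)
    geneSig <- minpAdjust(Sg, buildNullGene(randomA, randomB, idMap),
                          levels = lev)
  }

  manifest <- list(
    package = "CoExSig",
    version = as.character(utils::packageVersion("CoExSig")),
    seed = config@seed, K = config@K, minDocs = config@minDocs,
    nPermA = config@nPermA, nPermB = config@nPermB,
    strictLevel = config@strictLevel,
    marginalLevel = config@marginalLevel,
    traitPThreshold = config@traitPThreshold,
    tissues = tn,
    netParams = lapply(netParams, function(p)
      list(softPower = p@softPower, minModuleSize = p@minModuleSize,
           deepSplit = p@deepSplit, cutHeight = p@cutHeight,
           MEDissThres = p@MEDissThres, signed = p@signed)))

  methods::new("SignatureReport", modules = modules,
               traitResults = traitRes, annotations = annotations,
               significance = significance, geneSignificance = geneSig,
               signatures = signatures,
               summary = summarizeSimilarity(significance),
               manifest = manifest)
}

#' Per-category counts of significant module pairs
#'
#' @param significance named list of [PairSignificance-class] objects
#'   (or a [SignatureReport-class]).
#' @return data.frame with columns `category`, `strictPairs`,
#'   `marginalPairs`.
#' @export
summarizeSimilarity <- function(significance) {
  if (methods::is(significance, "SignatureReport"))
    significance <- significance@significance
  if (!length(significance))
    return(data.frame(category = character(0), strictPairs = integer(0),
                      marginalPairs = integer(0)))
  data.frame(
    category = names(significance),
    strictPairs = vapply(significance, function(s) sum(s@strict),
                         integer(1)),
    marginalPairs = vapply(significance, function(s) sum(s@marginal),
                           integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
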