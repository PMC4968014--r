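#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom Matrix Matrix sparseMatrix crossprod tcrossprod rowSums colSums t
#' @importFrom stats cor cutree hclust as.dist pt rnorm runif rbinom sd var
#'   lm lm.fit coef residuals
#' @importFrom utils head read.delim write.table packageVersion
NULL

#' Expression data for one tissue
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] holding one
#' genes-by-samples expression matrix in the `"expr"` assay and the
#' per-sample trait table (carrier status, CAG repeat, motor score, TFC
#' score, ...) as `colData`. Constructed with [tissueExpression()], which
#' validates sample alignment and drops zero-variance genes.
#'
#' @aliases TissueExpression-class
#' @exportClass TissueExpression
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
  v <- SummarizedExperiment::assay(object, "expr")
  if (anyNA(v)) return("expression matrix contains missing values")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("expression matrix must have gene and sample names")
  TRUE
})

#' Disjoint gene modules for one tissue
#'
#' Stores the gene-to-module assignment produced by [clusterAndCut()] /
#' [mergeModules()]. Every input gene is covered; genes not placed in any
#' module carry the unassigned label.
#'
#' @slot assignment named character vector, gene id -> module label.
#' @slot unassignedLabel label used for the unassigned pool.
#' @aliases ModuleSet-class
#' @exportClass ModuleSet
setClass("ModuleSet",
  slots = c(assignment = "character", unassignedLabel = "character"))

setValidity("ModuleSet", function(object) {
  if (length(object@unassignedLabel) != 1L) return("one unassigned label required")
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    return("assignment must be named by unique gene ids")
  TRUE
})

#' Network construction and tree-cut parameters
#'
#' @slot softPower soft-threshold exponent beta (> 0) for the adjacency.
#' @slot minModuleSize minimum number of genes per module.
#' @slot deepSplit integer >= 0; split sensitivity of the branch cut.
#' @slot cutHeight dendrogram cut height in (0, 1].
#' @slot MEDissThres eigengene-dissimilarity threshold in \[0, 1\] below
#'   which modules are merged.
#' @slot signed use the signed adjacency transform instead of |cor|^beta.
#' @aliases NetworkParams-class
#' @exportClass NetworkParams
setClass("NetworkParams",
  slots = c(softPower = "numeric", minModuleSize = "integer",
            deepSplit = "integer", cutHeight = "numeric",
            MEDissThres = "numeric", signed = "logical"))

setValidity("NetworkParams", function(object) {
  if (object@softPower <= 0) return("softPower must be > 0")
  if (object@minModuleSize < 1L) return("minModuleSize must be >= 1")
  if (object@deepSplit < 0L) return("deepSplit must be >= 0")
  if (object@cutHeight <= 0 || object@cutHeight > 1)
    return("cutHeight must be in (0, 1]")
  if (object@MEDissThres < 0 || object@MEDissThres > 1)
    return("MEDissThres must be in [0, 1]")
  TRUE
})

#' Module eigengenes and module-trait association
#'
#' @slot eigengenes modules x samples matrix of unit-norm eigengenes.
#' @slot r modules x traits Pearson correlation matrix (NA for a
#'   constant trait).
#' @slot p modules x traits two-sided p-values from the t statistic on
#'   n - 2 degrees of freedom.
#' @slot associated logical per module: min trait p < threshold.
#' @aliases ModuleTraitResult-class
#' @exportClass ModuleTraitResult
setClass("ModuleTraitResult",
  slots = c(eigengenes = "matrix", r = "matrix", p = "matrix",
            associated = "logical"))

#' Document corpus of concept occurrences
#'
#' Documents are deduplicated bags of concept identifiers; the vocabulary
#' assigns each concept a semantic category (`gene`, `biological_process`,
#' `cellular_component`, `molecular_function`, `disease_or_syndrome`).
#'
#' @slot docs named list (by document id) of character vectors.
#' @slot vocabulary data.frame with columns `concept`, `category`.
#' @aliases ConceptCorpus-class
#' @exportClass ConceptCorpus
setClass("ConceptCorpus",
  slots = c(docs = "list", vocabulary = "data.frame"))

setValidity("ConceptCorpus", function(object) {
  if (!all(c("concept", "category") %in% names(object@vocabulary)))
    return("vocabulary needs columns 'concept' and 'category'")
  if (anyDuplicated(object@vocabulary$concept))
    return("duplicate concepts in vocabulary")
  used <- unique(unlist(object@docs, use.names = FALSE))
  if (!all(used %in% object@vocabulary$concept))
    return("documents mention concepts missing from the vocabulary")
  TRUE
})

#' Exact document co-occurrence counts
#'
#' @slot nDocs total number of documents N.
#' @slot docFreq named integer vector of per-concept document frequencies.
#' @slot joint sparse symmetric concept x concept joint document counts
#'   (diagonal = document frequency).
#' @aliases CooccurrenceCounts-class
#' @exportClass CooccurrenceCounts
setClass("CooccurrenceCounts",
  slots = c(nDocs = "integer", docFreq = "integer", joint = "Matrix"))

#' Concept profiles built from a corpus
#'
#' Row `x` of `weights` is the concept profile of owner concept `x`: the
#' symmetric-uncertainty weight of every concept that co-occurs with `x`
#' in at least one document (owner excluded, zero weights dropped). Only
#' concepts occurring in at least `minDocs` documents are eligible for a
#' profile; ineligible concepts have no profile (not an empty one).
#'
#' @slot weights sparse concepts x concepts weight matrix.
#' @slot eligible character vector of owner concepts with a profile.
#' @slot minDocs the document-frequency eligibility threshold.
#' @slot categories named character vector concept -> semantic category.
#' @aliases ConceptProfiles-class
#' @exportClass ConceptProfiles
setClass("ConceptProfiles",
  slots = c(weights = "Matrix", eligible = "character",
            minDocs = "integer", categories = "character"))

#' Ranked per-module annotations
#'
#' @slot table data.frame with columns `module`, `category`, `rank`,
#'   `concept`, `score`; per (module, category) sorted by score
#'   descending, ties broken by concept id ascending, at most K rows.
#' @slot K the annotation list cap (20 by default).
#' @aliases ModuleAnnotationSet-class
#' @exportClass ModuleAnnotationSet
setClass("ModuleAnnotationSet",
  slots = c(table = "data.frame", K = "integer"))

#' Permutation null scores for all module pairs
#'
#' @slot scores (n*m) x R matrix of null overlap scores; pair (i, j) is
#'   row i + (j-1)*n, replicate (k, l) is column (k-1)*nB + l.
#' @slot n,m numbers of modules in the two tissues.
#' @slot nA,nB numbers of random module sets per tissue (R = nA*nB).
#' @slot category semantic category the scores belong to.
#' @aliases PermutationNull-class
#' @exportClass PermutationNull
setClass("PermutationNull",
  slots = c(scores = "matrix", n = "integer", m = "integer",
            nA = "integer", nB = "integer", category = "character"))

setValidity("PermutationNull", function(object) {
  if (nrow(object@scores) != object@n * object@m)
    return("null score rows must equal n*m pairs")
  if (ncol(object@scores) != object@nA * object@nB)
    return("null score columns must equal nA*nB replicates")
  TRUE
})

#' Observed scores with permutation and minP-adjusted significance
#'
#' @slot category semantic category.
#' @slot observed n x m observed overlap scores.
#' @slot rawP raw permutation p-values, `(1 + #{null >= obs}) / (1 + R)`.
#' @slot adjP step-down Westfall-Young minP adjusted p-values (FWER).
#' @slot strict,marginal logical n x m flags at the strict (0.10) and
#'   marginal (0.50) significance levels.
#' @slot levels numeric c(strict, marginal) thresholds used.
#' @aliases PairSignificance-class
#' @exportClass PairSignificance
setClass("PairSignificance",
  slots = c(category = "character", observed = "matrix", rawP = "matrix",
            adjP = "matrix", strict = "matrix", marginal = "matrix",
            levels = "numeric"))

setValidity("PairSignificance", function(object) {
  if (any(object@adjP < object@rawP - 1e-12))
    return("adjusted p must be >= raw p")
  if (any(object@rawP <= 0) || any(object@rawP > 1))
    return("raw p must lie in (0, 1]")
  TRUE
})

#' Synthetic study configuration
#'
#' Defines the planted structure of a two-tissue synthetic study: module
#' sizes, target eigengene-trait correlations, the shared-function links
#' between tissues, background genes, expression noise, and the document
#' corpus (size, per-concept document floor, planted co-occurrence
#' enrichment). See [simulationConfig()].
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(nSamples = "integer", moduleSpecs = "list",
            nBackgroundGenes = "integer", noiseSd = "numeric",
            corpusNDocs = "integer", docsPerConcept = "integer",
            enrichment = "numeric", baseRate = "numeric",
            conceptsPerFunction = "integer",
            nBackgroundConcepts = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nSamples < 1L) return("nSamples must be positive")
  if (object@nBackgroundGenes < 0L) return("nBackgroundGenes must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@corpusNDocs < 1L) return("corpusNDocs must be positive")
  if (object@docsPerConcept < 5L)
    return("docsPerConcept must be >= 5 so every planted concept earns a profile")
  if (object@enrichment < 1) return("cooccurrence enrichment must be >= 1")
  if (object@baseRate <= 0 || object@baseRate >= 1)
    return("baseRate must be in (0, 1)")
  for (tissue in names(object@moduleSpecs)) {
    for (sp in object@moduleSpecs[[tissue]]) {
      if (sp$nGenes < 1L) return("module sizes must be positive")
      if (length(sp$traitEffects) && any(abs(sp$traitEffects) > 1))
        return("trait correlation targets must lie in [-1, 1]")
    }
  }
  TRUE
})

#' Planted ground truth for one tissue
#'
#' @slot tissue tissue label.
#' @slot assignment named character gene -> planted module (background
#'   genes carry the label "background").
#' @slot functionIds named character module -> function id.
#' @slot traitEffects named list module -> target trait correlations.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(tissue = "character", assignment = "character",
            functionIds = "character", traitEffects = "list"))

#' End-to-end pipeline configuration
#'
#' @aliases PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(K = "integer", minDocs = "integer",
            nPermA = "integer", nPermB = "integer",
            strictLevel = "numeric", marginalLevel = "numeric",
            traitPThreshold = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  thr <- c(object@strictLevel, object@marginalLevel, object@traitPThreshold)
  if (any(thr <= 0) || any(thr > 1)) return("thresholds must be in (0, 1]")
  if (object@strictLevel > object@marginalLevel)
    return("strict level cannot exceed marginal level")
  if (object@nPermA < 1L || object@nPermB < 1L)
    return("permutation replicate counts must be positive")
  TRUE
})

#' Full pipeline report
#'
#' @slot modules,traitResults,annotations per-tissue results.
#' @slot significance named list of [PairSignificance-class] per category.
#' @slot geneSignificance [PairSignificance-class] for the gene-overlap
#'   baseline.
#' @slot signatures data.frame of classified common signatures.
#' @slot summary per-category counts of significant pairs.
#' @slot manifest list of parameters, seed and package version.
#' @aliases SignatureReport-class
#' @exportClass SignatureReport
setClass("SignatureReport",
  slots = c(modules = "list", traitResults = "list", annotations = "list",
            significance = "list", geneSignificance = "ANY",
            signatures = "data.frame", summary = "data.frame",
            manifest = "list"))
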