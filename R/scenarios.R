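#' Standard synthetic scenarios
#'
#' `strongScenario()` is the package's reference validation scenario:
#' three planted modules per tissue (20/15/15 genes) with trait effects
#' 0.6 (carrier), 0.5 (CAG) and 0.4 (motor), two shared functions
#' linking the first two module pairs across tissues, 30 background
#' genes, expression noise sd 0.5, and a 3000-document corpus with
#' planted co-occurrence enrichment 5. `globalNullScenario()` is the
#' matching no-signal condition: two private-function modules per
#' tissue, enrichment 1 (no planted gene-annotation association) and a
#' reduced 800-document corpus, used to check familywise error control.
#'
#' Both return the network parameters (soft power 6, minModuleSize 15,
#' deepSplit 2, cutHeight 0.97, eigengene merge threshold 0.15) and a
#' pipeline configuration with `nPerm` random module sets per tissue.
#'
#' @param seed integer seed.
#' @param nSamples samples per tissue.
#' @param nPerm random module sets per tissue for the permutation null.
#' @return list with `config` ([SimulationConfig-class]), `netParams`
#'   ([NetworkParams-class]) and `pipeConfig`
#'   ([PipelineConfig-class]).
#' @export
strongScenario <- function(seed = 1L, nSamples = 60L, nPerm = 20L) {
  specs <- list(
    blood = list(
      moduleSpec("A1", 20L, c(carrier = 0.6), "F1"),
      moduleSpec("A2", 15L, c(CAG = 0.5), "F2"),
      moduleSpec("A3", 15L, c(motor = 0.4))),
    brain = list(
      moduleSpec("B1", 20L, c(carrier = 0.6), "F1"),
      moduleSpec("B2", 15L, c(CAG = 0.5), "F2"),
      moduleSpec("B3", 15L, c(motor = 0.4))))
  config <- simulationConfig(
    moduleSpecs = specs, nSamples = nSamples, nBackgroundGenes = 30L,
    noiseSd = 0.5, corpusNDocs = 3000L, docsPerConcept = 5L,
    enrichment = 5, baseRate = 0.02, conceptsPerFunction = 10L,
    nBackgroundConcepts = 80L, seed = seed)
  list(config = config,
       netParams = networkParams(softPower = 6, minModuleSize = 15L,
                                 deepSplit = 2L, cutHeight = 0.97,
                                 MEDissThres = 0.15),
       pipeConfig = pipelineConfig(nPermA = nPerm, nPermB = nPerm,
                                   seed = seed))
}

#' @rdname strongScenario
#' @export
globalNullScenario <- function(seed = 1L, nSamples = 40L, nPerm = 20L) {
  specs <- list(
    blood = list(
      moduleSpec("A1", 15L, c(carrier = 0.5)),
      moduleSpec("A2", 15L, c(CAG = 0.5))),
    brain = list(
      moduleSpec("B1", 15L, c(carrier = 0.5)),
      moduleSpec("B2", 15L, c(CAG = 0.5))))
  config <- simulationConfig(
    moduleSpecs = specs, nSamples = nSamples, nBackgroundGenes = 15L,
    noiseSd = 0.5, corpusNDocs = 800L, docsPerConcept = 5L,
    enrichment = 1, baseRate = 0.03, conceptsPerFunction = 5L,
    nBackgroundConcepts = 25L, seed = seed)
  list(config = config,
       netParams = networkParams(softPower = 6, minModuleSize = 15L,
                                 deepSplit = 2L, cutHeight = 0.97,
                                 MEDissThres = 0.15),
       pipeConfig = pipelineConfig(nPermA = nPerm, nPermB = nPerm,
                                   seed = seed))
}
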