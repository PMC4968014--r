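#' Gene-annotation profile similarity matrix
#'
#' Inner products between the profiles of a set of gene concepts and a
#' set of annotation concepts. Genes (or annotations) without a profile
#' contribute zero rows/columns.
#'
#' @param profiles a [ConceptProfiles-class].
#' @param genes character vector of gene concept ids.
#' @param concepts character vector of annotation concept ids.
#' @return dense genes x concepts similarity matrix.
#' @export
geneAnnotationSimilarity <- function(profiles, genes, concepts) {
  W <- profiles@weights
  bad <- setdiff(c(genes, concepts), rownames(W))
  if (length(bad)) stop("unknown concepts: ", paste(head(bad), collapse = ", "))
  S <- as.matrix(W[genes, , drop = FALSE] %*%
                 Matrix::t(W[concepts, , drop = FALSE]))
  dimnames(S) <- list(genes, concepts)
  S
}

#' Summed similarity of a module to one annotation concept
#'
#' Sum over the module's genes (those that own a profile) of the
#' inner-product match between the gene profile and the annotation
#' profile. Genes without a profile contribute zero; if no module gene
#' has a profile the score is zero with a warning.
#'
#' @param profiles a [ConceptProfiles-class].
#' @param genes module gene concept ids.
#' @param concept annotation concept id (must own a profile).
#' @return non-negative numeric score.
#' @export
scoreAnnotation <- function(profiles, genes, concept) {
  if (!hasProfile(profiles, concept))
    stop("annotation concept has no profile: ", concept)
  covered <- genes[genes %in% profiles@eligible]
  if (!length(covered)) {
    warning("no module gene owns a profile; score is 0")
    return(0)
  }
  sum(geneAnnotationSimilarity(profiles, covered, concept))
}

#' Annotate one module against a concept set
#'
#' Scores every annotation concept of the set by its summed similarity
#' to the module genes, then keeps the top `K` in decreasing score
#' order, breaking ties by concept id ascending. Zero-score annotations
#' are dropped unless `keepZeroScores` is set.
#'
#' @param profiles a [ConceptProfiles-class].
#' @param genes module gene concept ids (non-empty).
#' @param conceptSet character vector of annotation concept ids.
#' @param K annotation list cap (20).
#' @param keepZeroScores keep zero-score annotations to fill up K.
#' @return data.frame with columns `rank`, `concept`, `score`.
#' @export
annotateModule <- function(profiles, genes, conceptSet, K = 20L,
                           keepZeroScores = FALSE) {
  if (!length(genes)) stop("empty module")
  if (!length(conceptSet)) stop("empty concept set")
  usable <- conceptSet[conceptSet %in% profiles@eligible]
  covered <- genes[genes %in% profiles@eligible]
  score <- stats::setNames(rep(0, length(conceptSet)), conceptSet)
  if (length(usable) && length(covered)) {
    S <- geneAnnotationSimilarity(profiles, covered, usable)
    score[usable] <- colSums(S)
  }
  ord <- order(-score, names(score))
  score <- score[ord]
  if (!keepZeroScores) score <- score[score > 0]
  score <- head(score, K)
  data.frame(rank = seq_along(score), concept = names(score),
             score = as.numeric(score), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Annotate all modules in all semantic categories
#'
#' @param profiles a [ConceptProfiles-class].
#' @param modules a [ModuleSet-class] (gene ids must be concept ids).
#' @param conceptSets named list category -> character vector of
#'   annotation concept ids.
#' @param K annotation list cap (20).
#' @param keepZeroScores see [annotateModule()].
#' @return A [ModuleAnnotationSet-class].
#' @export
annotateModules <- function(profiles, modules, conceptSets, K = 20L,
                            keepZeroScores = FALSE) {
  rows <- list()
  for (lab in moduleLabels(modules)) {
    genes <- moduleGenes(modules, lab)
    for (cat in names(conceptSets)) {
      tb <- annotateModule(profiles, genes, conceptSets[[cat]], K = K,
                           keepZeroScores = keepZeroScores)
      if (nrow(tb))
        rows[[length(rows) + 1L]] <-
          cbind(module = lab, category = cat, tb)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), category = character(0),
               rank = integer(0), concept = character(0),
               score = numeric(0))
  methods::new("ModuleAnnotationSet", table = table, K = as.integer(K))
}

## fast path used by the permutation null: top-K indicator rows for many
## gene sets against one precomputed similarity matrix
topKIndicator <- function(SIM, geneSets, K) {
  concepts <- colnames(SIM)
  P <- length(concepts)
  ii <- integer(0); jj <- integer(0)
  for (s in seq_along(geneSets)) {
    g <- geneSets[[s]]
    g <- g[g %in% rownames(SIM)]
    sc <- if (length(g)) colSums(SIM[g, , drop = FALSE]) else rep(0, P)
    ord <- order(-sc, concepts)
    sel <- ord[sc[ord] > 0]
    sel <- head(sel, K)
    ii <- c(ii, rep.int(s, length(sel)))
    jj <- c(jj, sel)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(geneSets), P))
}
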