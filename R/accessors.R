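#' Construct a TissueExpression object
#'
#' Bundles a genes-by-samples expression matrix with its per-sample trait
#' table. Sample ids must align between the two (same set, same order after
#' matching by name). Genes with zero variance across samples are dropped
#' with a warning; missing values are rejected.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param traits data.frame of numeric traits, one row per sample
#'   (rownames = sample ids). Binary traits are coded 0/1.
#' @return A [TissueExpression-class] object.
#' @examples
#' v <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' tr <- data.frame(carrier = c(0, 1, 0, 1, 1), row.names = colnames(v))
#' tissueExpression(v, tr)
#' @export
tissueExpression <- function(values, traits) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene and sample names")
  if (!setequal(colnames(values), rownames(traits)))
    stop("sample ids of the expression matrix and the trait table differ")
  traits <- traits[colnames(values), , drop = FALSE]
  rv <- apply(values, 1L, stats::var)
  if (any(rv == 0)) {
    warning(sum(rv == 0), " zero-variance gene(s) dropped")
    values <- values[rv > 0, , drop = FALSE]
  }
  if (nrow(values) == 0L) stop("no genes left after variance filtering")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(traits))
  methods::new("TissueExpression", se)
}

#' Expression matrix of a TissueExpression
#' @param x a [TissueExpression-class] object.
#' @return genes x samples numeric matrix.
#' @rdname exprValues
#' @export
setMethod("exprValues", "TissueExpression", function(x)
  SummarizedExperiment::assay(x, "expr"))

#' Trait table of a TissueExpression
#' @param x a [TissueExpression-class] object.
#' @return data.frame of numeric traits, rows = samples.
#' @rdname traitData
#' @export
setMethod("traitData", "TissueExpression", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' Construct a ModuleSet
#'
#' @param assignment named character vector gene -> module label.
#' @param unassignedLabel label marking the unassigned pool.
#' @return A [ModuleSet-class].
#' @export
moduleSet <- function(assignment, unassignedLabel = "unassigned") {
  methods::new("ModuleSet", assignment = assignment,
               unassignedLabel = unassignedLabel)
}

#' Module labels (excluding the unassigned pool)
#' @param x a [ModuleSet-class].
#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) {
  lab <- setdiff(unique(x@assignment), x@unassignedLabel)
  lab[order(lab)]
})

#' Genes of one module
#' @param x a [ModuleSet-class].
#' @param module a module label.
#' @rdname moduleGenes
#' @export
setMethod("moduleGenes", "ModuleSet", function(x, module) {
  names(x@assignment)[x@assignment == module]
})

#' Module sizes
#' @param x a [ModuleSet-class].
#' @return named integer vector of module sizes, decreasing.
#' @rdname moduleSizes
#' @export
setMethod("moduleSizes", "ModuleSet", function(x) {
  a <- x@assignment[x@assignment != x@unassignedLabel]
  if (!length(a)) return(stats::setNames(integer(0), character(0)))
  tb <- table(a)
  sz <- stats::setNames(as.integer(tb), names(tb))
  sort(sz, decreasing = TRUE)
})

#' All genes that entered module detection
#' @param x a [ModuleSet-class].
#' @rdname geneUniverse
#' @export
setMethod("geneUniverse", "ModuleSet", function(x) names(x@assignment))

#' Genes in the unassigned pool
#' @param x a [ModuleSet-class].
#' @rdname unassignedGenes
#' @export
setMethod("unassignedGenes", "ModuleSet", function(x)
  names(x@assignment)[x@assignment == x@unassignedLabel])

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleSet with", length(sz), "modules over",
      length(object@assignment), "genes\n")
  if (length(sz)) {
    cat("  sizes:", paste0(names(sz), "=", sz, collapse = ", "), "\n")
  }
  cat("  unassigned:", sum(object@assignment == object@unassignedLabel), "\n")
})

setMethod("show", "ConceptCorpus", function(object) {
  cat("ConceptCorpus:", length(object@docs), "documents,",
      nrow(object@vocabulary), "concepts\n")
  print(table(object@vocabulary$category))
})

setMethod("show", "ConceptProfiles", function(object) {
  cat("ConceptProfiles:", length(object@eligible), "eligible owners of",
      nrow(object@weights), "concepts (minDocs =", object@minDocs, ")\n")
})

setMethod("show", "PairSignificance", function(object) {
  cat("PairSignificance [", object@category, "]: ",
      nrow(object@observed), " x ", ncol(object@observed), " pairs; ",
      sum(object@strict), " strict (<= ", object@levels[1L], "), ",
      sum(object@marginal), " marginal (<= ", object@levels[2L], ")\n",
      sep = "")
})

setMethod("show", "SignatureReport", function(object) {
  cat("SignatureReport\n")
  for (t in names(object@modules))
    cat("  ", t, ": ", length(moduleLabels(object@modules[[t]])),
        " modules\n", sep = "")
  cat("  signatures:", nrow(object@signatures), "\n")
})

#' Annotation table of a ModuleAnnotationSet
#' @param x a [ModuleAnnotationSet-class].
#' @rdname annotationTable
#' @export
setMethod("annotationTable", "ModuleAnnotationSet", function(x) x@table)

#' Ranked annotation concepts of one module in one category
#' @param x a [ModuleAnnotationSet-class].
#' @param module module label.
#' @param category semantic category.
#' @return character vector of concept ids, best first.
#' @rdname annotationConcepts
#' @export
setMethod("annotationConcepts", "ModuleAnnotationSet",
  function(x, module, category) {
    tb <- x@table
    tb <- tb[tb$module == module & tb$category == category, , drop = FALSE]
    tb$concept[order(tb$rank)]
  })

#' Long-format significance table
#' @param x a [PairSignificance-class].
#' @return data.frame with one row per (blood module, brain module) pair.
#' @rdname significanceTable
#' @export
setMethod("significanceTable", "PairSignificance", function(x) {
  n <- nrow(x@observed); m <- ncol(x@observed)
  data.frame(
    blood = rep(rownames(x@observed), m),
    brain = rep(colnames(x@observed), each = n),
    category = x@category,
    score = as.vector(x@observed),
    rawP = as.vector(x@rawP),
    adjP = as.vector(x@adjP),
    strict = as.vector(x@strict),
    marginal = as.vector(x@marginal),
    stringsAsFactors = FALSE)
})
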