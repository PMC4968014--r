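## Tab-separated readers/writers for every pipeline artifact. All writers
## emit header lines and no quoting so that write -> read -> write is
## byte-stable.

fmtNum <- function(x) {
  # fixed, locale-independent numeric formatting for byte-stable output
  ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g"))
}

#' Read / write expression matrices
#'
#' Expression TSV: one row per gene, first column `gene`, remaining
#' columns the samples.
#'
#' @param x matrix or [TissueExpression-class].
#' @param path file path.
#' @return `readExpression` returns a genes x samples numeric matrix.
#' @export
writeExpression <- function(x, path) {
  v <- asExprMatrix(x)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read / write per-sample trait tables
#'
#' Trait TSV: one row per sample, first column `sample`.
#'
#' @param traits data.frame with sample rownames.
#' @param path file path.
#' @export
writeTraits <- function(traits, path) {
  df <- data.frame(sample = rownames(traits), traits,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraits
#' @export
readTraits <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  df[, -1L, drop = FALSE]
}

#' Read / write a concept corpus
#'
#' Documents are line-delimited records: document id followed by
#' whitespace-separated concept ids. The vocabulary is a two-column TSV
#' (`concept`, `category`).
#'
#' @param corpus a [ConceptCorpus-class].
#' @param docsPath,vocabPath file paths.
#' @export
writeCorpus <- function(corpus, docsPath, vocabPath) {
  lines <- vapply(names(corpus@docs), function(id)
    paste(c(id, sort(corpus@docs[[id]])), collapse = " "), character(1))
  writeLines(lines, docsPath)
  utils::write.table(corpus@vocabulary, vocabPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(docsPath)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(docsPath, vocabPath) {
  lines <- readLines(docsPath)
  parts <- strsplit(lines, "[[:space:]]+")
  docs <- lapply(parts, function(p) p[-1L])
  names(docs) <- vapply(parts, `[[`, character(1), 1L)
  vocab <- utils::read.delim(vocabPath, stringsAsFactors = FALSE)
  conceptCorpus(docs, vocab)
}

#' Read / write concept-set definitions
#'
#' GMT-like lines: set name, semantic category, then the member concept
#' ids, all tab-separated.
#'
#' @param conceptSets named list category -> concept ids (the set name
#'   equals the category).
#' @param path file path.
#' @export
writeConceptSets <- function(conceptSets, path) {
  lines <- vapply(names(conceptSets), function(nm)
    paste(c(nm, nm, conceptSets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeConceptSets
#' @export
readConceptSets <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- vapply(parts, `[[`, character(1), 2L)
  out
}

#' Read / write module assignments
#'
#' Two-column TSV (`gene`, `module`); the unassigned pool keeps its
#' label.
#'
#' @param modules a [ModuleSet-class].
#' @param path file path.
#' @param unassignedLabel label used for the unassigned pool on read.
#' @export
writeModuleAssignments <- function(modules, path) {
  df <- data.frame(gene = names(modules@assignment),
                   module = unname(modules@assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeModuleAssignments
#' @export
readModuleAssignments <- function(path, unassignedLabel = "unassigned") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  moduleSet(stats::setNames(df$module, df$gene), unassignedLabel)
}

#' Write module-trait correlation results
#'
#' Long TSV: module, trait, r, p.
#'
#' @param x a [ModuleTraitResult-class].
#' @param path file path.
#' @export
writeModuleTrait <- function(x, path) {
  df <- data.frame(
    module = rep(rownames(x@r), ncol(x@r)),
    trait = rep(colnames(x@r), each = nrow(x@r)),
    r = fmtNum(as.vector(x@r)), p = fmtNum(as.vector(x@p)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-module annotations
#'
#' TSV columns: module, category, rank, concept, score.
#'
#' @param x a [ModuleAnnotationSet-class].
#' @param path file path.
#' @export
writeAnnotations <- function(x, path) {
  tb <- x@table
  tb$score <- fmtNum(tb$score)
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write pair significance tables
#'
#' @param x a [PairSignificance-class] or named list of them.
#' @param path file path.
#' @export
writeSignificance <- function(x, path) {
  if (methods::is(x, "PairSignificance")) x <- list(x)
  tb <- do.call(rbind, lapply(x, significanceTable))
  tb$rawP <- fmtNum(tb$rawP); tb$adjP <- fmtNum(tb$adjP)
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the signature report
#'
#' Structured text: a manifest block (key/value), the per-category
#' summary, and one block per classified signature listing its shared
#' annotation concepts. Timestamp-free, so identical runs produce
#' byte-identical reports.
#'
#' @param report a [SignatureReport-class].
#' @param path file path.
#' @export
writeSignatureReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# manifest")
  mf <- report@manifest
  for (nm in setdiff(names(mf), "netParams"))
    w(nm, "\t", paste(unlist(mf[[nm]]), collapse = ","))
  w("# summary")
  s <- report@summary
  w("category\tstrictPairs\tmarginalPairs")
  for (i in seq_len(nrow(s)))
    w(s$category[i], "\t", s$strictPairs[i], "\t", s$marginalPairs[i])
  w("# signatures")
  sg <- report@signatures
  if (nrow(sg) == 0L) {
    w("(none)")
  } else {
    for (i in seq_len(nrow(sg))) {
      w("signature\t", sg$blood[i], "\t", sg$brain[i], "\t",
        sg$category[i], "\t", sg$flag[i])
      w("  score\t", sg$score[i], "\tadjP\t", fmtNum(sg$adjP[i]))
      w("  shared\t", sg$sharedConcepts[i])
    }
  }
  invisible(path)
}

#' Read a two-column gene-identifier mapping
#'
#' TSV with columns `from`, `to`; returns the named character vector
#' used by [geneOverlap()].
#'
#' @param path file path.
#' @export
readGeneIdMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}
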