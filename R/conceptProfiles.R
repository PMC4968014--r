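#' Construct a concept corpus
#'
#' @param docs named list (by document id) of character vectors of
#'   concept ids; each document's concepts are deduplicated.
#' @param vocabulary data.frame with columns `concept` and `category`
#'   covering every concept appearing in the documents.
#' @return A [ConceptCorpus-class].
#' @export
conceptCorpus <- function(docs, vocabulary) {
  if (length(docs) && (is.null(names(docs)) || anyDuplicated(names(docs))))
    stop("documents must carry unique ids")
  docs <- lapply(docs, function(d) unique(as.character(d)))
  methods::new("ConceptCorpus", docs = docs,
               vocabulary = as.data.frame(vocabulary))
}

#' Exact document co-occurrence counts
#'
#' Counts, over the whole corpus, the number of documents each concept
#' occurs in (`docFreq`) and the number of documents each concept pair
#' co-occurs in (sparse `joint`, with the document frequencies on the
#' diagonal).
#'
#' @param corpus a [ConceptCorpus-class] with at least one document.
#' @return A [CooccurrenceCounts-class].
#' @export
cooccurrenceCounts <- function(corpus) {
  N <- length(corpus@docs)
  if (N < 1L) stop("empty corpus")
  vocab <- corpus@vocabulary$concept
  lens <- lengths(corpus@docs)
  j <- match(unlist(corpus@docs, use.names = FALSE), vocab)
  i <- rep.int(seq_len(N), lens)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(N, length(vocab)),
                            dimnames = list(names(corpus@docs), vocab))
  joint <- Matrix::crossprod(M)
  df <- as.integer(Matrix::diag(joint))
  names(df) <- vocab
  methods::new("CooccurrenceCounts", nDocs = as.integer(N),
               docFreq = df, joint = joint)
}

xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Symmetric uncertainty coefficient of two binary occurrence indicators
#'
#' `U = 2 I(X; Y) / (H(X) + H(Y))`, with X and Y the document-occurrence
#' indicators implied by the 2x2 contingency table of `(nX, nY, nXY, N)`.
#' Entropies are in bits (the base cancels). `U = 0` is returned when
#' `H(X) + H(Y) = 0`. Vectorized over its arguments.
#'
#' @param nX,nY per-concept document frequencies.
#' @param nXY joint document frequency, `0 <= nXY <= min(nX, nY)`.
#' @param N total number of documents (> 0).
#' @return numeric in \[0, 1\].
#' @examples
#' symmetricUncertainty(5, 5, 5, 10)  # identical occurrence -> 1
#' symmetricUncertainty(5, 4, 2, 10)  # exact independence -> 0
#' @export
symmetricUncertainty <- function(nX, nY, nXY, N) {
  if (any(N <= 0)) stop("N must be positive")
  if (any(nXY > pmin(nX, nY)) || any(nXY < 0) || any(nX > N) || any(nY > N))
    stop("inconsistent counts: need 0 <= nXY <= min(nX, nY) <= N")
  if (any(nX + nY - nXY > N))
    stop("inconsistent counts: nX + nY - nXY exceeds N")
  pa <- nXY / N
  pb <- (nX - nXY) / N
  pc <- (nY - nXY) / N
  pd <- 1 - pa - pb - pc
  px <- nX / N
  py <- nY / N
  H <- function(p) -(xlog2(p) + xlog2(1 - p))
  term <- function(p, qx, qy)
    ifelse(p > 0, p * (log2(p) - log2(qx) - log2(qy)), 0)
  I <- term(pa, px, py) + term(pb, px, 1 - py) +
       term(pc, 1 - px, py) + term(pd, 1 - px, 1 - py)
  den <- H(px) + H(py)
  u <- ifelse(den == 0, 0, 2 * I / den)
  pmin(pmax(u, 0), 1)
}

#' Build concept profiles from co-occurrence counts
#'
#' A profile is created for every concept occurring in at least
#' `minDocs` documents. The profile of owner `x` assigns to every other
#' concept `y` that co-occurs with `x` at least once the weight
#' `U(x, y)` (symmetric uncertainty); zero weights are dropped and the
#' owner is excluded from its own profile. Ineligible concepts have no
#' profile.
#'
#' @param counts a [CooccurrenceCounts-class].
#' @param minDocs eligibility threshold on document frequency (5).
#' @param categories optional named character vector concept ->
#'   semantic category, carried into the result.
#' @return A [ConceptProfiles-class].
#' @export
buildProfiles <- function(counts, minDocs = 5L, categories = NULL) {
  vocab <- names(counts@docFreq)
  eligible <- vocab[counts@docFreq >= minDocs]
  J <- methods::as(methods::as(counts@joint, "generalMatrix"), "TsparseMatrix")
  i <- J@i + 1L; j <- J@j + 1L; x <- J@x
  keep <- i != j & x >= 1 & vocab[i] %in% eligible
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  u <- if (length(i))
    symmetricUncertainty(counts@docFreq[i], counts@docFreq[j], x,
                         counts@nDocs)
  else numeric(0)
  pos <- u > 0
  W <- Matrix::sparseMatrix(i = i[pos], j = j[pos], x = u[pos],
                            dims = c(length(vocab), length(vocab)),
                            dimnames = list(vocab, vocab))
  if (is.null(categories))
    categories <- stats::setNames(rep(NA_character_, length(vocab)), vocab)
  methods::new("ConceptProfiles", weights = W, eligible = eligible,
               minDocs = as.integer(minDocs), categories = categories)
}

#' Concept profiles derived directly from a corpus
#'
#' @param corpus a [ConceptCorpus-class].
#' @param minDocs eligibility threshold (5).
#' @return A [ConceptProfiles-class] carrying the vocabulary categories.
#' @export
corpusProfiles <- function(corpus, minDocs = 5L) {
  counts <- cooccurrenceCounts(corpus)
  cats <- stats::setNames(corpus@vocabulary$category,
                          corpus@vocabulary$concept)
  buildProfiles(counts, minDocs = minDocs, categories = cats)
}

#' Retrieve one concept profile
#'
#' @param x a [ConceptProfiles-class].
#' @param concept owner concept id.
#' @return named numeric vector of positive weights, or `NULL` when the
#'   concept is ineligible (occurs in fewer than `minDocs` documents).
#'   An eligible concept co-occurring with nothing yields an empty
#'   (length zero) vector.
#' @rdname conceptProfile
#' @export
setMethod("conceptProfile", "ConceptProfiles", function(x, concept) {
  if (!concept %in% rownames(x@weights)) stop("unknown concept: ", concept)
  if (!concept %in% x@eligible) return(NULL)
  w <- x@weights[concept, ]
  w <- w[w > 0]
  if (!length(w)) return(stats::setNames(numeric(0), character(0)))
  w
})

#' @rdname conceptProfile
#' @export
setMethod("hasProfile", "ConceptProfiles", function(x, concept)
  concept %in% x@eligible)

#' Inner-product match of two concept profiles
#'
#' Sum over shared concepts of the product of the two weights;
#' symmetric, zero when the supports are disjoint.
#'
#' @param p,q named numeric weight vectors as returned by
#'   [conceptProfile()], or (when `profiles` is given) two concept ids.
#' @param profiles optional [ConceptProfiles-class] to look `p` and `q`
#'   up in; both concepts must be eligible.
#' @return non-negative numeric scalar.
#' @examples
#' profileMatch(c(a = 0.5, b = 0.2), c(b = 0.4, c = 0.9))  # 0.08
#' @export
profileMatch <- function(p, q, profiles = NULL) {
  if (!is.null(profiles)) {
    if (!hasProfile(profiles, p)) stop("no profile for concept: ", p)
    if (!hasProfile(profiles, q)) stop("no profile for concept: ", q)
    return(as.numeric(profiles@weights[p, , drop = FALSE] %*%
                      Matrix::t(profiles@weights[q, , drop = FALSE])))
  }
  shared <- intersect(names(p), names(q))
  if (!length(shared)) return(0)
  sum(p[shared] * q[shared])
}
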