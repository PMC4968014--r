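#' Network construction parameters
#'
#' Presets encode the per-network settings of the reference HD blood
#' and brain networks: soft powers blood/caudate 9, BA4 3, BA9/cerebellum
#' 5; minModuleSize 15 everywhere; deepSplit 0 (blood) or 2 (brain);
#' cutHeight 0.995 (blood) or 0.999 (brain); MEDissThres 0.30 (blood) or
#' 0.0001 (brain, effectively no merging).
#'
#' @param softPower soft-threshold exponent (> 0).
#' @param minModuleSize minimum module size.
#' @param deepSplit branch-split sensitivity (integer >= 0).
#' @param cutHeight dendrogram cut height in (0, 1].
#' @param MEDissThres eigengene dissimilarity merge threshold.
#' @param signed logical; use the signed adjacency transform.
#' @param preset optional name: "blood", "caudate", "BA4", "BA9" or
#'   "cerebellum". Explicit arguments override preset values.
#' @return A [NetworkParams-class] object.
#' @examples
#' networkParams(preset = "blood")
#' networkParams(softPower = 6, deepSplit = 2, cutHeight = 0.97)
#' @export
networkParams <- function(softPower = NULL, minModuleSize = NULL,
                          deepSplit = NULL, cutHeight = NULL,
                          MEDissThres = NULL, signed = FALSE,
                          preset = NULL) {
  def <- list(softPower = 6, minModuleSize = 15L, deepSplit = 2L,
              cutHeight = 0.995, MEDissThres = 0.15)
  if (!is.null(preset)) {
    presets <- list(
      blood      = list(softPower = 9, deepSplit = 0L, cutHeight = 0.995,
                        MEDissThres = 0.30),
      caudate    = list(softPower = 9, deepSplit = 2L, cutHeight = 0.999,
                        MEDissThres = 0.0001),
      BA4        = list(softPower = 3, deepSplit = 2L, cutHeight = 0.999,
                        MEDissThres = 0.0001),
      BA9        = list(softPower = 5, deepSplit = 2L, cutHeight = 0.999,
                        MEDissThres = 0.0001),
      cerebellum = list(softPower = 5, deepSplit = 2L, cutHeight = 0.999,
                        MEDissThres = 0.0001))
    if (!preset %in% names(presets)) stop("unknown preset: ", preset)
    def[names(presets[[preset]])] <- presets[[preset]]
    def$minModuleSize <- 15L
  }
  pick <- function(x, d) if (is.null(x)) d else x
  methods::new("NetworkParams",
    softPower = as.numeric(pick(softPower, def$softPower)),
    minModuleSize = as.integer(pick(minModuleSize, def$minModuleSize)),
    deepSplit = as.integer(pick(deepSplit, def$deepSplit)),
    cutHeight = as.numeric(pick(cutHeight, def$cutHeight)),
    MEDissThres = as.numeric(pick(MEDissThres, def$MEDissThres)),
    signed = isTRUE(signed))
}

asExprMatrix <- function(x) {
  if (methods::is(x, "TissueExpression")) exprValues(x) else as.matrix(x)
}

#' Gene-gene Pearson correlation matrix
#'
#' @param x a [TissueExpression-class] or genes x samples matrix with at
#'   least 3 samples and no zero-variance gene.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(x) {
  v <- asExprMatrix(x)
  if (ncol(v) < 3L) stop("at least 3 samples are required")
  rv <- apply(v, 1L, stats::var)
  if (any(rv == 0)) stop("zero-variance gene(s): ",
                         paste(head(rownames(v)[rv == 0]), collapse = ", "))
  cc <- stats::cor(t(v))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Soft-threshold adjacency
#'
#' Unsigned mode: `a_ij = |cor_ij|^beta`; signed mode:
#' `a_ij = ((1 + cor_ij)/2)^beta`. The diagonal is set to zero so row
#' sums are connectivities.
#'
#' @param corr correlation matrix.
#' @param params a [NetworkParams-class] (uses `softPower`, `signed`).
#' @return adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
softAdjacency <- function(corr, params) {
  beta <- params@softPower
  if (beta <= 0) stop("soft power must be > 0")
  a <- if (params@signed) ((1 + corr) / 2)^beta else abs(corr)^beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Bins connectivities `k_i = sum_j a_ij`, regresses `log10(freq)` on
#' `log10(mean k)` per occupied bin and returns the signed R squared
#' (negated when the slope is positive). Used to validate a chosen soft
#' power, not to auto-select one.
#'
#' @param adjacency adjacency matrix (zero diagonal), >= 10 genes.
#' @param nBins number of connectivity bins.
#' @return signed R squared in \[-1, 1\].
#' @export
scaleFreeFit <- function(adjacency, nBins = 10L) {
  if (nrow(adjacency) < 10L) stop("at least 10 genes are required")
  k <- Matrix::rowSums(adjacency)
  if (all(k == 0)) stop("all-zero adjacency")
  if (stats::sd(k) == 0) {
    warning("constant connectivity; fit undefined, returning 0")
    return(0)
  }
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mk > 0
  freq <- freq[keep]; mk <- mk[keep]
  if (length(freq) < 3L) {
    warning("fewer than 3 occupied bins; fit undefined, returning 0")
    return(0)
  }
  fit <- stats::lm(log10(freq / sum(freq)) ~ log10(mk))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2L] > 0) -r2 else r2
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, and `TOM_ii = 1`.
#'
#' @param adjacency symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return TOM similarity matrix in \[0, 1\], unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0) || any(a > 1)) stop("adjacency must lie in [0, 1]")
  if (any(abs(a - t(a)) > 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  if (any(den <= 0)) stop("non-positive TOM denominator (invalid adjacency)")
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  pmin(pmax(tom, 0), 1)
}

## --- dendrogram helpers (merge-tree navigation for the branch cut) ------

nodeMembers <- function(merge, node) {
  # members (leaf indices) of internal node `node` (row of merge)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    for (ch in merge[nd, ]) {
      if (ch < 0) out <- c(out, -ch) else stack <- c(stack, ch)
    }
  }
  out
}

#' Cut the co-expression dendrogram into modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, followed by a
#' branch cut: connected branches below `cutHeight` of size at least
#' `minModuleSize` become modules. With `deepSplit >= 1` a branch whose
#' two sub-branches are separated from the branch merge height by more
#' than `(0.25 / deepSplit) * height` is split recursively, provided both
#' halves satisfy `minModuleSize`. Leftover genes are adopted by the
#' module with the highest mean TOM to its members when that mean exceeds
#' both the gene's mean TOM to non-members and the cohesion floor
#' `1 - cutHeight`; otherwise they stay unassigned.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param params a [NetworkParams-class].
#' @return A [ModuleSet-class]; modules are labelled "M1", "M2", ... in
#'   decreasing size order.
#' @export
clusterAndCut <- function(tom, params) {
  genes <- rownames(tom)
  n <- length(genes)
  if (params@minModuleSize > n) {
    warning("minModuleSize exceeds the number of genes; all unassigned")
    return(moduleSet(stats::setNames(rep("unassigned", n), genes)))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # ties in the dissimilarity can leave float-level height inversions
  hc$height <- cummax(hc$height)
  base <- stats::cutree(hc, h = params@cutHeight)

  merge <- hc$merge; height <- hc$height
  nodeH <- function(ch) if (ch < 0) 0 else height[ch]
  nodeSize <- function(ch) if (ch < 0) 1L else length(nodeMembers(merge, ch))
  chMembers <- function(ch) if (ch < 0) -ch else nodeMembers(merge, ch)

  splitBranch <- function(node) {
    # node: index into merge rows; returns list of member index vectors
    h <- height[node]
    ch <- merge[node, ]
    h1 <- nodeH(ch[1L]); h2 <- nodeH(ch[2L])
    s1 <- nodeSize(ch[1L]); s2 <- nodeSize(ch[2L])
    ds <- params@deepSplit
    if (ds >= 1L && s1 >= params@minModuleSize && s2 >= params@minModuleSize &&
        (h - max(h1, h2)) > (0.25 / ds) * h) {
      out <- list()
      for (c2 in ch) {
        if (c2 < 0) out <- c(out, list(-c2))
        else out <- c(out, splitBranch(c2))
      }
      out
    } else {
      list(nodeMembers(merge, node))
    }
  }

  groups <- list()
  for (cl in unique(base)) {
    members <- which(base == cl)
    if (length(members) < params@minModuleSize) next
    if (length(members) == 1L) next
    # root node of this branch: internal node whose member set == members
    root <- NA_integer_
    for (nd in seq_len(nrow(merge))) {
      mm <- nodeMembers(merge, nd)
      if (length(mm) == length(members) && all(sort(mm) == sort(members))) {
        root <- nd; break
      }
    }
    if (is.na(root)) { groups <- c(groups, list(members)); next }
    groups <- c(groups, splitBranch(root))
  }

  assignment <- stats::setNames(rep("unassigned", n), genes)
  for (i in seq_along(groups))
    assignment[genes[groups[[i]]]] <- paste0("tmp", i)

  # leftover adoption with cohesion floor
  floorTom <- 1 - params@cutHeight
  left <- names(assignment)[assignment == "unassigned"]
  labs <- setdiff(unique(assignment), "unassigned")
  if (length(labs) && length(left)) {
    memberIdx <- lapply(labs, function(l) which(assignment == l))
    adopted <- assignment
    for (g in left) {
      gi <- match(g, genes)
      mm <- vapply(memberIdx, function(ix) mean(tom[gi, ix]), numeric(1))
      best <- which.max(mm)
      others <- setdiff(seq_len(n), c(gi, memberIdx[[best]]))
      nonMean <- if (length(others)) mean(tom[gi, others]) else 0
      if (mm[best] > nonMean && mm[best] > floorTom)
        adopted[g] <- labs[best]
    }
    assignment <- adopted
  }

  relabelBySize(assignment)
}

relabelBySize <- function(assignment, unassignedLabel = "unassigned") {
  labs <- setdiff(unique(assignment), unassignedLabel)
  if (!length(labs))
    return(moduleSet(assignment, unassignedLabel))
  sz <- vapply(labs, function(l) sum(assignment == l), integer(1))
  ord <- labs[order(-sz, labs)]
  map <- stats::setNames(paste0("M", seq_along(ord)), ord)
  out <- assignment
  keep <- assignment != unassignedLabel
  out[keep] <- map[assignment[keep]]
  moduleSet(out, unassignedLabel)
}

#' Module eigengene
#'
#' First principal component of the per-gene z-scored module submatrix
#' across samples; returned with unit norm and oriented so that its
#' correlation with the module's mean expression profile is
#' non-negative.
#'
#' @param x a [TissueExpression-class] or genes x samples matrix.
#' @param genes character vector of module gene ids (>= 2).
#' @return named per-sample numeric vector with unit Euclidean norm.
#' @export
moduleEigengene <- function(x, genes) {
  v <- asExprMatrix(x)
  if (length(genes) < 2L) stop("a module needs at least 2 genes")
  if (!all(genes %in% rownames(v))) stop("unknown module genes")
  sub <- v[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) stop("module contains constant gene rows")
  z <- (sub - rowMeans(sub)) / sds
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  m <- colMeans(sub)
  if (stats::sd(m) > 0) {
    r <- stats::cor(e, m)
    if (!is.na(r) && r < 0) e <- -e
  }
  stats::setNames(e, colnames(v))
}

#' Eigengenes of all modules
#'
#' @param x a [TissueExpression-class] or matrix.
#' @param modules a [ModuleSet-class].
#' @return modules x samples matrix of unit-norm eigengenes.
#' @export
moduleEigengenes <- function(x, modules) {
  labs <- moduleLabels(modules)
  v <- asExprMatrix(x)
  E <- t(vapply(labs, function(l) moduleEigengene(v, moduleGenes(modules, l)),
                numeric(ncol(v))))
  rownames(E) <- labs
  E
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest module pair whose eigengene
#' dissimilarity `1 - cor(E_a, E_b)` is below `MEDissThres`, recomputing
#' eigengenes after every merge, until no such pair remains. Idempotent.
#'
#' @param x a [TissueExpression-class] or matrix.
#' @param modules a [ModuleSet-class].
#' @param MEDissThres merge threshold in \[0, 1\]; taken from `params`
#'   when a [NetworkParams-class] is given.
#' @return A [ModuleSet-class] relabelled by size.
#' @export
mergeModules <- function(x, modules, MEDissThres) {
  if (methods::is(MEDissThres, "NetworkParams"))
    MEDissThres <- MEDissThres@MEDissThres
  assignment <- modules@assignment
  v <- asExprMatrix(x)
  repeat {
    ms <- moduleSet(assignment, modules@unassignedLabel)
    labs <- moduleLabels(ms)
    if (length(labs) < 2L) break
    E <- moduleEigengenes(v, ms)
    diss <- 1 - stats::cor(t(E))
    diag(diss) <- Inf
    idx <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[idx[1L], idx[2L]] >= MEDissThres) break
    a <- labs[idx[1L]]; b <- labs[idx[2L]]
    assignment[assignment == b] <- a
  }
  relabelBySize(assignment, modules@unassignedLabel)
}

#' Detect co-expression modules for one tissue
#'
#' Convenience wrapper: correlation, soft-threshold adjacency,
#' topological overlap, branch cut and eigengene merging.
#'
#' @param x a [TissueExpression-class].
#' @param params a [NetworkParams-class].
#' @return A [ModuleSet-class].
#' @export
detectModules <- function(x, params) {
  cc <- correlationMatrix(x)
  a <- softAdjacency(cc, params)
  tom <- tomSimilarity(a)
  ms <- clusterAndCut(tom, params)
  if (length(moduleLabels(ms)) >= 2L)
    ms <- mergeModules(x, ms, params@MEDissThres)
  ms
}

#' Module-trait Pearson correlation
#'
#' Correlates every module eigengene with every trait; two-sided
#' p-values come from the t statistic on n - 2 degrees of freedom. A
#' module is flagged disease-associated when its smallest trait p-value
#' is below `pThreshold`. A constant trait yields r = NA and p = 1 with
#' a warning.
#'
#' @param x a [TissueExpression-class].
#' @param modules a [ModuleSet-class].
#' @param pThreshold per-cell association threshold (0.05).
#' @return A [ModuleTraitResult-class].
#' @export
moduleTraitCorrelation <- function(x, modules, pThreshold = 0.05) {
  v <- exprValues(x)
  n <- ncol(v)
  if (n < 3L) stop("at least 3 samples are required")
  tr <- traitData(x)
  if (!all(vapply(tr, is.numeric, logical(1))))
    stop("all traits must be numeric")
  E <- moduleEigengenes(v, modules)
  labs <- rownames(E)
  r <- p <- matrix(NA_real_, length(labs), ncol(tr),
                   dimnames = list(labs, colnames(tr)))
  for (j in seq_len(ncol(tr))) {
    tv <- tr[[j]]
    if (stats::sd(tv) == 0) {
      warning("constant trait '", colnames(tr)[j],
              "': correlation undefined, p set to 1")
      p[, j] <- 1
      next
    }
    for (i in seq_along(labs)) {
      rij <- stats::cor(E[i, ], tv)
      tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      r[i, j] <- rij
      p[i, j] <- max(2 * stats::pt(-abs(tstat), df = n - 2),
                     .Machine$double.xmin)
    }
  }
  assoc <- apply(p, 1L, function(z) any(z < pThreshold, na.rm = TRUE))
  methods::new("ModuleTraitResult", eigengenes = E, r = r, p = p,
               associated = assoc)
}
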