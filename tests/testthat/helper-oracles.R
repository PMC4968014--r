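# Independent naive re-derivation of the step-down minP adjustment,
# used as the oracle against the vectorized implementation. Triple
# loops on purpose; shares no code with the package.
bruteMinP <- function(obs, null) {
  H <- length(obs); R <- ncol(null)
  pfun <- function(s, v) (1 + sum(v >= s)) / (1 + R)
  raw <- sapply(seq_len(H), function(h) pfun(obs[h], null[h, ]))
  repP <- matrix(NA_real_, H, R)
  for (h in seq_len(H)) for (r in seq_len(R))
    repP[h, r] <- pfun(null[h, r], null[h, ])
  ord <- order(raw, seq_len(H))
  adj <- numeric(H)
  for (pos in seq_len(H)) {
    hs <- ord[pos:H]
    cnt <- 0
    for (r in seq_len(R)) {
      if (min(repP[hs, r, drop = FALSE]) <= raw[ord[pos]]) cnt <- cnt + 1
    }
    adj[pos] <- (1 + cnt) / (1 + R)
  }
  for (pos in seq_len(H)) adj[pos] <- max(adj[1:pos])
  out <- numeric(H); out[ord] <- adj
  pmax(out, raw)
}

randomNullInstance <- function(n, m, KA, KB, smax = 20L) {
  obs <- matrix(sample(0:smax, n * m, TRUE), n, m,
                dimnames = list(paste0("A", seq_len(n)),
                                paste0("B", seq_len(m))))
  null <- methods::new("PermutationNull",
    scores = matrix(sample(0:smax, n * m * KA * KB, TRUE),
                    n * m, KA * KB),
    n = as.integer(n), m = as.integer(m),
    nA = as.integer(KA), nB = as.integer(KB), category = "test")
  list(obs = obs, null = null)
}

# detected module label -> planted module id, by majority gene overlap
matchToTruth <- function(ms, truth) {
  sapply(moduleLabels(ms), function(l) {
    tt <- table(truth@assignment[moduleGenes(ms, l)])
    names(tt)[which.max(tt)]
  })
}

# block-structured TOM matrix with planted modules
blockTom <- function(sizes, within = 0.9, between = 0.05,
                     nNoise = 0L, noiseLevel = 0.01) {
  n <- sum(sizes) + nNoise
  tom <- matrix(between, n, n)
  off <- 0L
  for (s in sizes) {
    idx <- off + seq_len(s)
    tom[idx, idx] <- within
    off <- off + s
  }
  if (nNoise > 0) {
    idx <- sum(sizes) + seq_len(nNoise)
    tom[idx, ] <- noiseLevel
    tom[, idx] <- noiseLevel
  }
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tom
}

# tiny handmade corpus for annotation arithmetic
handCorpus <- function() {
  docs <- list(
    d1 = c("g1", "a1", "a2"),
    d2 = c("g1", "a1"),
    d3 = c("g2", "a2", "x1"),
    d4 = c("g2", "a1", "a2"),
    d5 = c("g3", "x1"),
    d6 = c("g1", "g2", "a2"),
    d7 = c("g3", "a1", "x1"),
    d8 = c("g1", "g3", "a1", "a2", "x1"),
    d9 = c("g2", "x1"),
    d10 = c("g3", "a2"))
  vocab <- data.frame(
    concept = c("g1", "g2", "g3", "a1", "a2", "x1"),
    category = c("gene", "gene", "gene", "biological_process",
                 "biological_process", "molecular_function"),
    stringsAsFactors = FALSE)
  conceptCorpus(docs, vocab)
}
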