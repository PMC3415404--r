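# Independent brute-force oracles used to validate the exact statistics.
# These deliberately avoid the distribution functions the package calls.

binomTailOracle <- function(s, n, p) {
  if (s == 0) return(1)
  i <- s:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

hyperTailOracle <- function(k, draws, K, N) {
  i <- k:min(draws, K)
  sum(choose(K, i) * choose(N - K, draws - i)) / choose(N, draws)
}

poisTailOracle <- function(k, lam) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lam) * lam^i / factorial(i))
}

# exact Mann-Whitney by full enumeration of group assignments (ties allowed
# via midranks of the pooled sample)
mwEnumOracle <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  nA <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(length(pooled), nA)
  us <- apply(combos, 2, function(idx)
    sum(r[idx]) - nA * (nA + 1) / 2)
  pG <- mean(us >= uObs - 1e-9)
  pL <- mean(us <= uObs + 1e-9)
  switch(alternative,
         greater = pG, less = pL,
         two.sided = min(1, 2 * min(pG, pL)))
}

# count overlapping occurrences of a degenerate motif by enumerating every
# concrete expansion
iupacMap <- c(A = "A", C = "C", G = "G", T = "T",
              R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
              B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

expandIupac <- function(pattern) {
  sets <- strsplit(iupacMap[strsplit(pattern, "")[[1]]], "")
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

motifCountOracle <- function(seq, pattern) {
  words <- expandIupac(pattern)
  L <- nchar(pattern)
  if (nchar(seq) < L) return(0L)
  starts <- seq_len(nchar(seq) - L + 1)
  sum(vapply(starts, function(i)
    substr(seq, i, i + L - 1) %in% words, TRUE))
}

# guilt-by-association p-values by direct neighbor counting + pmf summation
gbaOracle <- function(edges, nodes, seeds) {
  n <- length(nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  vapply(nodes, function(g) {
    d <- length(adj[[g]])
    if (d == 0) return(1)
    s <- sum(adj[[g]] %in% seeds)
    q <- length(setdiff(seeds, g)) / (n - 1)
    binomTailOracle(s, d, q)
  }, 1.0)
}

# small deterministic random graph as an edge data.frame
randomGraphEdges <- function(n, pEdge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < pEdge
  data.frame(u = pairs[1, keep], v = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# toy evidence record builder
mkEvidence <- function(idA, idB, type = "physical", method = "Y2H",
                       pubmed = "1", source = "dbX", ptm = FALSE,
                       taxon = 559292L) {
  data.frame(idA = idA, idB = idB, taxonA = taxon, taxonB = taxon,
             detectionMethod = method, pubmedIds = pubmed,
             interactionType = type, sourceDb = source, ptm = ptm,
             stringsAsFactors = FALSE)
}
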