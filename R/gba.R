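#' Guilt-by-association candidate ranking
#'
#' Scores every node of the network for over-connection to a seed list. A
#' node with total degree `d` of which `s` edges hit seeds gets the exact
#' binomial upper-tail p-value `P(Bin(d, q) >= s)`. Under the default
#' `null = "node"`, the background probability `q` is the seed fraction among
#' the other nodes, `|seeds \ {g}| / (n - 1)`; `null = "endpoint"` instead
#' uses the seeds' share of all edge endpoints, an alternative null that
#' weights seeds by their connectivity. Seeds themselves are scored too
#' (flagged), with `s` counting edges to *other* seeds.
#'
#' Ranking is fully deterministic: ascending p, ties broken by descending
#' specificity, then descending degree, then lexical gene id.
#'
#' @param net An [Interactome-class].
#' @param seeds Character vector of seed gene ids (at least one must be in
#'   the network).
#' @param alpha Significance cutoff for the `significant` flag
#'   (default 0.05). No multiplicity correction is applied to the flag; BH
#'   q-values are reported alongside.
#' @param null Background model, `"node"` (default) or `"endpoint"`.
#' @return A `data.frame` ordered by rank with columns `gene`, `degree`,
#'   `seedDegree`, `specificityPct`, `pValue`, `qValue`, `isSeed`,
#'   `significant`.
#' @examples
#' net <- Interactome(edges = data.frame(
#'   u = c("C", "C", "C", "S1", "X", "Y"),
#'   v = c("S1", "S2", "X", "S2", "Y", "S2")))
#' gbaRank(net, c("S1", "S2"))
#' @export
gbaRank <- function(net, seeds, alpha = 0.05,
                    null = c("node", "endpoint")) {
  null <- match.arg(null)
  seeds <- unique(as.character(seeds))
  nodes <- networkNodes(net)
  seedsIn <- intersect(seeds, nodes)
  if (length(seedsIn) == 0L)
    stop("no seed gene is present in the network")
  deg <- nodeDegrees(net)[nodes]
  sdeg <- .setDegree(net, seedsIn)[nodes]
  isSeed <- nodes %in% seedsIn
  nNodes <- length(nodes)
  if (null == "node") {
    # q differs between seeds and non-seeds: seeds exclude themselves
    q <- ifelse(isSeed, (length(seedsIn) - 1) / (nNodes - 1),
                length(seedsIn) / (nNodes - 1))
  } else {
    ends <- 2 * sum(deg) / 2  # total endpoints = sum of degrees
    seedEnds <- sum(deg[isSeed])
    q <- rep(if (ends > 0) seedEnds / ends else 0, nNodes)
  }
  p <- vapply(seq_len(nNodes), function(i) {
    if (deg[i] == 0L) 1 else pBinomTail(sdeg[i], deg[i], q[i])
  }, 1.0)
  spec <- ifelse(deg > 0, 100 * sdeg / deg, 0)
  out <- data.frame(gene = nodes,
                    degree = as.integer(deg),
                    seedDegree = as.integer(sdeg),
                    specificityPct = spec,
                    pValue = p,
                    isSeed = isSeed,
                    stringsAsFactors = FALSE)
  out$qValue <- bhQvalues(out$pValue)
  out$significant <- out$pValue < alpha
  ord <- order(out$pValue, -out$specificityPct, -out$degree, out$gene)
  out <- out[ord, c("gene", "degree", "seedDegree", "specificityPct",
                    "pValue", "qValue", "isSeed", "significant")]
  rownames(out) <- NULL
  out
}

#' Candidate list from a guilt-by-association ranking
#'
#' Convenience filter: significant non-seed genes, in rank order.
#'
#' @param ranking Result of [gbaRank()].
#' @param includeSeeds Keep seed genes too? Default `FALSE`.
#' @return Filtered `data.frame`.
#' @export
gbaCandidates <- function(ranking, includeSeeds = FALSE) {
  keep <- ranking$significant & (includeSeeds | !ranking$isSeed)
  out <- ranking[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leave-one-out recovery of a seed list
#'
#' Exhaustive leave-one-out validation of guilt-by-association: each seed
#' present in the network is withheld in turn, the ranking is recomputed from
#' the remaining seeds, and the withheld seed counts as recovered if its
#' binomial p-value falls below `alpha`. The recovery rate estimates the
#' sensitivity of the method on that network/seed-list pair.
#'
#' @inheritParams gbaRank
#' @return List with `perSeed` (`data.frame` of gene, pValue, recovered),
#'   `recoveryRatePct`, `alpha`, `nTested`.
#' @export
looRecovery <- function(net, seeds, alpha = 0.05,
                        null = c("node", "endpoint")) {
  null <- match.arg(null)
  seeds <- unique(as.character(seeds))
  seedsIn <- intersect(seeds, networkNodes(net))
  if (length(seedsIn) < 2L)
    stop("leave-one-out needs at least 2 seeds present in the network")
  res <- lapply(seedsIn, function(g) {
    rk <- gbaRank(net, setdiff(seedsIn, g), alpha = alpha, null = null)
    row <- rk[rk$gene == g, , drop = FALSE]
    data.frame(gene = g, pValue = row$pValue,
               recovered = row$pValue < alpha, stringsAsFactors = FALSE)
  })
  perSeed <- do.call(rbind, res)
  rownames(perSeed) <- NULL
  list(perSeed = perSeed,
       recoveryRatePct = 100 * mean(perSeed$recovered),
       alpha = alpha,
       nTested = nrow(perSeed))
}

#' Complement a species' seed list with orthologs of other species' seeds
#'
#' Builds the ortholog-complemented seed list for a target species: the union
#' of its native seeds with the target-species orthologs of every other
#' species' seeds. Provenance (native vs transferred, and the source species)
#' is retained; a gene reached both natively and by transfer appears once
#' with both provenances.
#'
#' @param seedLists Named list of character vectors; names are taxon ids (as
#'   strings) of the species each seed list belongs to.
#' @param orthology `data.frame` with columns `gene`, `taxon`, `ortholog`,
#'   `orthologTaxon` mapping genes of `taxon` to orthologs in
#'   `orthologTaxon`.
#' @param targetTaxon Taxon id of the species whose list is being built.
#' @return List with `genes` (character vector) and `provenance`
#'   (`data.frame` of gene, origin, sourceTaxon).
#' @export
complementWithOrthologs <- function(seedLists, orthology, targetTaxon) {
  need <- c("gene", "taxon", "ortholog", "orthologTaxon")
  if (!all(need %in% names(orthology)))
    stop("orthology table needs columns: ", paste(need, collapse = ", "))
  targetTaxon <- as.character(targetTaxon)
  native <- unique(as.character(seedLists[[targetTaxon]]))
  prov <- if (length(native))
    data.frame(gene = native, origin = "native", sourceTaxon = targetTaxon,
               stringsAsFactors = FALSE)
  else
    data.frame(gene = character(), origin = character(),
               sourceTaxon = character(), stringsAsFactors = FALSE)
  for (tx in setdiff(names(seedLists), targetTaxon)) {
    hits <- orthology[orthology$taxon == as.integer(tx) &
                      orthology$orthologTaxon == as.integer(targetTaxon) &
                      orthology$gene %in% seedLists[[tx]], , drop = FALSE]
    if (nrow(hits))
      prov <- rbind(prov, data.frame(gene = unique(hits$ortholog),
                                     origin = "transferred",
                                     sourceTaxon = tx,
                                     stringsAsFactors = FALSE))
  }
  prov <- unique(prov)
  rownames(prov) <- NULL
  list(genes = unique(prov$gene), provenance = prov)
}

#' Read a one-gene-per-line seed list
#'
#' Lines starting with `#` are skipped. An optional second tab-separated
#' column gives the species taxon; when present, a named list split by
#' species is returned.
#'
#' @param path Path to the TSV.
#' @return Character vector, or named list of character vectors when a
#'   species column is present.
#' @export
readSeedList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, "", 1)
  if (all(lengths(parts) >= 2L) && length(parts) > 0L) {
    taxa <- vapply(parts, `[`, "", 2)
    return(split(genes, taxa))
  }
  genes
}
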