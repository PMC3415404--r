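#' Expression-weighted link scores of an interactome
#'
#' Scores every edge by the joint expression change of its endpoints:
#' `linkScore(u, v) = log2(ratio_u) + log2(ratio_v)`. This is the condensed
#' form of the log-ratio of the endpoints' joint expression after versus
#' before the intervention; a strongly positive score marks an induced
#' ("startup") interaction, a strongly negative one a suppressed
#' ("shutdown") interaction. Edges with a missing fold change at either
#' endpoint are dropped and reported.
#'
#' @param net An [Interactome-class].
#' @param fc A [FoldChangeTable-class].
#' @return `data.frame` with columns `u`, `v`, `linkScore` (plus any edge
#'   attributes carried over); dropped edge count attached as attribute
#'   `"droppedEdges"`.
#' @export
linkScores <- function(net, fc) {
  e <- networkEdges(net)
  ratios <- ratioVector(fc)
  ok <- e$u %in% names(ratios) & e$v %in% names(ratios)
  out <- e[ok, , drop = FALSE]
  out$linkScore <- log2(ratios[out$u]) + log2(ratios[out$v])
  rownames(out) <- NULL
  attr(out, "droppedEdges") <- sum(!ok)
  out
}

#' Partition scored edges into startup and shutdown networks
#'
#' Startup keeps edges with `linkScore >= threshold`, shutdown keeps
#' `linkScore <= -threshold`; the nodes of each network are the endpoints of
#' its retained edges. Edges with exactly zero score belong to neither side.
#'
#' @param scored Scored edge `data.frame` from [linkScores()].
#' @param threshold Non-negative score cutoff.
#' @param taxon Taxonomy id to tag the networks with.
#' @return List with `startup` and `shutdown` ([Interactome-class] each) and
#'   `threshold`.
#' @export
partitionStartupShutdown <- function(scored, threshold = 0,
                                     taxon = NA_integer_) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single non-negative number")
  mk <- function(e) {
    e <- e[, intersect(c("u", "v", "linkScore", "score"), names(e)),
           drop = FALSE]
    rownames(e) <- NULL
    Interactome(edges = e, taxon = taxon)
  }
  # zero scores belong to neither partition, even at threshold 0
  up <- scored[scored$linkScore >= max(threshold, .Machine$double.xmin), ,
               drop = FALSE]
  down <- scored[scored$linkScore <= -max(threshold,
                                          .Machine$double.xmin), ,
                 drop = FALSE]
  list(startup = mk(up), shutdown = mk(down), threshold = threshold)
}

#' Condense one side of a scored network to a target gene count
#'
#' Finds, by monotone search over the sorted absolute scores of the chosen
#' side, the smallest threshold whose retained subgraph has at most
#' `targetGenes` nodes, and returns that subgraph with the threshold. If even
#' the single strongest edge exceeds the target, its two endpoints are
#' returned with a warning.
#'
#' @param scored Scored edge `data.frame` from [linkScores()].
#' @param targetGenes Target node count (default 1000).
#' @param side `"startup"` (positive scores) or `"shutdown"` (negative).
#' @param taxon Taxonomy id for the result.
#' @return List with `network` ([Interactome-class]), `threshold` (absolute
#'   score cutoff) and `nGenes`.
#' @export
condenseToTarget <- function(scored, targetGenes = 1000L,
                             side = c("startup", "shutdown"),
                             taxon = NA_integer_) {
  side <- match.arg(side)
  if (!is.numeric(targetGenes) || targetGenes < 1)
    stop("'targetGenes' must be >= 1")
  if (nrow(scored) == 0L) stop("no scored edges")
  e <- if (side == "startup") scored[scored$linkScore > 0, , drop = FALSE]
       else scored[scored$linkScore < 0, , drop = FALSE]
  if (nrow(e) == 0L) stop("no edges on the ", side, " side")
  e$absScore <- abs(e$linkScore)
  e <- e[order(-e$absScore, e$u, e$v), , drop = FALSE]
  # node count after keeping the strongest k edges, k = 1..n; monotone in k
  nodesAfter <- integer(nrow(e))
  seen <- character()
  for (k in seq_len(nrow(e))) {
    seen <- union(seen, c(e$u[k], e$v[k]))
    nodesAfter[k] <- length(seen)
  }
  # keep whole threshold classes: candidate thresholds are the distinct
  # absolute scores; pick the smallest one meeting the target
  classEnd <- which(!duplicated(e$absScore, fromLast = TRUE))
  okClasses <- classEnd[nodesAfter[classEnd] <= targetGenes]
  if (length(okClasses) == 0L) {
    warning("even the strongest edge class exceeds the target; ",
            "returning the top edge's endpoints")
    keep <- 1L
  } else {
    keep <- max(okClasses)
  }
  kept <- e[seq_len(keep), , drop = FALSE]
  threshold <- kept$absScore[keep]
  kept$absScore <- NULL
  rownames(kept) <- NULL
  net <- Interactome(edges = kept, taxon = taxon)
  list(network = net, threshold = threshold,
       nGenes = length(networkNodes(net)))
}

#' Write a scored-edge table as TSV
#'
#' @param scored Result of [linkScores()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeScoredEdgesTSV <- function(scored, path) {
  utils::write.table(scored, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
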