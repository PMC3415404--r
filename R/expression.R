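#' FoldChangeTable: per-gene condition ratios
#'
#' Result of replicate averaging and fold-change computation between two
#' conditions. Ratios are linear-scale numerator/denominator; genes whose
#' denominator mean is zero are excluded and listed.
#'
#' @slot table `data.frame` with columns `gene`, `numMean`, `denMean`,
#'   `ratio`.
#' @slot numerator,denominator Condition labels.
#' @slot excluded Genes dropped because of a zero denominator mean.
#' @export
setClass("FoldChangeTable",
         representation(table = "data.frame",
                        numerator = "character",
                        denominator = "character",
                        excluded = "character"))

setValidity("FoldChangeTable", function(object) {
  t <- object@table
  if (!all(c("gene", "ratio") %in% names(t)))
    return("table needs columns 'gene' and 'ratio'")
  if (nrow(t) > 0 && any(!is.finite(t$ratio) | t$ratio <= 0))
    return("ratios must be finite and positive")
  if (anyDuplicated(t$gene)) return("duplicate genes")
  TRUE
})

setMethod("show", "FoldChangeTable", function(object) {
  cat("FoldChangeTable:", object@numerator, "/", object@denominator, "\n")
  cat("  genes:", nrow(object@table),
      " excluded:", length(object@excluded), "\n")
  invisible(NULL)
})

#' @describeIn FoldChangeTable Per-gene ratio table.
#' @param x A `FoldChangeTable`.
#' @export
foldChanges <- function(x) {
  stopifnot(is(x, "FoldChangeTable"))
  x@table
}

#' @describeIn FoldChangeTable Named vector of ratios.
#' @export
ratioVector <- function(x) {
  stopifnot(is(x, "FoldChangeTable"))
  stats::setNames(x@table$ratio, x@table$gene)
}

#' Read an expression matrix plus sample sheet into a SummarizedExperiment
#'
#' The expression TSV has gene ids in the first column and sample ids in the
#' header; the sample sheet is a TSV with columns `sample`, `condition`,
#' `replicate`. GEO series-matrix exports work after stripping their `!`
#' metadata lines (`seriesMatrix = TRUE` does this).
#'
#' @param exprPath Path to the genes x samples TSV.
#' @param samplesPath Path to the sample sheet TSV.
#' @param seriesMatrix Skip `!`-prefixed metadata lines and the
#'   series-matrix table delimiters before parsing.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `intensity` and colData columns `condition`, `replicate`.
#' @export
readExpressionTSV <- function(exprPath, samplesPath, seriesMatrix = FALSE) {
  if (seriesMatrix) {
    lines <- readLines(exprPath)
    lines <- lines[!startsWith(lines, "!")]
    lines <- lines[nzchar(lines)]
    tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                             stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    tab <- utils::read.delim(exprPath, stringsAsFactors = FALSE,
                             check.names = FALSE)
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  storage.mode(mat) <- "double"
  samples <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!all(colnames(mat) %in% samples$sample))
    stop("samples missing from the sample sheet: ",
         paste(setdiff(colnames(mat), samples$sample), collapse = ", "))
  samples <- samples[match(colnames(mat), samples$sample), ]
  makeExpressionSE(mat, samples$condition, samples$replicate)
}

#' Build an expression SummarizedExperiment from a matrix
#'
#' @param mat Non-negative genes x samples matrix with rownames.
#' @param condition,replicate Per-sample labels.
#' @return A `SummarizedExperiment`.
#' @export
makeExpressionSE <- function(mat, condition, replicate) {
  if (any(mat < 0)) stop("intensities must be non-negative")
  if (length(condition) != ncol(mat) || length(replicate) != ncol(mat))
    stop("condition/replicate labels must match the number of samples")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.character(replicate),
                                   row.names = colnames(mat)))
}

#' Per-gene fold changes between two conditions
#'
#' Replicates of each condition are averaged per gene (arithmetic mean by
#' default, geometric by option) and the ratio numerator/denominator is
#' returned. Genes whose denominator mean is zero are excluded and listed in
#' the `excluded` slot.
#'
#' @param se Expression `SummarizedExperiment`
#'   (see [makeExpressionSE()]).
#' @param numerator,denominator Condition labels.
#' @param aggregate `"mean"` (default) or `"geometric"`.
#' @return A [FoldChangeTable-class].
#' @export
conditionFoldChanges <- function(se, numerator, denominator,
                                 aggregate = c("mean", "geometric")) {
  aggregate <- match.arg(aggregate)
  cond <- SummarizedExperiment::colData(se)$condition
  for (lab in c(numerator, denominator))
    if (!lab %in% cond) stop("unknown condition label: ", lab)
  mat <- SummarizedExperiment::assay(se, "intensity")
  avg <- function(m) {
    if (aggregate == "mean") rowMeans(m)
    else exp(rowMeans(log(pmax(m, .Machine$double.xmin))))
  }
  numMean <- avg(mat[, cond == numerator, drop = FALSE])
  denMean <- avg(mat[, cond == denominator, drop = FALSE])
  ok <- denMean > 0 & numMean > 0
  tab <- data.frame(gene = rownames(mat)[ok],
                    numMean = unname(numMean[ok]),
                    denMean = unname(denMean[ok]),
                    ratio = unname(numMean[ok] / denMean[ok]),
                    stringsAsFactors = FALSE)
  new("FoldChangeTable", table = tab,
      numerator = numerator, denominator = denominator,
      excluded = rownames(mat)[!ok])
}

#' Call differential expression by a fold-change cut-off
#'
#' Two-fold rule of the pipeline: up if ratio >= tau, down if
#' ratio <= 1/tau, both boundary-inclusive by default (`strict = TRUE`
#' switches to strict inequalities). Up and down partition the DE set.
#'
#' @param fc A [FoldChangeTable-class].
#' @param tau Fold-change threshold > 1 (default 2).
#' @param strict Use strict inequalities at the boundary.
#' @return List with `up`, `down` (character vectors), and `summary`
#'   (`data.frame` of counts and percentages over probed genes).
#' @export
callDE <- function(fc, tau = 2, strict = FALSE) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 1)
    stop("'tau' must be a single number > 1")
  t <- foldChanges(fc)
  up <- if (strict) t$gene[t$ratio > tau] else t$gene[t$ratio >= tau]
  down <- if (strict) t$gene[t$ratio < 1 / tau]
          else t$gene[t$ratio <= 1 / tau]
  n <- nrow(t)
  summary <- data.frame(
    probed = n, up = length(up), down = length(down),
    de = length(up) + length(down),
    upPct = 100 * length(up) / n, downPct = 100 * length(down) / n,
    dePct = 100 * (length(up) + length(down)) / n)
  list(up = up, down = down, summary = summary)
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Exact upper-tail probability of observing at least the given overlap when
#' `|setA|` genes are drawn from the universe containing `|setB|` marked
#' genes. Set members outside the universe are clipped and reported; the
#' statistic is symmetric in the two sets.
#'
#' @param setA,setB Character vectors of gene ids.
#' @param universe Character vector defining the population.
#' @return List with `overlap`, `nA`, `nB`, `nUniverse`, `pValue`,
#'   `clipped` (genes removed as outside the universe).
#' @export
overlapEnrichment <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  clipped <- c(setdiff(a, universe), setdiff(b, universe))
  a <- intersect(a, universe); b <- intersect(b, universe)
  ov <- length(intersect(a, b))
  list(overlap = ov, nA = length(a), nB = length(b),
       nUniverse = length(universe),
       pValue = pHyperTail(ov, length(a), length(b), length(universe)),
       clipped = unique(clipped))
}

#' Expression shift of a gene set
#'
#' Mean fold-change ratio of a gene set (optionally expanded by all network
#' interaction partners of its members) and a one-sided (greater)
#' Mann-Whitney test of the set's ratios against all other genes' ratios.
#'
#' @param fc A [FoldChangeTable-class].
#' @param geneSet Character vector of gene ids.
#' @param includeNeighbors Expand the set with its direct interaction
#'   partners before testing.
#' @param net An [Interactome-class], required when
#'   `includeNeighbors = TRUE`.
#' @return List with `meanRatio`, `test` (an `htest`), `nSet`, `setGenes`,
#'   `droppedFromSet` (set genes absent from the fold-change table).
#' @export
setShiftTest <- function(fc, geneSet, includeNeighbors = FALSE, net = NULL) {
  geneSet <- unique(as.character(geneSet))
  if (includeNeighbors) {
    if (is.null(net)) stop("'net' is required when includeNeighbors = TRUE")
    g <- asIgraph(net)
    present <- intersect(geneSet, igraph::V(g)$name)
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                               function(vs) vs$name)))
    geneSet <- union(geneSet, nb)
  }
  ratios <- ratioVector(fc)
  inSet <- intersect(geneSet, names(ratios))
  dropped <- setdiff(geneSet, names(ratios))
  if (length(inSet) == 0L)
    stop("no gene of the set has a fold-change value")
  setR <- ratios[inSet]
  bgR <- ratios[setdiff(names(ratios), inSet)]
  test <- if (length(bgR) > 0)
    mannWhitneyTest(setR, bgR, alternative = "greater")
  else NULL
  list(meanRatio = mean(setR), test = test, nSet = length(inSet),
       setGenes = inSet, droppedFromSet = dropped)
}
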