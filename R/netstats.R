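#' Compare the degree of a gene set against the rest of the interactome
#'
#' Tests whether set members have a higher average number of interactions
#' than other genes, using a one-sided (greater) Mann-Whitney U test on the
#' two degree lists. Degrees count merged edges. By default the background is
#' all non-set nodes; `background = "all"` compares against the literal
#' interactome-wide degree list including the set itself.
#'
#' @param net An [Interactome-class].
#' @param geneSet Character vector of gene ids.
#' @param background `"exclude"` (default) or `"all"`.
#' @return List with `setMeanDegree`, `backgroundMeanDegree`, `pValue`,
#'   `nSet`, `missing` (set genes absent from the network).
#' @export
degreeCompare <- function(net, geneSet, background = c("exclude", "all")) {
  background <- match.arg(background)
  geneSet <- unique(as.character(geneSet))
  deg <- nodeDegrees(net)
  present <- intersect(geneSet, names(deg))
  missing <- setdiff(geneSet, names(deg))
  if (length(present) == 0L)
    stop("no gene of the set is in the network; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  setDeg <- deg[present]
  bgDeg <- if (background == "exclude") deg[setdiff(names(deg), present)]
           else deg
  if (length(bgDeg) == 0L)
    stop("background is empty: the set covers every node")
  test <- mannWhitneyTest(setDeg, bgDeg, alternative = "greater")
  list(setMeanDegree = mean(setDeg),
       backgroundMeanDegree = mean(bgDeg),
       pValue = test$p.value,
       nSet = length(present),
       missing = missing)
}

#' Degree distribution and log-log slope
#'
#' Bins node degrees into a histogram of counts and fits, by simple least
#' squares, the slope of `log(count)` on `log(degree)` over nonzero-degree,
#' nonzero-count bins. A slope near -2 to -3 is the signature of the
#' approximate power-law degree distribution typical of interactomes.
#'
#' @param net An [Interactome-class].
#' @return List with `histogram` (`data.frame` of degree, count) and `slope`.
#' @export
degreeSlope <- function(net) {
  deg <- nodeDegrees(net)
  deg <- deg[deg > 0]
  tab <- table(deg)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  if (nrow(hist) < 3L)
    stop("undefined slope: fewer than 3 distinct nonzero degrees")
  fit <- stats::lm(log(count) ~ log(degree), data = hist)
  list(histogram = hist, slope = unname(stats::coef(fit)[2]))
}

#' Specificity of interconnectivity of a gene set
#'
#' For each set member present in the network with degree >= 1, the
#' percentage of its interactions that land on other set members
#' (100 x edges-to-set / all edges), plus the mean over members. Zero-degree
#' members are reported and excluded from the mean.
#'
#' @param net An [Interactome-class].
#' @param geneSet Character vector of gene ids.
#' @return List with `perGene` (`data.frame` of gene, degree, setDegree,
#'   specificityPct), `meanSpecificityPct`, `zeroDegree`, `missing`.
#' @export
interconnectivity <- function(net, geneSet) {
  geneSet <- unique(as.character(geneSet))
  g <- asIgraph(net)
  nodes <- igraph::V(g)$name
  present <- intersect(geneSet, nodes)
  missing <- setdiff(geneSet, nodes)
  deg <- igraph::degree(g, mode = "all")
  setDeg <- .setDegree(net, present)
  info <- data.frame(gene = present,
                     degree = unname(deg[present]),
                     setDegree = unname(setDeg[present]),
                     stringsAsFactors = FALSE)
  zero <- info$gene[info$degree == 0]
  info <- info[info$degree > 0, , drop = FALSE]
  if (nrow(info) == 0L)
    stop("no set member has degree >= 1")
  info$specificityPct <- 100 * info$setDegree / info$degree
  rownames(info) <- NULL
  list(perGene = info,
       meanSpecificityPct = mean(info$specificityPct),
       zeroDegree = zero,
       missing = missing)
}

# per-node count of merged edges whose other endpoint is in 'members'
# (for directed networks both orientations count, matching total degree)
.setDegree <- function(net, members) {
  e <- networkEdges(net)
  nodes <- networkNodes(net)
  out <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(e) == 0L) return(out)
  uIn <- e$u %in% members
  vIn <- e$v %in% members
  tu <- tapply(as.integer(vIn), e$u, sum)
  tv <- tapply(as.integer(uIn), e$v, sum)
  out[names(tu)] <- out[names(tu)] + tu
  out[names(tv)] <- out[names(tv)] + tv
  out
}

#' Per-gene degree/specificity table as TSV
#'
#' @param net An [Interactome-class].
#' @param geneSet Character vector of gene ids.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeSpecificityTSV <- function(net, geneSet, path) {
  res <- interconnectivity(net, geneSet)
  utils::write.table(res$perGene, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
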