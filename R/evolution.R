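#' Ortholog-presence enrichment of a gene set
#'
#' For each target species, computes the percentage of set genes with at
#' least one protein-coding ortholog and the genome-wide percentage; both are
#' averaged over all pairwise species comparisons and the enrichment is
#' scored on the averaged comparison with an exact Poisson upper tail:
#' observed = averaged count of set genes with orthologs (rounded to the
#' nearest integer), `lambda` = averaged genome fraction x set size. The
#' upper tail tests the enrichment direction (set more conserved than
#' expected); `lowerTail = TRUE` tests depletion instead.
#'
#' @param geneSet Character vector of genes of the seed species.
#' @param orthology `data.frame` with columns `gene` and `species`, one row
#'   per (gene, target species) pair in which the gene has >= 1 ortholog.
#'   Genes must be from the seed species; `species` values are the targets.
#' @param genomeGenes Character vector of all (protein-coding) genes of the
#'   seed species, defining the genome-wide rate.
#' @param speciesList Target species to compare against (default: all species
#'   appearing in `orthology`).
#' @param lowerTail Test depletion rather than enrichment.
#' @return List with `perSpecies` (`data.frame` of species, setPct,
#'   genomePct), `setPctAvg`, `genomePctAvg`, `poissonP`.
#' @export
orthologPresenceEnrichment <- function(geneSet, orthology, genomeGenes,
                                       speciesList = NULL,
                                       lowerTail = FALSE) {
  geneSet <- unique(as.character(geneSet))
  if (length(geneSet) == 0L) stop("'geneSet' must be non-empty")
  if (!all(c("gene", "species") %in% names(orthology)))
    stop("orthology table needs columns 'gene' and 'species'")
  genomeGenes <- unique(as.character(genomeGenes))
  if (is.null(speciesList)) speciesList <- unique(orthology$species)
  if (length(speciesList) == 0L) stop("no target species to compare against")
  per <- lapply(speciesList, function(sp) {
    with_orth <- unique(orthology$gene[orthology$species == sp])
    data.frame(species = sp,
               setPct = 100 * mean(geneSet %in% with_orth),
               genomePct = 100 * mean(genomeGenes %in% with_orth),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  setPctAvg <- mean(per$setPct)
  genomePctAvg <- mean(per$genomePct)
  observed <- round(setPctAvg / 100 * length(geneSet))
  lambda <- genomePctAvg / 100 * length(geneSet)
  p <- if (lowerTail) stats::ppois(observed, lambda)
       else pPoisTail(observed, lambda)
  list(perSpecies = per, setPctAvg = setPctAvg, genomePctAvg = genomePctAvg,
       poissonP = p)
}

#' Compare substitution rates of a gene set against a background
#'
#' Mann-Whitney comparison (default two-sided; pass `alternative = "less"`
#' for the directional claim that the set evolves more slowly) plus
#' arithmetic group means. Run it separately for dN, dS and dN/dS. The
#' caller applies the ancient-gene filter first (see [ancientGenes()]), so
#' the comparison is between equally old genes.
#'
#' @param setValues,backgroundValues Non-empty numeric vectors of rates.
#' @param alternative Passed to [mannWhitneyTest()].
#' @return List with `test` (an `htest`), `setMean`, `backgroundMean`.
#' @export
dndsCompare <- function(setValues, backgroundValues,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(setValues) == 0L || length(backgroundValues) == 0L)
    stop("both value lists must be non-empty")
  list(test = mannWhitneyTest(setValues, backgroundValues,
                              alternative = alternative),
       setMean = mean(setValues),
       backgroundMean = mean(backgroundValues))
}

#' Ancient-gene filter for substitution-rate comparisons
#'
#' Restricts a gene universe to genes that also have orthologs in at least
#' one of the named distant species, so that a conserved set is compared
#' against equally ancient background genes rather than against young genes.
#'
#' @param genes Character vector of candidate genes.
#' @param orthology Presence table as in [orthologPresenceEnrichment()].
#' @param ancientSpecies Species whose orthologs define "ancient".
#' @return The subset of `genes` with >= 1 ortholog in any ancient species.
#' @export
ancientGenes <- function(genes, orthology, ancientSpecies) {
  anc <- unique(orthology$gene[orthology$species %in% ancientSpecies])
  intersect(as.character(genes), anc)
}

#' Correlations and multiple regression of degree, orthology and dN/dS
#'
#' Works on a per-gene table of interactome degree, number of species with
#' orthologs and mean dN/dS. Genes with degree zero or missing/non-positive
#' dN/dS are removed so the data can be log-transformed (natural log for
#' degree and dN/dS; species counts stay linear). Reports the pairwise
#' Pearson correlations, a least-squares fit of each variable on the other
#' two, and - for a gene set of interest - the observed mean of each variable
#' next to the mean predicted from the other two (predictions on the log
#' scale are back-transformed by plain exponentiation).
#'
#' @param table `data.frame` with columns `gene`, `degree`, `nSpecies`,
#'   `dnds`.
#' @param geneSet Character vector of genes to contrast with the model.
#' @param minRows Minimum rows required after filtering (default 10).
#' @return List with `correlations` (3x3 matrix over logDegree, nSpecies,
#'   logDnds), `fits` (named list of `lm` objects), `setMeans`
#'   (`data.frame` of variable, observed, predicted), `nUsed`.
#' @export
conservationRegression <- function(table, geneSet = character(),
                                   minRows = 10L) {
  need <- c("gene", "degree", "nSpecies", "dnds")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  keep <- !is.na(table$degree) & table$degree > 0 &
          !is.na(table$dnds) & table$dnds > 0 & !is.na(table$nSpecies)
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) < minRows)
    stop("only ", nrow(tab), " usable rows after filtering (need >= ",
         minRows, ")")
  d <- data.frame(gene = tab$gene,
                  logDegree = log(tab$degree),
                  nSpecies = tab$nSpecies,
                  logDnds = log(tab$dnds),
                  stringsAsFactors = FALSE)
  vars <- c("logDegree", "nSpecies", "logDnds")
  correlations <- stats::cor(d[vars], method = "pearson")
  fits <- list(
    logDegree = stats::lm(logDegree ~ nSpecies + logDnds, data = d),
    nSpecies = stats::lm(nSpecies ~ logDegree + logDnds, data = d),
    logDnds = stats::lm(logDnds ~ logDegree + nSpecies, data = d))
  setMeans <- NULL
  inSet <- d$gene %in% geneSet
  if (any(inSet)) {
    sub <- d[inSet, , drop = FALSE]
    pred <- vapply(vars, function(v)
      mean(stats::predict(fits[[v]], newdata = sub)), 1.0)
    obs <- vapply(vars, function(v) mean(sub[[v]]), 1.0)
    # back-transform the logged variables to natural units
    backNames <- c(logDegree = "degree", nSpecies = "nSpecies",
                   logDnds = "dnds")
    back <- function(v, x) if (v == "nSpecies") x else exp(x)
    setMeans <- data.frame(
      variable = unname(backNames[vars]),
      observed = vapply(vars, function(v) back(v, obs[[v]]), 1.0),
      predicted = vapply(vars, function(v) back(v, pred[[v]]), 1.0),
      stringsAsFactors = FALSE)
    rownames(setMeans) <- NULL
  }
  list(correlations = correlations, fits = fits, setMeans = setMeans,
       nUsed = nrow(d))
}

#' Read an orthology/dN-dS table from TSV
#'
#' Flexible reader for the two table layouts used in this package: presence
#' tables (`gene`, `species`) and pairwise rate tables (`gene`, `dn`, `ds`,
#' `dnds`). When `dn`/`ds` are present but `dnds` is absent it is derived as
#' `dn/ds`; a stored `dnds` column always wins over recomputation.
#'
#' @param path Path to the TSV (header required).
#' @return `data.frame`.
#' @export
readOrthologyTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("dn", "ds") %in% names(tab)) && !("dnds" %in% names(tab)))
    tab$dnds <- ifelse(tab$ds > 0, tab$dn / tab$ds, NA_real_)
  tab
}
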