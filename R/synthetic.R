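# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. All
#' generators are pure functions of this configuration: the same config gives
#' byte-identical output. Defaults encode the study conditions the package is
#' validated under: a 500-gene scale-free interactome (3 edges per new node)
#' with a planted 25-gene seed module interconnected at probability 0.4; a
#' two-condition expression design (2 replicates) with a 10% DE fraction at
#' 4-fold effect and log-normal replicate noise of 0.2 (log2 scale); five
#' target species with ortholog presence 0.9 for module genes versus 0.5
#' genome-wide and log-normal dN/dS medians 0.08 (module) versus 0.15
#' (background); and 500-base promoters carrying a degenerate 10-mer motif
#' planted in 80% of a target set against a 5% background rate.
#'
#' @param rngSeed Integer seed driving all randomness.
#' @param nGenes Number of genes / network nodes.
#' @param edgesPerNode Preferential-attachment edges added per new node.
#' @param moduleSize Planted seed-module size.
#' @param intraModuleEdgeProb Probability of adding each absent intra-module
#'   edge.
#' @param deFraction Fraction of genes differentially expressed.
#' @param effectFold Fold-change of DE genes.
#' @param noiseSd Replicate noise standard deviation, log2 scale.
#' @param nReplicates Replicates per condition.
#' @param species Character vector of target species names.
#' @param baseOrthologRate,moduleOrthologRate Per-species ortholog presence
#'   probability for background / module genes.
#' @param dndsMedianModule,dndsMedianBackground Median dN/dS of module /
#'   background genes (log-normal).
#' @param dndsSdlog Log-scale spread of dN/dS.
#' @param promoterLength Promoter length in bases.
#' @param motif IUPAC motif to plant.
#' @param plantedFraction Fraction of the target set receiving the motif.
#' @param backgroundPlantRate Fraction of non-target genes receiving it.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(rngSeed = 1L,
                      nGenes = 500L,
                      edgesPerNode = 3L,
                      moduleSize = 25L,
                      intraModuleEdgeProb = 0.4,
                      deFraction = 0.1,
                      effectFold = 4,
                      noiseSd = 0.2,
                      nReplicates = 2L,
                      species = paste0("species", 1:5),
                      baseOrthologRate = 0.5,
                      moduleOrthologRate = 0.9,
                      dndsMedianModule = 0.08,
                      dndsMedianBackground = 0.15,
                      dndsSdlog = 0.6,
                      promoterLength = 500L,
                      motif = "YGNCACAAAW",
                      plantedFraction = 0.8,
                      backgroundPlantRate = 0.05) {
  probs <- c(intraModuleEdgeProb = intraModuleEdgeProb,
             deFraction = deFraction,
             baseOrthologRate = baseOrthologRate,
             moduleOrthologRate = moduleOrthologRate,
             plantedFraction = plantedFraction,
             backgroundPlantRate = backgroundPlantRate)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities outside [0, 1]: ", paste(bad, collapse = ", "))
  if (nGenes <= edgesPerNode || edgesPerNode < 1)
    stop("need nGenes > edgesPerNode >= 1")
  if (moduleSize > nGenes) stop("moduleSize exceeds nGenes")
  if (nReplicates < 1) stop("need at least one replicate")
  if (effectFold <= 1) stop("'effectFold' must exceed 1")
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
  motif <- checkIupac(motif)
  if (promoterLength < nchar(motif))
    stop("promoter shorter than the motif")
  cfg <- list(rngSeed = as.integer(rngSeed), nGenes = as.integer(nGenes),
              edgesPerNode = as.integer(edgesPerNode),
              moduleSize = as.integer(moduleSize),
              intraModuleEdgeProb = intraModuleEdgeProb,
              deFraction = deFraction, effectFold = effectFold,
              noiseSd = noiseSd, nReplicates = as.integer(nReplicates),
              species = species, baseOrthologRate = baseOrthologRate,
              moduleOrthologRate = moduleOrthologRate,
              dndsMedianModule = dndsMedianModule,
              dndsMedianBackground = dndsMedianBackground,
              dndsSdlog = dndsSdlog,
              promoterLength = as.integer(promoterLength),
              motif = motif, plantedFraction = plantedFraction,
              backgroundPlantRate = backgroundPlantRate)
  class(cfg) <- "SimConfig"
  cfg
}

.geneNames <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a scale-free interactome
#'
#' Preferential attachment (Barabasi-Albert): starting from `edgesPerNode`
#' isolated nodes, each new node attaches to `edgesPerNode` distinct existing
#' nodes with probability proportional to their current degree (the first
#' newcomer attaches to the initial nodes). The result has exactly
#' `edgesPerNode * (nGenes - edgesPerNode)` edges and an approximately
#' power-law degree distribution. Reproducible from the config seed.
#'
#' @param cfg A [simConfig()].
#' @return An [Interactome-class] with unit-evidence edge scores.
#' @export
genScaleFreeNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- cfg$nGenes; m <- cfg$edgesPerNode
  genes <- .geneNames(n)
  .withSeed(cfg$rngSeed, {
    us <- integer(0); vs <- integer(0)
    targets <- seq_len(m)
    repeated <- integer(0)
    for (source in seq.int(m + 1L, n)) {
      us <- c(us, rep.int(source, m)); vs <- c(vs, targets)
      repeated <- c(repeated, targets, rep.int(source, m))
      # m distinct degree-proportional picks, by rejection
      picked <- integer(0)
      while (length(picked) < m) {
        cand <- repeated[sample.int(length(repeated), 1L)]
        if (!cand %in% picked) picked <- c(picked, cand)
      }
      targets <- picked
    }
    edges <- data.frame(u = genes[pmin(us, vs)], v = genes[pmax(us, vs)],
                        score = 3L, nEvidence = 1L,
                        stringsAsFactors = FALSE)
    Interactome(edges = edges, nodes = genes)
  })
}

#' Plant a preferentially interconnected seed module
#'
#' Chooses `moduleSize` nodes uniformly and adds every absent intra-module
#' edge independently with probability `intraModuleEdgeProb`, emulating a
#' seed gene set that interacts with itself more than expected by chance.
#'
#' @param net An [Interactome-class].
#' @param cfg A [simConfig()].
#' @return List with `network` (augmented) and `module` (the planted seed
#'   truth, a character vector).
#' @export
plantSeedModule <- function(net, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  nodes <- networkNodes(net)
  if (cfg$moduleSize > length(nodes))
    stop("moduleSize exceeds the network's node count")
  .withSeed(cfg$rngSeed + 1L, {
    module <- sort(sample(nodes, cfg$moduleSize))
    e <- networkEdges(net)
    have <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
    pairs <- utils::combn(module, 2)
    pu <- pmin(pairs[1, ], pairs[2, ]); pv <- pmax(pairs[1, ], pairs[2, ])
    absent <- !(paste(pu, pv) %in% have)
    add <- absent & stats::runif(length(pu)) < cfg$intraModuleEdgeProb
    if (any(add)) {
      newE <- data.frame(u = pu[add], v = pv[add], score = 3L,
                         nEvidence = 1L, stringsAsFactors = FALSE)
      e <- rbind(e[, c("u", "v", "score", "nEvidence")], newE)
    }
    list(network = Interactome(edges = e, nodes = nodes,
                               taxon = taxonId(net)),
         module = module)
  })
}

#' Generate two-condition replicate expression profiles
#'
#' Baseline log2 intensities are Normal(9, 1) per gene; a `deFraction` of
#' genes (chosen uniformly, labeled up/down in equal numbers) is shifted by
#' +/- log2(effectFold) in the DR condition; each replicate adds
#' Normal(0, noiseSd) noise on the log2 scale; intensities are 2^x. The two
#' conditions are labeled `"DR"` (restricted) and `"AL"` (ad libitum
#' control), so the DR/AL fold change of an up gene centers on `effectFold`.
#'
#' @param genes Character vector of gene ids.
#' @param cfg A [simConfig()].
#' @return List with `se` (a `SummarizedExperiment`) and `truth`
#'   (`data.frame` of gene, status in up/down/none).
#' @export
genExpressionProfiles <- function(genes, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  nG <- length(genes); nR <- cfg$nReplicates
  .withSeed(cfg$rngSeed + 2L, {
    nDE <- round(cfg$deFraction * nG)
    de <- sample(genes, nDE)
    nUp <- floor(nDE / 2) + (nDE %% 2L) # up gets the odd one
    status <- stats::setNames(rep("none", nG), genes)
    status[de[seq_len(nUp)]] <- "up"
    if (nDE > nUp) status[de[(nUp + 1):nDE]] <- "down"
    base <- stats::rnorm(nG, mean = 9, sd = 1)
    shift <- ifelse(status == "up", log2(cfg$effectFold),
                    ifelse(status == "down", -log2(cfg$effectFold), 0))
    cols <- c(paste0("AL_r", seq_len(nR)), paste0("DR_r", seq_len(nR)))
    mat <- matrix(0, nG, 2 * nR, dimnames = list(genes, cols))
    for (r in seq_len(nR)) {
      mat[, r] <- base + stats::rnorm(nG, 0, cfg$noiseSd)
      mat[, nR + r] <- base + shift + stats::rnorm(nG, 0, cfg$noiseSd)
    }
    se <- makeExpressionSE(2^mat,
                           condition = rep(c("AL", "DR"), each = nR),
                           replicate = rep(seq_len(nR), 2))
    list(se = se,
         truth = data.frame(gene = genes, status = unname(status),
                            stringsAsFactors = FALSE))
  })
}

#' Generate ortholog presence and dN/dS profiles
#'
#' Per target species, each gene has an ortholog with probability
#' `moduleOrthologRate` if it belongs to the module and `baseOrthologRate`
#' otherwise. dN/dS values are log-normal with a lower median for the module
#' (conserved) group; dS is log-normal around 1 and dN is derived as
#' dN/dS x dS.
#'
#' @param genes Character vector of gene ids.
#' @param module Character vector: the conserved subset.
#' @param cfg A [simConfig()].
#' @return List with `presence` (`data.frame` of gene, species) and `rates`
#'   (`data.frame` of gene, inModule, dn, ds, dnds).
#' @export
genOrthologyProfiles <- function(genes, module, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  inMod <- genes %in% module
  .withSeed(cfg$rngSeed + 3L, {
    rate <- ifelse(inMod, cfg$moduleOrthologRate, cfg$baseOrthologRate)
    presence <- do.call(rbind, lapply(cfg$species, function(sp) {
      has <- stats::runif(length(genes)) < rate
      if (!any(has)) return(NULL)
      data.frame(gene = genes[has], species = sp, stringsAsFactors = FALSE)
    }))
    if (is.null(presence))
      presence <- data.frame(gene = character(), species = character(),
                             stringsAsFactors = FALSE)
    mu <- ifelse(inMod, log(cfg$dndsMedianModule),
                 log(cfg$dndsMedianBackground))
    dnds <- stats::rlnorm(length(genes), meanlog = mu,
                          sdlog = cfg$dndsSdlog)
    ds <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 0.3)
    rates <- data.frame(gene = genes, inModule = inMod,
                        dn = dnds * ds, ds = ds, dnds = dnds,
                        stringsAsFactors = FALSE)
    list(presence = presence, rates = rates)
  })
}

#' Generate promoter sequences with a planted motif
#'
#' Promoters are i.i.d. uniform ACGT sequences of `promoterLength` bases. A
#' `plantedFraction` of the target set (and a `backgroundPlantRate` fraction
#' of the remaining genes) gets one concrete expansion of the degenerate
#' motif written over a uniformly chosen window.
#'
#' @param genes Character vector of gene ids.
#' @param targetSet Genes eligible for planting at the target rate.
#' @param cfg A [simConfig()].
#' @return List with `promoters` (named `DNAStringSet`) and `planted`
#'   (character vector of genes that received the motif).
#' @export
genPromoters <- function(genes, targetSet, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  L <- cfg$promoterLength
  motifChars <- strsplit(cfg$motif, "")[[1]]
  mLen <- length(motifChars)
  if (L < mLen) stop("motif longer than promoter")
  .withSeed(cfg$rngSeed + 4L, {
    seqs <- vapply(genes, function(g)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
    inTarget <- genes %in% targetSet
    pPlant <- ifelse(inTarget, cfg$plantedFraction, cfg$backgroundPlantRate)
    plant <- stats::runif(length(genes)) < pPlant
    for (i in which(plant)) {
      concrete <- paste(vapply(motifChars, function(ch) {
        opts <- strsplit(.iupacCodes[[ch]], "")[[1]]
        opts[sample.int(length(opts), 1L)]
      }, ""), collapse = "")
      at <- sample.int(L - mLen + 1L, 1L)
      substr(seqs[i], at, at + mLen - 1L) <- concrete
    }
    list(promoters = Biostrings::DNAStringSet(seqs),
         planted = genes[plant])
  })
}

#' Write synthetic fixtures in standard formats
#'
#' `writeMitab` emits one PSI-MITAB 2.5-style line per edge (fixture
#' dialect: `fixture:` id namespace, two-hybrid detection, one synthetic
#' publication per edge); `writeExpressionTSV` emits the genes x samples
#' matrix plus a sample sheet; `writeOrthologyTSV` and `writeTruthTSV` write
#' plain tables. All outputs round-trip through the package readers.
#'
#' @param net An [Interactome-class].
#' @param path,exprPath,samplesPath Output paths.
#' @param taxon Taxon id to write (default 559292, budding yeast).
#' @return Invisibly, the (first) path.
#' @export
writeMitab <- function(net, path, taxon = 559292L) {
  e <- networkEdges(net)
  tx <- paste0("taxid:", taxon)
  lines <- vapply(seq_len(nrow(e)), function(i) {
    paste(c(paste0("fixture:", e$u[i]), paste0("fixture:", e$v[i]),
            "-", "-", "-", "-",
            "psi-mi:\"MI:0018\"(two hybrid)", "-",
            paste0("pubmed:", 10000 + i),
            tx, tx,
            "psi-mi:\"MI:0915\"(physical association)",
            "psi-mi:\"MI:0469\"(fixture)", "-", "-"),
          collapse = "\t")
  }, "")
  writeLines(c("#ID(A)\tID(B)\t...", lines), path)
  invisible(path)
}

#' @rdname writeMitab
#' @param se Expression `SummarizedExperiment`.
#' @export
writeExpressionTSV <- function(se, exprPath, samplesPath) {
  mat <- SummarizedExperiment::assay(se, "intensity")
  tab <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(tab, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- SummarizedExperiment::colData(se)
  sheet <- data.frame(sample = rownames(cd), condition = cd$condition,
                      replicate = cd$replicate)
  utils::write.table(sheet, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(exprPath)
}

#' @rdname writeMitab
#' @param table A `data.frame` (presence, rates or truth labels).
#' @export
writeOrthologyTSV <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMitab
#' @export
writeTruthTSV <- writeOrthologyTSV
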