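#' Derive a synthetic TF-to-target table from a network
#'
#' Picks the `nTfs` highest-degree nodes as transcription factors and assigns
#' each its direct neighbors as targets, emulating a regulatory-network
#' table keyed by factor.
#'
#' @param net An [Interactome-class].
#' @param nTfs Number of factors to derive (default 10).
#' @return `data.frame` with columns `tf`, `target`.
#' @export
genTfTargets <- function(net, nTfs = 10L) {
  deg <- sort(nodeDegrees(net), decreasing = TRUE)
  tfs <- names(deg)[seq_len(min(nTfs, length(deg)))]
  g <- asIgraph(net)
  do.call(rbind, lapply(tfs, function(tf) {
    nb <- igraph::neighbors(g, tf)$name
    data.frame(tf = tf, target = nb, stringsAsFactors = FALSE)
  }))
}

.pipelineStages <- c("simulate", "build-net", "netstats", "gba", "loo",
                     "expression", "evolution", "motif", "tf-spec",
                     "condense", "combine-p", "report")

#' Run the analysis pipeline from a single configuration
#'
#' Orchestrates the package's stages in dependency order from one structured
#' configuration (a YAML file or an equivalent nested list): synthetic-data
#' generation, network building, degree statistics, guilt-by-association
#' ranking and leave-one-out validation, expression fold changes and DE
#' calling, conservation statistics, motif and TF-specificity enrichment,
#' expression-weighted condensation, and p-value combination. Each stage
#' writes TSV/GraphML outputs into `outDir`; a machine-readable run report
#' (package version, seed, parameters, per-stage row counts) is written as
#' `run_report.json` and a log as `run.log`. All randomness flows from the
#' configured seed. Validation (stage names, required paths) happens before
#' any stage executes; `dryRun = TRUE` returns the execution plan without
#' touching outputs.
#'
#' Config keys: `outDir`, `seed`, `stages` (subset of
#' simulate, build-net, netstats, gba, loo, expression, evolution, motif,
#' tf-spec, condense, combine-p, report), plus one optional block per stage
#' with its file paths and parameters (`alpha`, `tau`, `targetGenes`, ...).
#' Stages after `simulate` default their inputs to the simulate outputs in
#' `outDir`.
#'
#' @param config Path to a YAML file, or a named list.
#' @param outDir Output directory (overrides the config's `outDir`).
#' @param dryRun List the plan without executing.
#' @param quiet Suppress console logging.
#' @return The run report (named list), invisibly unless `dryRun`.
#' @export
runPipeline <- function(config, outDir = NULL, dryRun = FALSE,
                        quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (!is.null(outDir)) config$outDir <- outDir
  if (is.null(config$outDir)) stop("config needs an 'outDir'")
  stages <- config$stages
  if (is.null(stages)) stop("config needs a 'stages' list")
  unknown <- setdiff(stages, .pipelineStages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; valid stages: ", paste(.pipelineStages, collapse = ", "))
  stages <- .pipelineStages[.pipelineStages %in% stages]
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  od <- config$outDir
  pathOf <- function(stage, key, default) {
    v <- config[[stage]][[key]]
    if (!is.null(v)) v else file.path(od, default)
  }
  paramOf <- function(stage, key, default) {
    v <- config[[stage]][[key]]
    if (!is.null(v)) v else default
  }

  # ---- validate required inputs before executing anything ----
  simulated <- "simulate" %in% stages
  needs <- list(
    "build-net" = c(mitab = "interactions.mitab"),
    "netstats" = c(network = "network.graphml", seeds = "seeds.tsv"),
    "gba" = c(network = "network.graphml", seeds = "seeds.tsv"),
    "loo" = c(network = "network.graphml", seeds = "seeds.tsv"),
    "expression" = c(expression = "expression.tsv",
                     samples = "samples.tsv"),
    "evolution" = c(presence = "orthology_presence.tsv",
                    rates = "dnds_rates.tsv", seeds = "seeds.tsv"),
    "motif" = c(promoters = "promoters.fasta", seeds = "seeds.tsv"),
    "tf-spec" = c(tfTargets = "tf_targets.tsv",
                  network = "network.graphml"),
    "condense" = c(network = "network.graphml",
                   expression = "expression.tsv",
                   samples = "samples.tsv"),
    "combine-p" = c(pvalues = "pvalues.tsv"))
  plan <- list()
  for (st in stages) {
    req <- needs[[st]]
    files <- if (length(req))
      stats::setNames(vapply(names(req), function(k)
        pathOf(st, k, req[[k]]), ""), names(req))
    else character()
    plan[[st]] <- list(stage = st, inputs = files)
    if (!simulated && length(files)) {
      miss <- files[!file.exists(files)]
      if (length(miss))
        stop("stage '", st, "': missing input file(s): ",
             paste(miss, collapse = ", "))
    }
  }
  if (dryRun) return(plan)

  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(od, "run.log")
  cat("", file = logPath)
  logmsg <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = logPath, append = TRUE)
    if (!quiet) message(line)
  }
  report <- list(package = "netGBA",
                 version = as.character(utils::packageVersion("netGBA")),
                 seed = seed, stages = stages, counts = list(),
                 parameters = config[intersect(names(config),
                                               .pipelineStages)])
  wtsv <- function(x, name) {
    utils::write.table(x, file.path(od, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  for (st in stages) {
    logmsg("[stage] ", st)
    inp <- plan[[st]]$inputs
    if (st == "simulate") {
      ov <- config$simulate
      ov <- ov[intersect(names(ov), names(formals(simConfig)))]
      cfg <- do.call(simConfig, c(list(rngSeed = seed), ov))
      net0 <- genScaleFreeNetwork(cfg)
      planted <- plantSeedModule(net0, cfg)
      net <- planted$network
      writeGraphML(net, file.path(od, "network.graphml"))
      writeMitab(net, file.path(od, "interactions.mitab"))
      writeLines(planted$module, file.path(od, "seeds.tsv"))
      expr <- genExpressionProfiles(networkNodes(net), cfg)
      writeExpressionTSV(expr$se, file.path(od, "expression.tsv"),
                         file.path(od, "samples.tsv"))
      writeTruthTSV(expr$truth, file.path(od, "expression_truth.tsv"))
      orth <- genOrthologyProfiles(networkNodes(net), planted$module, cfg)
      writeOrthologyTSV(orth$presence,
                        file.path(od, "orthology_presence.tsv"))
      writeOrthologyTSV(orth$rates, file.path(od, "dnds_rates.tsv"))
      prom <- genPromoters(networkNodes(net), planted$module, cfg)
      Biostrings::writeXStringSet(
        stats::setNames(prom$promoters, networkNodes(net)),
        file.path(od, "promoters.fasta"))
      wtsv(genTfTargets(net), "tf_targets.tsv")
      report$counts$simulate <- list(nodes = length(networkNodes(net)),
                                     edges = nrow(networkEdges(net)),
                                     seeds = length(planted$module))
    } else if (st == "build-net") {
      rec <- readMitab(inp[["mitab"]])
      net <- mergeInteractions(rec, directed = paramOf(st, "directed",
                                                       FALSE))
      writeGraphML(net, file.path(od, "network.graphml"))
      writeSIF(net, file.path(od, "network.sif"))
      report$counts[["build-net"]] <-
        list(records = nrow(rec), edges = nrow(networkEdges(net)),
             droppedCrossSpecies = attr(rec, "droppedCrossSpecies"))
    } else if (st == "netstats") {
      net <- readGraphML(inp[["network"]])
      seeds <- readLines(inp[["seeds"]])
      dc <- degreeCompare(net, seeds)
      ic <- interconnectivity(net, seeds)
      sl <- degreeSlope(net)
      wtsv(ic$perGene, "specificity.tsv")
      wtsv(sl$histogram, "degree_histogram.tsv")
      report$counts$netstats <- list(setMeanDegree = dc$setMeanDegree,
                                     backgroundMeanDegree =
                                       dc$backgroundMeanDegree,
                                     degreeP = dc$pValue,
                                     meanSpecificityPct =
                                       ic$meanSpecificityPct,
                                     slope = sl$slope)
    } else if (st == "gba") {
      net <- readGraphML(inp[["network"]])
      seeds <- readLines(inp[["seeds"]])
      rk <- gbaRank(net, seeds, alpha = paramOf(st, "alpha", 0.05))
      wtsv(rk, "gba_ranking.tsv")
      report$counts$gba <- list(scored = nrow(rk),
                                significant = sum(rk$significant),
                                candidates = nrow(gbaCandidates(rk)))
    } else if (st == "loo") {
      net <- readGraphML(inp[["network"]])
      seeds <- readLines(inp[["seeds"]])
      lr <- looRecovery(net, seeds, alpha = paramOf(st, "alpha", 0.05))
      wtsv(lr$perSeed, "loo_report.tsv")
      report$counts$loo <- list(tested = lr$nTested,
                                recoveryRatePct = lr$recoveryRatePct)
    } else if (st == "expression") {
      se <- readExpressionTSV(inp[["expression"]], inp[["samples"]])
      fc <- conditionFoldChanges(se, paramOf(st, "numerator", "DR"),
                                 paramOf(st, "denominator", "AL"))
      de <- callDE(fc, tau = paramOf(st, "tau", 2))
      wtsv(foldChanges(fc), "fold_changes.tsv")
      writeLines(de$up, file.path(od, "de_up.tsv"))
      writeLines(de$down, file.path(od, "de_down.tsv"))
      report$counts$expression <- as.list(de$summary)
    } else if (st == "evolution") {
      presence <- readOrthologyTSV(inp[["presence"]])
      rates <- readOrthologyTSV(inp[["rates"]])
      seeds <- readLines(inp[["seeds"]])
      enr <- orthologPresenceEnrichment(seeds, presence, rates$gene)
      inSet <- rates$gene %in% seeds
      cmp <- dndsCompare(rates$dnds[inSet], rates$dnds[!inSet])
      wtsv(enr$perSpecies, "ortholog_presence.tsv")
      report$counts$evolution <- list(setPctAvg = enr$setPctAvg,
                                      genomePctAvg = enr$genomePctAvg,
                                      poissonP = enr$poissonP,
                                      dndsP = cmp$test$p.value,
                                      dndsSetMean = cmp$setMean,
                                      dndsBackgroundMean =
                                        cmp$backgroundMean)
    } else if (st == "motif") {
      prom <- readPromoterFasta(inp[["promoters"]])
      target <- readLines(inp[["seeds"]])
      motifs <- if (!is.null(config$motif$collection))
        readMotifTSV(config$motif$collection)
      else data.frame(name = paramOf(st, "pattern", "YGNCACAAAW"),
                      pattern = paramOf(st, "pattern", "YGNCACAAAW"),
                      stringsAsFactors = FALSE)
      me <- motifEnrichment(motifs, target, prom)
      wtsv(me, "motif_enrichment.tsv")
      report$counts$motif <- list(motifs = nrow(me),
                                  minQ = min(me$qValue))
    } else if (st == "tf-spec") {
      tt <- readTfTargetsTSV(inp[["tfTargets"]])
      net <- readGraphML(inp[["network"]])
      de <- readLines(pathOf(st, "deSet", "de_up.tsv"))
      rk <- tfSpecificityRank(tt, de, networkNodes(net))
      wtsv(rk, "tf_specificity.tsv")
      report$counts[["tf-spec"]] <- list(tfs = nrow(rk))
    } else if (st == "condense") {
      net <- readGraphML(inp[["network"]])
      se <- readExpressionTSV(inp[["expression"]], inp[["samples"]])
      fc <- conditionFoldChanges(se, paramOf(st, "numerator", "DR"),
                                 paramOf(st, "denominator", "AL"))
      sc <- linkScores(net, fc)
      writeScoredEdgesTSV(sc, file.path(od, "link_scores.tsv"))
      tg <- paramOf(st, "targetGenes", 1000L)
      for (side in c("startup", "shutdown")) {
        cd <- condenseToTarget(sc, targetGenes = tg, side = side)
        writeGraphML(cd$network,
                     file.path(od, paste0(side, ".graphml")))
        report$counts[[paste0("condense_", side)]] <-
          list(nGenes = cd$nGenes, threshold = cd$threshold)
      }
    } else if (st == "combine-p") {
      tab <- utils::read.delim(inp[["pvalues"]], stringsAsFactors = FALSE)
      ps <- as.matrix(tab[, -1, drop = FALSE])
      comb <- data.frame(
        term = tab[[1]],
        analyticP = apply(ps, 1, function(r)
          combinePAnalytic(r[!is.na(r)])),
        zMethodP = apply(ps, 1, function(r) combinePZ(r[!is.na(r)])))
      wtsv(comb, "combined_pvalues.tsv")
      report$counts[["combine-p"]] <- list(terms = nrow(comb))
    }
  }
  jsonlite::write_json(report, file.path(od, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("[done] report written to ", file.path(od, "run_report.json"))
  invisible(report)
}
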