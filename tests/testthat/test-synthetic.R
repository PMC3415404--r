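test_that("simConfig validates its fields", {
  expect_error(simConfig(intraModuleEdgeProb = 1.2), "probabilities")
  expect_error(simConfig(nGenes = 3, edgesPerNode = 3), "nGenes")
  expect_error(simConfig(moduleSize = 600, nGenes = 500), "moduleSize")
  expect_error(simConfig(motif = "XYZ"), "IUPAC")
  expect_error(simConfig(promoterLength = 5), "shorter")
})

test_that("generators are pure functions of the config", {
  cfg <- simConfig(rngSeed = 7, nGenes = 100, edgesPerNode = 2,
                   moduleSize = 10)
  n1 <- genScaleFreeNetwork(cfg); n2 <- genScaleFreeNetwork(cfg)
  expect_identical(networkEdges(n1), networkEdges(n2))
  p1 <- plantSeedModule(n1, cfg); p2 <- plantSeedModule(n2, cfg)
  expect_identical(p1$module, p2$module)
  expect_identical(networkEdges(p1$network), networkEdges(p2$network))
  genes <- networkNodes(n1)
  e1 <- genExpressionProfiles(genes, cfg)
  e2 <- genExpressionProfiles(genes, cfg)
  expect_identical(SummarizedExperiment::assay(e1$se),
                   SummarizedExperiment::assay(e2$se))
  o1 <- genOrthologyProfiles(genes, p1$module, cfg)
  o2 <- genOrthologyProfiles(genes, p1$module, cfg)
  expect_identical(o1, o2)
  pr1 <- genPromoters(genes, p1$module, cfg)
  pr2 <- genPromoters(genes, p1$module, cfg)
  expect_identical(as.character(pr1$promoters),
                   as.character(pr2$promoters))
  # generators leave the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(genScaleFreeNetwork(cfg))
  expect_identical(stats::runif(1), before)
})

test_that("preferential attachment has the contracted edge count", {
  cfg <- simConfig(rngSeed = 7, nGenes = 100, edgesPerNode = 2,
                   moduleSize = 10)
  net <- genScaleFreeNetwork(cfg)
  expect_equal(length(networkNodes(net)), 100)
  expect_equal(nrow(networkEdges(net)), 2 * (100 - 2))  # m*(n-m)
  # no duplicates or self loops by construction (validity would throw)
  expect_true(validObject(net))
})

test_that("module planting controls intra-module density", {
  cfg0 <- simConfig(rngSeed = 8, nGenes = 60, edgesPerNode = 2,
                    moduleSize = 8, intraModuleEdgeProb = 0)
  net <- genScaleFreeNetwork(cfg0)
  pl0 <- plantSeedModule(net, cfg0)
  expect_equal(networkEdges(pl0$network), networkEdges(net))
  cfg1 <- simConfig(rngSeed = 8, nGenes = 60, edgesPerNode = 2,
                    moduleSize = 8, intraModuleEdgeProb = 1)
  pl1 <- plantSeedModule(net, cfg1)
  e <- networkEdges(pl1$network)
  intra <- sum(e$u %in% pl1$module & e$v %in% pl1$module)
  expect_equal(intra, choose(8, 2))  # clique
})

test_that("planted modules are denser than background across seeds", {
  for (s in 1:5) {
    cfg <- simConfig(rngSeed = s)
    pl <- plantSeedModule(genScaleFreeNetwork(cfg), cfg)
    e <- networkEdges(pl$network)
    inMod <- e$u %in% pl$module & e$v %in% pl$module
    nMod <- length(pl$module); nAll <- length(networkNodes(pl$network))
    dIntra <- sum(inMod) / choose(nMod, 2)
    dBg <- sum(!inMod) / (choose(nAll, 2) - choose(nMod, 2))
    expect_gte(dIntra / dBg, 5)
  }
})

test_that("noiseless expression profiles give exact fold changes", {
  cfg <- simConfig(rngSeed = 9, nGenes = 50, edgesPerNode = 2,
                   moduleSize = 5, noiseSd = 0, effectFold = 4)
  genes <- sprintf("g%02d", 1:50)
  ex <- genExpressionProfiles(genes, cfg)
  fc <- foldChanges(conditionFoldChanges(ex$se, "DR", "AL"))
  ratio <- stats::setNames(fc$ratio, fc$gene)
  up <- ex$truth$gene[ex$truth$status == "up"]
  down <- ex$truth$gene[ex$truth$status == "down"]
  none <- ex$truth$gene[ex$truth$status == "none"]
  expect_equal(unname(ratio[up]), rep(4, length(up)), tolerance = 1e-9)
  expect_equal(unname(ratio[down]), rep(0.25, length(down)),
               tolerance = 1e-9)
  expect_equal(unname(ratio[none]), rep(1, length(none)), tolerance = 1e-9)
  # zero DE fraction, zero noise: nothing is called
  cfg0 <- simConfig(rngSeed = 9, nGenes = 50, edgesPerNode = 2,
                    moduleSize = 5, noiseSd = 0, deFraction = 0)
  ex0 <- genExpressionProfiles(genes, cfg0)
  de0 <- callDE(conditionFoldChanges(ex0$se, "DR", "AL"))
  expect_equal(de0$summary$de, 0)
})

test_that("orthology generator honours extreme rates", {
  cfg <- simConfig(rngSeed = 10, nGenes = 30, edgesPerNode = 2,
                   moduleSize = 5, baseOrthologRate = 0,
                   moduleOrthologRate = 1)
  genes <- sprintf("g%02d", 1:30)
  orth <- genOrthologyProfiles(genes, genes[1:5], cfg)
  expect_setequal(unique(orth$presence$gene), genes[1:5])
  expect_equal(nrow(orth$presence), 5 * length(cfg$species))
})

test_that("promoter planting covers the target set at rate one", {
  cfg <- simConfig(rngSeed = 11, nGenes = 40, edgesPerNode = 2,
                   moduleSize = 10, plantedFraction = 1,
                   backgroundPlantRate = 0)
  genes <- sprintf("g%02d", 1:40)
  target <- genes[1:10]
  pr <- genPromoters(genes, target, cfg)
  expect_setequal(pr$planted, target)
  hits <- scanMotif(pr$promoters, cfg$motif)$hitGenes
  expect_true(all(target %in% hits))
  expect_true(all(Biostrings::width(pr$promoters) == cfg$promoterLength))
  # without planting, a 10-base motif essentially never occurs by chance
  cfg0 <- simConfig(rngSeed = 11, nGenes = 40, edgesPerNode = 2,
                    moduleSize = 10, plantedFraction = 0,
                    backgroundPlantRate = 0)
  pr0 <- genPromoters(genes, target, cfg0)
  expect_lte(length(scanMotif(pr0$promoters, cfg0$motif)$hitGenes), 1)
})

test_that("synthetic networks round-trip through the MITAB dialect", {
  cfg <- simConfig(rngSeed = 12, nGenes = 40, edgesPerNode = 2,
                   moduleSize = 5)
  net <- genScaleFreeNetwork(cfg)
  path <- withr::local_tempfile(fileext = ".mitab")
  writeMitab(net, path)
  rec <- readMitab(path)
  expect_equal(nrow(rec), nrow(networkEdges(net)))
  back <- mergeInteractions(rec)
  key <- function(n) {
    e <- networkEdges(n)
    sort(paste(pmin(e$u, e$v), pmax(e$u, e$v)))
  }
  expect_equal(key(back), key(net))
  expect_equal(sort(unique(networkEdges(back)$score)), 3L)
})
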