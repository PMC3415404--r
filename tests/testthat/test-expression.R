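toySE <- function() {
  mat <- rbind(g1 = c(100, 110, 200, 220),
               g2 = c(50, 50, 50, 50),
               g3 = c(0, 0, 10, 10))
  colnames(mat) <- c("AL_r1", "AL_r2", "DR_r1", "DR_r2")
  makeExpressionSE(mat, condition = c("AL", "AL", "DR", "DR"),
                   replicate = c(1, 2, 1, 2))
}

test_that("fold changes average replicates and exclude zero denominators", {
  fc <- conditionFoldChanges(toySE(), "DR", "AL")
  t <- foldChanges(fc)
  expect_equal(t$ratio[t$gene == "g1"], 2)
  expect_equal(t$numMean[t$gene == "g1"], 210)
  expect_equal(t$denMean[t$gene == "g1"], 105)
  expect_equal(fc@excluded, "g3")
  expect_error(conditionFoldChanges(toySE(), "DR", "fasted"),
               "unknown condition")
  # identical conditions give all-unit ratios
  same <- conditionFoldChanges(toySE(), "AL", "AL")
  expect_true(all(foldChanges(same)$ratio == 1))
})

test_that("DE calling is boundary-inclusive and partitions up/down", {
  tab <- data.frame(gene = paste0("g", 1:4),
                    numMean = 1, denMean = 1,
                    ratio = c(2.0, 1.99, 0.5, 0.51))
  fc <- new("FoldChangeTable", table = tab, numerator = "DR",
            denominator = "AL", excluded = character())
  de <- callDE(fc, tau = 2)
  expect_equal(de$up, "g1")
  expect_equal(de$down, "g3")
  expect_equal(de$summary$de, 2)
  expect_equal(callDE(fc, tau = 1.5)$summary$de, 4)
  expect_error(callDE(fc, tau = 1), "> 1")
  strict <- callDE(fc, tau = 2, strict = TRUE)
  expect_equal(strict$summary$de, 0)
  # partition property on random ratios
  set.seed(12)
  tab2 <- data.frame(gene = sprintf("r%03d", 1:200), numMean = 1,
                     denMean = 1, ratio = exp(stats::rnorm(200, 0, 1)))
  fc2 <- new("FoldChangeTable", table = tab2, numerator = "DR",
             denominator = "AL", excluded = character())
  de2 <- callDE(fc2)
  expect_length(intersect(de2$up, de2$down), 0)
  expect_equal(de2$summary$de, length(de2$up) + length(de2$down))
})

test_that("two-fold calling hits the planted truth at the design point", {
  cfg <- simConfig(rngSeed = 3, nGenes = 1000)
  genes <- sprintf("g%04d", 1:1000)
  ex <- genExpressionProfiles(genes, cfg)
  de <- callDE(conditionFoldChanges(ex$se, "DR", "AL"), tau = 2)
  trueDE <- ex$truth$gene[ex$truth$status != "none"]
  called <- c(de$up, de$down)
  expect_gte(mean(trueDE %in% called), 0.9)                    # sensitivity
  expect_lte(mean(setdiff(genes, trueDE) %in% called), 0.05)   # FPR
  # direction agrees with the truth labels for called genes
  ups <- intersect(de$up, trueDE)
  expect_true(all(ex$truth$status[ex$truth$gene %in% ups] == "up"))
})

test_that("overlap enrichment is exact, symmetric, and clips outsiders", {
  uni <- sprintf("u%02d", 1:10)
  a <- uni[1:5]; b <- uni[c(1, 2, 3, 6)]
  res <- overlapEnrichment(a, b, uni)
  expect_equal(res$overlap, 3)
  expect_equal(res$pValue, 66 / 252, tolerance = 1e-12)
  expect_equal(overlapEnrichment(b, a, uni)$pValue, res$pValue)
  # zero overlap -> p = 1
  expect_equal(overlapEnrichment(uni[1:2], uni[9:10], uni)$pValue, 1)
  res2 <- overlapEnrichment(c(a, "alien"), b, uni)
  expect_equal(res2$clipped, "alien")
  expect_equal(res2$nA, 5)
  expect_error(overlapEnrichment(a, b, character()), "non-empty")
})

test_that("set shift test matches the exact rank p on the toy case", {
  tab <- data.frame(gene = paste0("g", 1:6), numMean = 1, denMean = 1,
                    ratio = c(2, 4, 1, 1, 1, 1))
  fc <- new("FoldChangeTable", table = tab, numerator = "DR",
            denominator = "AL", excluded = character())
  res <- setShiftTest(fc, c("g1", "g2"))
  expect_equal(res$meanRatio, 3)
  expect_equal(res$test$p.value, 1 / 15, tolerance = 1e-9)
  expect_error(setShiftTest(fc, "absent"), "no gene")
})

test_that("neighbor expansion includes interaction partners in the mean", {
  tab <- data.frame(gene = c("A", "B", "C"), numMean = 1, denMean = 1,
                    ratio = c(4, 2, 1))
  fc <- new("FoldChangeTable", table = tab, numerator = "DR",
            denominator = "AL", excluded = character())
  net <- Interactome(edges = data.frame(u = "A", v = "B"), nodes = c("A", "B", "C"))
  res <- setShiftTest(fc, "A", includeNeighbors = TRUE, net = net)
  expect_setequal(res$setGenes, c("A", "B"))
  expect_equal(res$meanRatio, 3)
  expect_error(setShiftTest(fc, "A", includeNeighbors = TRUE), "required")
})

test_that("a random sample of genes shows no shift", {
  set.seed(4)
  tab <- data.frame(gene = sprintf("g%03d", 1:300), numMean = 1,
                    denMean = 1, ratio = exp(stats::rnorm(300, 0, 0.5)))
  fc <- new("FoldChangeTable", table = tab, numerator = "DR",
            denominator = "AL", excluded = character())
  ps <- vapply(1:30, function(i)
    setShiftTest(fc, sample(tab$gene, 20))$test$p.value, 1.0)
  expect_gt(mean(ps), 0.25)  # roughly uniform under the null
  expect_lt(mean(ps), 0.75)
})

test_that("expression tables round-trip through TSV and the series-matrix
           path strips metadata", {
  ex <- genExpressionProfiles(sprintf("g%02d", 1:20),
                              simConfig(rngSeed = 5, nGenes = 20,
                                        edgesPerNode = 2, moduleSize = 5))
  ep <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTSV(ex$se, ep, sp)
  back <- readExpressionTSV(ep, sp)
  expect_equal(SummarizedExperiment::assay(back, "intensity"),
               SummarizedExperiment::assay(ex$se, "intensity"),
               tolerance = 1e-6)
  expect_equal(SummarizedExperiment::colData(back)$condition,
               SummarizedExperiment::colData(ex$se)$condition)
  # series-matrix dialect: '!' metadata lines are ignored
  lines <- readLines(ep)
  writeLines(c("!Series_title\tsynthetic", lines, "!series_matrix_table_end"),
             ep)
  back2 <- readExpressionTSV(ep, sp, seriesMatrix = TRUE)
  expect_equal(dim(back2), dim(back))
})
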