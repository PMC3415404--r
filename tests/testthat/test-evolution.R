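test_that("ortholog-presence enrichment follows the Poisson tail", {
  # 4-gene set, 3 with orthologs in the one target species, genome rate 25%
  genome <- sprintf("g%02d", 1:20)
  geneSet <- genome[1:4]
  withOrth <- c(genome[1:3], genome[5:6])  # 3 of the set, 5/20 = 25% genome
  presence <- data.frame(gene = withOrth, species = "sp1")
  res <- orthologPresenceEnrichment(geneSet, presence, genome)
  expect_equal(res$setPctAvg, 75)
  expect_equal(res$genomePctAvg, 25)
  expect_equal(res$poissonP, 0.080301, tolerance = 1e-5)

  # set rate equal to genome rate: observed = lambda -> p >= 0.5 (median)
  pres2 <- data.frame(gene = genome, species = "sp1")
  res2 <- orthologPresenceEnrichment(geneSet, pres2, genome)
  expect_gte(res2$poissonP, 0.5)

  # set with no orthologs anywhere
  pres3 <- data.frame(gene = genome[10:12], species = "sp1")
  res3 <- orthologPresenceEnrichment(geneSet, pres3, genome)
  expect_equal(res3$setPctAvg, 0)
  expect_equal(res3$poissonP, 1)
  expect_error(orthologPresenceEnrichment(character(), pres3, genome),
               "non-empty")
})

test_that("planted conserved subsets score enriched across seeds", {
  hits <- 0
  for (s in 1:5) {
    cfg <- simConfig(rngSeed = s, nGenes = 1000, moduleSize = 100)
    genes <- sprintf("g%04d", 1:1000)
    module <- genes[1:100]
    orth <- genOrthologyProfiles(genes, module, cfg)
    res <- orthologPresenceEnrichment(module, orth$presence, genes)
    if (res$poissonP < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("dN/dS comparison reports exact small-sample rank p-values", {
  res <- dndsCompare(c(0.01, 0.02), c(0.03, 0.04), alternative = "less")
  expect_equal(res$test$p.value, 1 / 6, tolerance = 1e-9)
  expect_equal(res$setMean, 0.015)
  expect_equal(dndsCompare(c(1, 2), c(1, 2))$test$p.value, 1)
  # background lower than set: one-sided 'less' p above 0.5
  res2 <- dndsCompare(c(0.5, 0.6), c(0.1, 0.2), alternative = "less")
  expect_gt(res2$test$p.value, 0.5)
  expect_error(dndsCompare(numeric(), 1:3), "non-empty")
})

test_that("module dN/dS sits below background in synthetic profiles", {
  for (s in 1:5) {
    cfg <- simConfig(rngSeed = s, nGenes = 400, moduleSize = 50)
    genes <- sprintf("g%04d", 1:400)
    orth <- genOrthologyProfiles(genes, genes[1:50], cfg)
    r <- orth$rates
    expect_lt(stats::median(r$dnds[r$inModule]),
              stats::median(r$dnds[!r$inModule]))
  }
})

test_that("ancient-gene filter keeps genes with distant orthologs", {
  pres <- data.frame(gene = c("A", "B", "C"),
                     species = c("yeast", "mouse", "yeast"))
  expect_setequal(ancientGenes(c("A", "B", "C", "D"), pres, "yeast"),
                  c("A", "C"))
})

test_that("conservation regression recovers noiseless linear structure", {
  set.seed(21)
  n <- 60
  deg <- sample(1:200, n, replace = TRUE)
  nSpecies <- sample(1:10, n, replace = TRUE)
  # noiseless: log(dnds) = 2*log(degree) + 3*nSpecies
  dnds <- exp(2 * log(deg) + 3 * nSpecies)
  tab <- data.frame(gene = sprintf("g%02d", 1:n), degree = deg,
                    nSpecies = nSpecies, dnds = dnds)
  res <- conservationRegression(tab, geneSet = tab$gene[1:10])
  co <- suppressWarnings(stats::coef(res$fits$logDnds))
  expect_equal(unname(co[2:3]), c(2, 3), tolerance = 1e-8)
  expect_equal(suppressWarnings(summary(res$fits$logDnds)$r.squared), 1,
               tolerance = 1e-9)
  # noiseless data: set predictions equal observations
  expect_equal(res$setMeans$observed, res$setMeans$predicted,
               tolerance = 1e-6)
  # perfectly anti-monotone pair gives r = -1
  tab2 <- data.frame(gene = tab$gene, degree = deg, nSpecies = 5,
                     dnds = exp(-log(deg)))
  r2 <- suppressWarnings(
    conservationRegression(tab2)$correlations["logDegree", "logDnds"])
  expect_equal(unname(r2), -1, tolerance = 1e-9)
})

test_that("coefficients are recovered within three standard errors", {
  set.seed(33)
  n <- 300
  logDeg <- stats::rnorm(n, 2, 1)
  nSpecies <- sample(1:10, n, replace = TRUE)
  logDnds <- -0.4 * logDeg - 0.2 * nSpecies + stats::rnorm(n, 0, 0.5)
  tab <- data.frame(gene = sprintf("g%03d", 1:n), degree = exp(logDeg),
                    nSpecies = nSpecies, dnds = exp(logDnds))
  fit <- conservationRegression(tab)$fits$logDnds
  est <- stats::coef(summary(fit))
  expect_lt(abs(est["logDegree", "Estimate"] - (-0.4)),
            3 * est["logDegree", "Std. Error"])
  expect_lt(abs(est["nSpecies", "Estimate"] - (-0.2)),
            3 * est["nSpecies", "Std. Error"])
})

test_that("filtering commutes with transformation and rejects tiny tables", {
  tab <- data.frame(gene = sprintf("g%02d", 1:15),
                    degree = c(0, 1:14),
                    nSpecies = rep(3, 15),
                    dnds = c(0.1, NA, 0.2, -1, seq(0.1, 1.1, 0.1)))
  res <- suppressWarnings(conservationRegression(tab))
  # rows used = degree > 0 & dnds present and positive
  expect_equal(res$nUsed, sum(tab$degree > 0 & !is.na(tab$dnds) &
                                tab$dnds > 0))
  expect_error(conservationRegression(tab[1:5, ]), "usable rows")
})

test_that("orthology TSV reader derives dnds only when absent", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tdn\tds", "A\t0.1\t0.5", "B\t0.2\t0"), path)
  tab <- readOrthologyTSV(path)
  expect_equal(tab$dnds, c(0.2, NA))
  writeLines(c("gene\tdn\tds\tdnds", "A\t0.1\t0.5\t0.9"), path)
  expect_equal(readOrthologyTSV(path)$dnds, 0.9)  # stored value wins
})
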