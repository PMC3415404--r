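mitabLine <- function(idA = "uniprotkb:P1", idB = "uniprotkb:P2",
                      taxA = "taxid:559292(yeast)",
                      taxB = "taxid:559292(yeast)",
                      method = "psi-mi:\"MI:0018\"(two hybrid)",
                      pub = "pubmed:123",
                      type = "psi-mi:\"MI:0915\"(physical association)",
                      db = "psi-mi:\"MI:0469\"(IntAct)",
                      ncol = 15L) {
  f <- rep("-", ncol)
  f[1] <- idA; f[2] <- idB; f[7] <- method; f[9] <- pub
  f[10] <- taxA; f[11] <- taxB; f[12] <- type; f[13] <- db
  paste(f, collapse = "\t")
}

test_that("MITAB parsing maps fields, drops cross-species, flags errors", {
  path <- withr::local_tempfile(fileext = ".mitab")
  writeLines(c("#header", mitabLine()), path)
  rec <- readMitab(path)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$idA, "P1")
  expect_equal(rec$detectionMethod, "MI:0018")
  expect_equal(rec$pubmedIds, "123")
  expect_equal(rec$taxonA, 559292L)
  expect_false(rec$ptm)

  writeLines("#only a header", path)
  expect_equal(nrow(readMitab(path)), 0)

  writeLines(mitabLine(ncol = 14L), path)
  expect_error(readMitab(path), "line 1")

  writeLines(c(mitabLine(), mitabLine(taxB = "taxid:9606(human)")), path)
  rec <- readMitab(path)
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "droppedCrossSpecies"), 1L)

  # a phosphorylation interaction type sets the PTM flag
  writeLines(mitabLine(type = "psi-mi:\"MI:0217\"(phosphorylation reaction)"),
             path)
  expect_true(readMitab(path)$ptm)
})

test_that("generic TSV reader fills defaults and respects taxon columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "A\tB", "B\tC"), path)
  rec <- readInteractionsTSV(path, taxon = 7227L)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$taxonA, c(7227L, 7227L))
  expect_equal(rec$sourceDb, c("", ""))
  writeLines(c("source\ttarget\ttaxonA\ttaxonB\tptm",
               "A\tB\t1\t2\tTRUE", "A\tC\t1\t1\tTRUE"), path)
  rec <- readInteractionsTSV(path)
  expect_equal(nrow(rec), 1)
  expect_true(rec$ptm)
  expect_equal(attr(rec, "droppedCrossSpecies"), 1L)
})

test_that("identifier mapping resolves primaries, max support, and ties", {
  syn <- data.frame(
    namespace = c("primary", "primary", "uniprot", "uniprot",
                  "uniprot", "uniprot"),
    identifier = c("P1", "P2", "P3", "P3", "P4", "P4"),
    canonical = c("G1", "G2", "G5", "G6", "G7", "G8"),
    support = c(1, 1, 3, 1, 2, 2),
    stringsAsFactors = FALSE)
  rec <- rbind(mkEvidence("P1", "P2"), mkEvidence("P3", "P1"),
               mkEvidence("P4", "P1"), mkEvidence("P9", "P1"))
  res <- mapIdentifiers(rec, syn)
  expect_equal(res$records$idA, c("G1", "G5"))
  expect_equal(res$records$idB, c("G2", "G1"))
  expect_setequal(res$unmapped$identifier, c("P4", "P9"))
  expect_equal(res$unmapped$reason[res$unmapped$identifier == "P4"],
               "tied synonym support")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeMappingReport(res, tf)
  expect_equal(nrow(utils::read.delim(tf)), 2)
})

test_that("merging pools, directs, de-duplicates and counts self-loops", {
  rec <- rbind(mkEvidence("A", "B", pubmed = "1"),
               mkEvidence("B", "A", pubmed = "2", method = "coIP"))
  un <- mergeInteractions(rec, directed = FALSE)
  expect_equal(nrow(networkEdges(un)), 1)
  expect_equal(networkEdges(un)$nEvidence, 2L)
  di <- mergeInteractions(rec, directed = TRUE)
  expect_equal(nrow(networkEdges(di)), 2)

  loop <- mergeInteractions(mkEvidence("A", "A"))
  expect_equal(nrow(networkEdges(loop)), 0)
  expect_equal(mergeReport(loop)$selfLoops, 1L)

  # duplicate evidence collapses
  dup <- mergeInteractions(rbind(mkEvidence("A", "B"), mkEvidence("A", "B")))
  expect_equal(networkEdges(dup)$nEvidence, 1L)

  # undirected never has more edges than directed
  set.seed(5)
  rec <- do.call(rbind, lapply(1:30, function(i)
    mkEvidence(sample(LETTERS[1:6], 1), sample(LETTERS[1:6], 1))))
  rec <- rec[rec$idA != rec$idB, ]
  expect_lte(nrow(networkEdges(mergeInteractions(rec, FALSE))),
             nrow(networkEdges(mergeInteractions(rec, TRUE))))
})

test_that("merging is idempotent on the pooled evidence", {
  rec <- rbind(mkEvidence("A", "B", pubmed = "1"),
               mkEvidence("B", "A", pubmed = "2"),
               mkEvidence("B", "C", pubmed = "3"),
               mkEvidence("A", "B", pubmed = "1"))
  net1 <- mergeInteractions(rec)
  net2 <- mergeInteractions(do.call(rbind, net1@evidence))
  expect_equal(networkEdges(net1), networkEdges(net2))
})

test_that("edge scoring counts distinct features plus the PTM bonus", {
  e1 <- mkEvidence("A", "B", type = "physical", method = "Y2H",
                   pubmed = "p1")
  expect_equal(edgeScore(e1), 3L)
  e2 <- rbind(e1, mkEvidence("A", "B", type = "physical", method = "coIP",
                             pubmed = "p2"))
  expect_equal(edgeScore(e2), 5L)
  ptm <- mkEvidence("A", "B", type = "phosphorylation", ptm = TRUE)
  expect_equal(edgeScore(ptm), 4L)
  expect_error(edgeScore(e1[0, ]), "non-empty")
  # monotone: pooling more evidence never lowers the score
  set.seed(8)
  ev <- mkEvidence("A", "B")
  s <- edgeScore(ev)
  for (i in 1:20) {
    ev <- rbind(ev, mkEvidence("A", "B",
                               type = sample(c("physical", "genetic"), 1),
                               method = sample(c("Y2H", "coIP", "MS"), 1),
                               pubmed = as.character(sample(9, 1)),
                               ptm = sample(c(TRUE, FALSE), 1)))
    s2 <- edgeScore(ev)
    expect_gte(s2, s)
    s <- s2
  }
})

test_that("Interactome validity rejects malformed networks", {
  expect_error(Interactome(edges = data.frame(u = "A", v = "A")),
               "self-loops")
  expect_error(Interactome(edges = data.frame(u = c("A", "B"),
                                              v = c("B", "A"))),
               "duplicate")
  expect_error(Interactome(edges = data.frame(u = "A", v = "B"),
                           nodes = "A"), "endpoint")
})

test_that("GraphML round-trip preserves topology and scores", {
  rec <- rbind(mkEvidence("A", "B", pubmed = "1|2"),
               mkEvidence("B", "C", pubmed = "3", ptm = TRUE),
               mkEvidence("C", "D"))
  net <- mergeInteractions(rec)
  path <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, path)
  back <- readGraphML(path)
  expect_setequal(networkNodes(back), networkNodes(net))
  key <- function(n) {
    e <- networkEdges(n)
    o <- order(pmin(e$u, e$v), pmax(e$u, e$v))
    data.frame(u = pmin(e$u, e$v)[o], v = pmax(e$u, e$v)[o],
               score = e$score[o])
  }
  expect_equal(key(back), key(net))
  sif <- withr::local_tempfile(fileext = ".sif")
  writeSIF(net, sif)
  expect_equal(length(readLines(sif)), 3)
})
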