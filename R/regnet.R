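#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   vcountPattern reverseComplement
NULL

.iupacCodes <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Validate an IUPAC nucleotide motif
#'
#' @param pattern Motif string over the IUPAC nucleotide alphabet
#'   (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return The upper-cased pattern, invisibly erroring on invalid codes.
#' @export
checkIupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("motif pattern must be a single non-empty string")
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(.iupacCodes))
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad),
                                                   collapse = ", "))
  pattern
}

#' Scan promoters for a degenerate IUPAC motif
#'
#' Counts motif occurrences in each promoter sequence: IUPAC codes expand to
#' their base classes (Y = C/T, W = A/T, N = any, ...), every start position
#' is tested and overlapping matches all count. With `bothStrands = TRUE`
#' the reverse complement of each sequence is scanned as well and the hits
#' added (a palindromic motif therefore counts double).
#'
#' @param promoters Named [Biostrings::DNAStringSet] (or named character
#'   vector), one upstream sequence per gene.
#' @param pattern IUPAC motif string.
#' @param bothStrands Also scan the reverse strand. Default `FALSE`:
#'   annotated upstream regions are scanned as given.
#' @return List with `counts` (named integer vector) and `hitGenes`
#'   (genes with >= 1 match).
#' @examples
#' scanMotif(c(g1 = "TGATGA"), "YGW")
#' @export
scanMotif <- function(promoters, pattern, bothStrands = FALSE) {
  pattern <- checkIupac(pattern)
  if (is.character(promoters))
    promoters <- Biostrings::DNAStringSet(promoters)
  if (is.null(names(promoters)) || anyDuplicated(names(promoters)))
    stop("promoters must have unique gene names")
  counts <- Biostrings::vcountPattern(pattern, promoters, fixed = FALSE)
  if (bothStrands)
    counts <- counts + Biostrings::vcountPattern(
      pattern, Biostrings::reverseComplement(promoters), fixed = FALSE)
  counts <- stats::setNames(as.integer(counts), names(promoters))
  list(counts = counts, hitGenes = names(counts)[counts > 0])
}

#' Motif enrichment in the promoters of a target gene set
#'
#' For each motif of a collection, the promoters of all genes form the
#' universe, the motif's hit genes are the marked subpopulation and the
#' target set is the draw; enrichment is the exact hypergeometric upper tail
#' of the observed hit overlap, with BH q-values computed across the
#' collection. Target genes without a promoter are clipped and reported.
#'
#' @param motifs `data.frame` with columns `name` and `pattern`, or a single
#'   IUPAC string.
#' @param targetSet Character vector of gene ids.
#' @param promoters Named `DNAStringSet` of promoter sequences.
#' @param bothStrands Passed to [scanMotif()].
#' @return `data.frame` with columns `name`, `pattern`, `hitsInUniverse`,
#'   `hitsInTarget`, `nTarget`, `pValue`, `qValue`, plus attribute
#'   `"clipped"`.
#' @export
motifEnrichment <- function(motifs, targetSet, promoters,
                            bothStrands = FALSE) {
  if (is.character(motifs))
    motifs <- data.frame(name = motifs, pattern = motifs,
                         stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(motifs)))
    stop("motif collection needs columns 'name' and 'pattern'")
  if (length(promoters) == 0L) stop("promoter set is empty")
  universe <- names(promoters)
  target <- unique(as.character(targetSet))
  clipped <- setdiff(target, universe)
  target <- intersect(target, universe)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    hits <- scanMotif(promoters, motifs$pattern[i],
                      bothStrands = bothStrands)$hitGenes
    k <- length(intersect(hits, target))
    data.frame(name = motifs$name[i], pattern = motifs$pattern[i],
               hitsInUniverse = length(hits), hitsInTarget = k,
               nTarget = length(target),
               pValue = pHyperTail(k, length(target), length(hits),
                                   length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qValue <- bhQvalues(out$pValue)
  rownames(out) <- NULL
  attr(out, "clipped") <- clipped
  out
}

#' Rank transcription factors by target specificity for a DE set
#'
#' For each transcription factor with `t` targets inside the universe of
#' which `s` are differentially expressed: specificity = 100 s/t and the
#' exact binomial upper-tail p-value of `s` hits in `t` trials at the DE
#' background rate `|deSet|/|universe|`. TFs with no target in the universe
#' are excluded and reported; DE genes outside the universe are clipped.
#' Output is ranked by ascending p, then descending specificity.
#'
#' @param tfTargets `data.frame` with columns `tf` and `target`.
#' @param deSet Character vector of differentially expressed genes.
#' @param universe Character vector of all genes considered.
#' @return `data.frame` with columns `tf`, `nTargets`, `nDeTargets`,
#'   `specificityPct`, `pValue`, `qValue`; attributes `"excludedTFs"` and
#'   `"clipped"`.
#' @export
tfSpecificityRank <- function(tfTargets, deSet, universe) {
  if (!all(c("tf", "target") %in% names(tfTargets)))
    stop("TF table needs columns 'tf' and 'target'")
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  de <- unique(as.character(deSet))
  clipped <- setdiff(de, universe)
  de <- intersect(de, universe)
  q <- length(de) / length(universe)
  tt <- tfTargets[tfTargets$target %in% universe, , drop = FALSE]
  tt <- unique(tt[, c("tf", "target")])
  excluded <- setdiff(unique(tfTargets$tf), unique(tt$tf))
  if (nrow(tt) == 0L)
    stop("no TF has a target inside the universe")
  bySet <- split(tt$target, tt$tf)
  rows <- lapply(names(bySet), function(tf) {
    targets <- bySet[[tf]]
    s <- length(intersect(targets, de))
    data.frame(tf = tf, nTargets = length(targets), nDeTargets = s,
               specificityPct = 100 * s / length(targets),
               pValue = pBinomTail(s, length(targets), q),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qValue <- bhQvalues(out$pValue)
  out <- out[order(out$pValue, -out$specificityPct, out$tf), ]
  rownames(out) <- NULL
  attr(out, "excludedTFs") <- excluded
  attr(out, "clipped") <- clipped
  out
}

#' Extract fixed-length promoters from a genome
#'
#' Cuts the `width` bases immediately upstream of each transcription start
#' site, 1-based, strand-aware and TSS-exclusive: `[TSS - width, TSS - 1]`
#' on the coding strand. Minus-strand genes take `[TSS + 1, TSS + width]`
#' reverse-complemented, so every promoter reads 5'-to-3' towards the gene.
#' Windows extending past a contig end are skipped with a report.
#'
#' @param genome Named [Biostrings::DNAStringSet] of contig sequences.
#' @param annot `data.frame` with columns `gene`, `seqname`, `strand`
#'   (`"+"`/`"-"`), `tss` (1-based position of the transcription start).
#' @param width Promoter length in bases (default 500).
#' @return Named `DNAStringSet`; genes skipped for out-of-range windows are
#'   attached as attribute `"skipped"`.
#' @export
extractPromoters <- function(genome, annot, width = 500L) {
  need <- c("gene", "seqname", "strand", "tss")
  if (!all(need %in% names(annot)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  seqs <- character(); skipped <- character()
  for (i in seq_len(nrow(annot))) {
    contig <- genome[[annot$seqname[i]]]
    tss <- annot$tss[i]
    if (annot$strand[i] == "+") {
      from <- tss - width; to <- tss - 1
    } else {
      from <- tss + 1; to <- tss + width
    }
    if (from < 1 || to > length(contig)) {
      skipped <- c(skipped, annot$gene[i]); next
    }
    s <- Biostrings::subseq(contig, from, to)
    if (annot$strand[i] == "-")
      s <- Biostrings::reverseComplement(s)
    seqs[annot$gene[i]] <- as.character(s)
  }
  out <- Biostrings::DNAStringSet(seqs)
  attr(out, "skipped") <- skipped
  out
}

#' Read promoter FASTA / motif TSV / TF-target TSV
#'
#' `readPromoterFasta` reads gene-keyed promoter sequences;
#' `readMotifTSV` reads a motif collection (columns `name`, `pattern`);
#' `readTfTargetsTSV` reads a two-column TF-to-target table.
#'
#' @param path File path.
#' @return `DNAStringSet` or `data.frame` respectively.
#' @export
readPromoterFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate gene ids in promoter FASTA")
  x
}

#' @rdname readPromoterFasta
#' @export
readMotifTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(tab)))
    stop("motif TSV needs columns 'name' and 'pattern'")
  tab$pattern <- vapply(tab$pattern, checkIupac, "")
  tab
}

#' @rdname readPromoterFasta
#' @export
readTfTargetsTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("TF-target TSV needs two columns")
  names(tab)[1:2] <- c("tf", "target")
  tab
}
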