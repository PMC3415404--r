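#' Parse PSI-MITAB 2.5/2.6 interaction records
#'
#' Reads the tab-delimited PSI-MITAB format: one evidence record per line,
#' interactor ids in columns 1-2, detection method in column 7, publication
#' ids in column 9, interactor taxa in columns 10-11, interaction type in
#' column 12 and source database in column 13. Lines starting with `#` are
#' headers. Missing fields (`-`) become empty strings. Records whose two
#' interactors carry different taxon ids are dropped and tallied (only
#' same-species interactions are analyzed).
#'
#' @param path Path to a MITAB file.
#' @return A `data.frame` of evidence records with columns `idA`, `idB`,
#'   `taxonA`, `taxonB`, `detectionMethod`, `pubmedIds`, `interactionType`,
#'   `sourceDb`, `ptm`. The number of taxon-mismatched records dropped is
#'   attached as attribute `"droppedCrossSpecies"`.
#' @export
readMitab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- .emptyEvidence()
    attr(out, "droppedCrossSpecies") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 15L)
  if (length(bad))
    stop("MITAB format error: line ", bad[1], " has ", ncols[bad[1]],
         " columns (>= 15 required)")
  get <- function(i) vapply(fields, function(f) .mitabField(f[i]), "")
  rec <- data.frame(
    idA = .stripNamespace(get(1)),
    idB = .stripNamespace(get(2)),
    taxonA = .mitabTaxon(get(10)),
    taxonB = .mitabTaxon(get(11)),
    detectionMethod = .mitabTerm(get(7)),
    pubmedIds = vapply(get(9), .mitabPubmed, "", USE.NAMES = FALSE),
    interactionType = .mitabTerm(get(12)),
    sourceDb = .mitabTerm(get(13)),
    stringsAsFactors = FALSE)
  rec$ptm <- .looksLikePtm(get(12))
  same <- is.na(rec$taxonA) | is.na(rec$taxonB) | rec$taxonA == rec$taxonB
  dropped <- sum(!same)
  rec <- rec[same, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "droppedCrossSpecies") <- dropped
  rec
}

.emptyEvidence <- function() {
  data.frame(idA = character(), idB = character(),
             taxonA = integer(), taxonB = integer(),
             detectionMethod = character(), pubmedIds = character(),
             interactionType = character(), sourceDb = character(),
             ptm = logical(), stringsAsFactors = FALSE)
}

.mitabField <- function(x) {
  if (is.na(x) || x == "-") "" else x
}

# first alternative of a possibly '|'-separated field
.firstAlt <- function(x) sub("\\|.*$", "", x)

.stripNamespace <- function(x) {
  sub("^[^:]*:", "", .firstAlt(x))
}

.mitabTaxon <- function(x) {
  x <- .firstAlt(x)
  num <- sub("^taxid:(-?[0-9]+).*$", "\\1", x)
  suppressWarnings(as.integer(ifelse(grepl("^taxid:", x), num, NA)))
}

# "psi-mi:\"MI:0018\"(two hybrid)" -> "MI:0018"; plain tokens pass through
.mitabTerm <- function(x) {
  x <- .firstAlt(x)
  out <- x
  has <- vapply(regmatches(x, gregexpr("MI:[0-9]+", x)), length, 1L) > 0
  out[has] <- vapply(x[has], function(s)
    regmatches(s, regexpr("MI:[0-9]+", s)), "")
  out
}

.mitabPubmed <- function(x) {
  if (!nzchar(x)) return("")
  parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  pm <- sub("^pubmed:", "", parts[startsWith(parts, "pubmed:")])
  paste(unique(pm), collapse = "|")
}

.ptmKeywords <- c("phosphorylation", "dephosphorylation", "ubiquitin",
                  "acetylation", "deacetylation", "methylation",
                  "sumoylation", "glycosylation", "cleavage",
                  "modification")

.looksLikePtm <- function(typeField) {
  low <- tolower(typeField)
  Reduce(`|`, lapply(.ptmKeywords, function(k) grepl(k, low, fixed = TRUE)))
}

#' Read generic source/target interaction TSV
#'
#' Accepts a tab-separated table with a header whose first two columns are the
#' interactor ids; optional columns `taxonA`, `taxonB` (or a single `taxon`),
#' `detectionMethod`, `pubmedIds`, `interactionType`, `sourceDb`, `ptm` are
#' used when present, and default to empty / `FALSE` otherwise.
#'
#' @param path Path to the TSV.
#' @param taxon Default taxon applied when the file has no taxon columns.
#' @return Evidence `data.frame` as from [readMitab()].
#' @export
readInteractionsTSV <- function(path, taxon = NA_integer_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("interaction TSV needs at least 2 columns")
  rec <- data.frame(
    idA = as.character(tab[[1]]),
    idB = as.character(tab[[2]]),
    taxonA = if ("taxonA" %in% names(tab)) as.integer(tab$taxonA)
             else if ("taxon" %in% names(tab)) as.integer(tab$taxon)
             else as.integer(rep(taxon, nrow(tab))),
    stringsAsFactors = FALSE)
  rec$taxonB <- if ("taxonB" %in% names(tab)) as.integer(tab$taxonB)
                else rec$taxonA
  opt <- function(col, default) {
    if (col %in% names(tab)) as.character(tab[[col]])
    else rep(default, nrow(tab))
  }
  rec$detectionMethod <- opt("detectionMethod", "")
  rec$pubmedIds <- opt("pubmedIds", "")
  rec$interactionType <- opt("interactionType", "")
  rec$sourceDb <- opt("sourceDb", "")
  rec$ptm <- if ("ptm" %in% names(tab)) as.logical(tab$ptm)
             else rep(FALSE, nrow(tab))
  same <- is.na(rec$taxonA) | is.na(rec$taxonB) | rec$taxonA == rec$taxonB
  out <- rec[same, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "droppedCrossSpecies") <- sum(!same)
  out
}

#' Map interactor identifiers to canonical gene ids
#'
#' Two-pass resolution against a synonym table. Pass 1 resolves identifiers
#' with a primary mapping (`namespace == "primary"`). Pass 2 resolves the
#' remainder through synonyms, choosing the candidate canonical id with the
#' highest support count (the id with the highest level of matches across
#' source databases); ties are treated as unmappable. Records with any
#' unmapped endpoint are excluded and reported.
#'
#' @param records Evidence `data.frame` ([readMitab()] layout).
#' @param synonyms `data.frame` with columns `namespace`, `identifier`,
#'   `canonical`, `support`.
#' @return List with `records` (mapped, canonical ids in `idA`/`idB`) and
#'   `unmapped` (`data.frame` of identifier, reason).
#' @export
mapIdentifiers <- function(records, synonyms) {
  need <- c("namespace", "identifier", "canonical", "support")
  if (!all(need %in% names(synonyms)))
    stop("synonym table needs columns: ", paste(need, collapse = ", "))
  resolve <- function(id) {
    hit <- synonyms[synonyms$identifier == id, , drop = FALSE]
    if (nrow(hit) == 0L) return(list(id = NA_character_, reason = "no match"))
    prim <- hit[hit$namespace == "primary", , drop = FALSE]
    if (nrow(prim) > 0L) {
      cand <- unique(prim$canonical)
      if (length(cand) == 1L) return(list(id = cand, reason = ""))
      return(list(id = NA_character_, reason = "ambiguous primary"))
    }
    agg <- tapply(hit$support, hit$canonical, sum)
    best <- names(agg)[agg == max(agg)]
    if (length(best) == 1L) return(list(id = best, reason = ""))
    list(id = NA_character_, reason = "tied synonym support")
  }
  ids <- unique(c(records$idA, records$idB))
  res <- lapply(ids, resolve)
  canon <- vapply(res, `[[`, "", "id")
  reason <- vapply(res, `[[`, "", "reason")
  names(canon) <- names(reason) <- ids
  mappedA <- canon[records$idA]
  mappedB <- canon[records$idB]
  keep <- !is.na(mappedA) & !is.na(mappedB)
  out <- records[keep, , drop = FALSE]
  out$idA <- unname(mappedA[keep])
  out$idB <- unname(mappedB[keep])
  rownames(out) <- NULL
  failed <- ids[is.na(canon)]
  unmapped <- data.frame(identifier = failed,
                         reason = unname(reason[failed]),
                         stringsAsFactors = FALSE)
  list(records = out, unmapped = unmapped)
}

#' Write an identifier-mapping report as TSV
#'
#' @param mapping Result of [mapIdentifiers()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeMappingReport <- function(mapping, path) {
  utils::write.table(mapping$unmapped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score the pooled evidence of one edge
#'
#' An edge gains one point per distinct interaction type, one per distinct
#' detection method, one per distinct publication, and one extra point if any
#' evidence record involves a post-translational modification. Missing
#' annotations count as a single "(unspecified)" level of their feature, so
#' every evidenced edge scores at least 3.
#'
#' @param evidence Non-empty evidence `data.frame` ([readMitab()] layout).
#' @return Integer score.
#' @examples
#' ev <- data.frame(interactionType = "physical", detectionMethod = "Y2H",
#'                  pubmedIds = "1", ptm = FALSE)
#' edgeScore(ev)
#' @export
edgeScore <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0L)
    stop("evidence must be non-empty")
  lev <- function(x) {
    x[!nzchar(x)] <- "(unspecified)"
    length(unique(x))
  }
  pubs <- unlist(strsplit(evidence$pubmedIds, "|", fixed = TRUE))
  pubs <- unique(pubs[nzchar(pubs)])
  nPubs <- max(1L, length(pubs))
  lev(evidence$interactionType) + lev(evidence$detectionMethod) + nPubs +
    as.integer(any(evidence$ptm))
}

#' Merge evidence records into a scored network
#'
#' In undirected mode, records `(A,B)` and `(B,A)` are fused into one edge
#' pooling their evidence; directed mode keeps them distinct. Self-loops are
#' removed and counted. Evidence is de-duplicated on
#' (sourceDb, pubmedIds, detectionMethod, interactionType) before scoring.
#' Merging is idempotent: re-merging a merged network's record list returns
#' the same edges and scores.
#'
#' @param records Identifier-mapped evidence `data.frame`.
#' @param directed Build a directional network?
#' @param taxon Taxonomy id of the network (default: taken from the records).
#' @return An [Interactome-class].
#' @export
mergeInteractions <- function(records, directed = FALSE,
                              taxon = NA_integer_) {
  if (is.na(taxon) && nrow(records) > 0) {
    tx <- unique(records$taxonA[!is.na(records$taxonA)])
    if (length(tx) == 1L) taxon <- tx
  }
  selfLoop <- records$idA == records$idB
  nSelf <- sum(selfLoop)
  rec <- records[!selfLoop, , drop = FALSE]
  if (nrow(rec) == 0L)
    return(Interactome(directed = directed, taxon = taxon,
                       report = list(selfLoops = nSelf)))
  key <- if (directed) paste(rec$idA, rec$idB, sep = "\r")
         else paste(pmin(rec$idA, rec$idB), pmax(rec$idA, rec$idB),
                    sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  ord <- order(names(groups))
  groups <- groups[ord]
  ev <- lapply(groups, function(idx) {
    e <- rec[idx, , drop = FALSE]
    dupKey <- paste(e$sourceDb, e$pubmedIds, e$detectionMethod,
                    e$interactionType, sep = "\r")
    e <- e[!duplicated(dupKey), , drop = FALSE]
    rownames(e) <- NULL
    e
  })
  ends <- strsplit(names(groups), "\r", fixed = TRUE)
  edges <- data.frame(u = vapply(ends, `[`, "", 1),
                      v = vapply(ends, `[`, "", 2),
                      stringsAsFactors = FALSE)
  edges$score <- vapply(ev, edgeScore, 1L)
  edges$nEvidence <- vapply(ev, nrow, 1L)
  rownames(edges) <- NULL
  Interactome(edges = edges, directed = directed, taxon = taxon,
              evidence = unname(ev), report = list(selfLoops = nSelf))
}

#' Export / import Interactome as GraphML
#'
#' Node names and edge attributes (score, linkScore) round-trip; pooled
#' evidence tables do not.
#'
#' @param net An [Interactome-class].
#' @param path File path.
#' @return `writeGraphML` invisibly returns the path; `readGraphML` returns an
#'   [Interactome-class].
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname writeGraphML
#' @param taxon Taxonomy id to tag the imported network with.
#' @export
readGraphML <- function(path, taxon = NA_integer_) {
  g <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  names(edges)[1:2] <- c("u", "v")
  if ("score" %in% names(edges)) edges$score <- as.integer(edges$score)
  Interactome(edges = edges, nodes = igraph::V(g)$name,
              directed = igraph::is_directed(g), taxon = taxon)
}

#' Export an Interactome as SIF (simple interaction format)
#'
#' @param net An [Interactome-class].
#' @param path File path.
#' @param relation Interaction label for the middle column.
#' @return Invisibly, the path.
#' @export
writeSIF <- function(net, path, relation = "interacts") {
  e <- networkEdges(net)
  lines <- if (nrow(e)) paste(e$u, relation, e$v, sep = "\t") else character()
  iso <- setdiff(networkNodes(net), c(e$u, e$v))
  writeLines(c(lines, iso), path)
  invisible(path)
}
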