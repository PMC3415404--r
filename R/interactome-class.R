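#' @import methods
NULL

#' Interactome: a species-tagged, evidence-scored interaction network
#'
#' Container for a merged molecular-interaction network. Edges carry an
#' integer evidence score (distinct interaction types + distinct detection
#' methods + distinct publications, +1 if any evidence involves a
#' post-translational modification) and optionally the pooled evidence
#' records they were merged from. Self-loops are removed at merge time and
#' counted in the `report` slot.
#'
#' @slot taxon NCBI taxonomy id (integer; `NA` allowed for synthetic data).
#' @slot directed Logical; whether edges are directional.
#' @slot nodes Character vector of canonical gene ids.
#' @slot edges `data.frame` with at least columns `u` and `v`; typically also
#'   `score` (integer evidence score) and `nEvidence`. Condensed networks add
#'   `linkScore`.
#' @slot evidence List of per-edge evidence `data.frame`s (may be empty).
#' @slot report Named list of merge diagnostics (self-loop count, dropped
#'   records, ...).
#'
#' @export
setClass("Interactome",
         representation(taxon = "integer",
                        directed = "logical",
                        nodes = "character",
                        edges = "data.frame",
                        evidence = "list",
                        report = "list"),
         prototype(taxon = NA_integer_, directed = FALSE,
                   nodes = character(), edges = data.frame(),
                   evidence = list(), report = list()))

setValidity("Interactome", function(object) {
  msgs <- character()
  e <- object@edges
  if (nrow(e) > 0) {
    if (!all(c("u", "v") %in% names(e)))
      msgs <- c(msgs, "edges must have columns 'u' and 'v'")
    else {
      if (!all(c(e$u, e$v) %in% object@nodes))
        msgs <- c(msgs, "every edge endpoint must be in nodes")
      if (any(e$u == e$v))
        msgs <- c(msgs, "self-loops are not allowed")
      key <- if (object@directed) paste(e$u, e$v)
             else paste(pmin(e$u, e$v), pmax(e$u, e$v))
      if (anyDuplicated(key))
        msgs <- c(msgs, "duplicate edges after merging are not allowed")
    }
  }
  if (length(object@evidence) > 0 && length(object@evidence) != nrow(e))
    msgs <- c(msgs, "evidence list must be empty or parallel to edges")
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicate node ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct an Interactome
#'
#' @param nodes Character vector of node ids (defaults to all edge endpoints).
#' @param edges `data.frame` with columns `u`, `v` and optional attributes.
#' @param directed Logical flag.
#' @param taxon NCBI taxonomy id.
#' @param evidence Optional list of per-edge evidence tables.
#' @param report Optional named list of diagnostics.
#' @return An [Interactome-class] object.
#' @examples
#' net <- Interactome(edges = data.frame(u = "A", v = "B"))
#' @export
Interactome <- function(edges = data.frame(u = character(), v = character()),
                        nodes = NULL, directed = FALSE, taxon = NA_integer_,
                        evidence = list(), report = list()) {
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  if (is.null(nodes)) nodes <- unique(c(edges$u, edges$v))
  new("Interactome", taxon = as.integer(taxon), directed = directed,
      nodes = as.character(nodes), edges = edges, evidence = evidence,
      report = report)
}

#' @describeIn Interactome Node ids.
#' @param x,object An `Interactome`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname Interactome
#' @export
setMethod("networkNodes", "Interactome", function(x) x@nodes)

#' @describeIn Interactome Edge table.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname Interactome
#' @export
setMethod("networkEdges", "Interactome", function(x) x@edges)

#' @describeIn Interactome Taxonomy id.
#' @export
setGeneric("taxonId", function(x) standardGeneric("taxonId"))

#' @rdname Interactome
#' @export
setMethod("taxonId", "Interactome", function(x) x@taxon)

#' @describeIn Interactome Whether the network is directed.
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname Interactome
#' @export
setMethod("isDirected", "Interactome", function(x) x@directed)

#' @describeIn Interactome Merge diagnostics.
#' @export
setGeneric("mergeReport", function(x) standardGeneric("mergeReport"))

#' @rdname Interactome
#' @export
setMethod("mergeReport", "Interactome", function(x) x@report)

setMethod("show", "Interactome", function(object) {
  cat("Interactome (", if (object@directed) "directed" else "undirected",
      ")\n", sep = "")
  cat("  taxon:", object@taxon, "\n")
  cat("  nodes:", length(object@nodes), " edges:", nrow(object@edges), "\n")
  if ("score" %in% names(object@edges) && nrow(object@edges) > 0)
    cat("  edge scores:", paste(range(object@edges$score), collapse = ".."),
        "\n")
  invisible(NULL)
})

#' Convert an Interactome to an igraph graph
#'
#' Edge attributes (score, linkScore, ...) are carried over; isolated nodes
#' are preserved.
#'
#' @param x An [Interactome-class].
#' @return An `igraph` object.
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "Interactome"))
  igraph::graph_from_data_frame(x@edges, directed = x@directed,
                                vertices = data.frame(name = x@nodes))
}

#' Node degrees of an Interactome
#'
#' Counts merged edges incident on each node (total degree for directed
#' networks).
#'
#' @param x An [Interactome-class].
#' @return Named integer vector over all nodes.
#' @export
nodeDegrees <- function(x) {
  igraph::degree(asIgraph(x), mode = "all")
}
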