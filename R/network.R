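#' Coerce an igraph object to a Network
#'
#' Symmetrises and simplifies the graph (direction dropped, duplicate edges
#' collapsed, self-loops removed) and assigns vertex names
#' \code{"1", "2", ...} when the graph is unnamed.
#'
#' @param g an \code{igraph} object.
#' @return a [Network-class].
#' @examples
#' asNetwork(igraph::make_ring(5))
#' @export
asNetwork <- function(g) {
  if (!inherits(g, "igraph"))
    stopParameter("asNetwork() expects an igraph object")
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g)
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  new("Network", graph = g)
}

#' Read a network from a plain-text edge list
#'
#' One edge per line as two whitespace-separated node labels; everything from
#' \code{#} to the end of a line is a comment; blank lines are ignored; extra
#' tokens after the first two are ignored. The graph is symmetrised and
#' deduplicated, self-loops are dropped, labels are preserved verbatim, and
#' the order of first appearance fixes the internal vertex order.
#'
#' @param source path to an edge-list file, or a character vector of lines
#'   (anything \code{readLines} accepts, e.g. a connection).
#' @return a [Network-class].
#' @examples
#' net <- readEdgeList(textConnection("a b\nb c\nb a\na a"))
#' numNodes(net)  # 3
#' numEdges(net)  # 2
#' @export
readEdgeList <- function(source) {
  lines <- if (is.character(source) && length(source) > 1) source
           else readLines(source)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineNo <- which(keep)
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0)
    stopParse("malformed edge-list line %d: need at least two tokens",
              lineNo[bad[1]])
  if (length(toks) == 0) {
    return(new("Network", graph = igraph::make_empty_graph(0, directed = FALSE)))
  }
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  # first-appearance order, scanning each line left to right
  labels <- unique(as.vector(rbind(from, to)))
  g <- igraph::make_empty_graph(length(labels), directed = FALSE)
  igraph::V(g)$name <- labels
  g <- igraph::add_edges(g, rbind(match(from, labels), match(to, labels)))
  asNetwork(g)
}

#' Write a network to a plain-text edge list
#'
#' Inverse of [readEdgeList()] on the set-of-edges representation: one edge
#' per line, two whitespace-separated labels, in internal edge order.
#'
#' @param net a [Network-class].
#' @param path output file path or connection.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  el <- igraph::as_edgelist(asIgraph(net), names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("numNodes", "Network", function(x) igraph::vcount(x@graph))

#' @rdname accessors
#' @export
setMethod("numEdges", "Network", function(x) igraph::ecount(x@graph))

#' @rdname accessors
#' @export
setMethod("nodeLabels", "Network", function(x) {
  if (igraph::vcount(x@graph) == 0) character(0) else igraph::V(x@graph)$name
})

#' @rdname accessors
#' @export
setMethod("asIgraph", "Network", function(x) x@graph)

setMethod("show", "Network", function(object) {
  cat(sprintf("Network: %d nodes, %d edges (undirected, simple)\n",
              numNodes(object), numEdges(object)))
  n <- numNodes(object)
  if (n > 0) {
    lab <- nodeLabels(object)
    shown <- paste(utils::head(lab, 6), collapse = ", ")
    cat(sprintf("  labels: %s%s\n", shown, if (n > 6) ", ..." else ""))
  }
})

# neighbor index lists (1-based integer vectors), the workhorse structure
# for BFS and the SIR simulator
adjList <- function(net) {
  lapply(igraph::as_adj_list(asIgraph(net), mode = "all"), as.integer)
}

degreeOf <- function(net) {
  as.numeric(igraph::degree(asIgraph(net)))
}

nodeIndex <- function(net, node) {
  i <- match(as.character(node), nodeLabels(net))
  if (is.na(i))
    stopLookup("node '%s' not present in the network", as.character(node))
  i
}
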