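#' Build the interaction network over selected genes
#'
#' Induced subgraph of an interaction list on the selected genes: an edge is
#' retained iff both endpoints are selected. Interactions are treated as
#' undirected, so `(A, B)` and `(B, A)` (and repeats) collapse to a single
#' edge; self-loops are dropped with a message. Every selected gene is a
#' node, including isolated ones (degree 0). A gene's degree is its number
#' of retained interactions; genes with degree strictly greater than
#' `hub_threshold` are flagged as hubs.
#'
#' @param selected character vector of selected gene ids, or a
#'   `plsmc_selection` object.
#' @param interactions data.frame with columns `geneA`, `geneB`, as from
#'   [read_interactions()] or [simulate_interactions()].
#' @param hub_threshold degree above which a gene is a hub (strict `>`).
#' @param regulation optional named vector of `"up"`/`"down"` labels per
#'   gene, carried into GraphML export for display colouring.
#' @return An object of class `interaction_network`: a list with `graph`
#'   (the [igraph][igraph::graph_from_data_frame] object), `nodes` (a
#'   data.frame with `gene`, `degree`, `hub`), `edges` (a lexicographically
#'   sorted two-column data.frame), `hub_threshold` and the counts of
#'   dropped self-loops / duplicate edges.
#' @export
build_network <- function(selected, interactions, hub_threshold = 10L,
                          regulation = NULL) {
  if (inherits(selected, "plsmc_selection")) selected <- selected_genes(selected)
  selected <- unique(as.character(selected))
  hub_threshold <- check_count(hub_threshold, "hub_threshold")
  a <- as.character(interactions$geneA)
  b <- as.character(interactions$geneB)
  keep <- a %in% selected & b %in% selected
  a <- a[keep]
  b <- b[keep]
  loops <- a == b
  if (any(loops)) {
    message(sprintf("build_network: dropped %d self-loop(s)", sum(loops)))
    a <- a[!loops]
    b <- b[!loops]
  }
  # canonical orientation, then dedup in either direction
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    message(sprintf("build_network: collapsed %d duplicate edge(s)", n_dup))
  }
  edges <- data.frame(geneA = lo[!dup], geneB = hi[!dup],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(selected)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)[nodes]
  node_df <- data.frame(gene = nodes, degree = as.integer(deg),
                        hub = as.integer(deg) > hub_threshold,
                        stringsAsFactors = FALSE)
  rownames(node_df) <- NULL
  if (!is.null(regulation)) {
    node_df$regulation <- unname(regulation[nodes])
  }
  structure(list(graph = g, nodes = node_df, edges = edges,
                 hub_threshold = hub_threshold,
                 n_self_loops_dropped = sum(loops),
                 n_duplicates_dropped = n_dup),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges, %d hub(s) (degree > %d)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$hub), x$hub_threshold))
  invisible(x)
}

#' @export
plot.interaction_network <- function(x, ...) {
  igraph::plot.igraph(x$graph, vertex.size = 4 + 2 * sqrt(igraph::degree(x$graph)),
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Hub genes of an interaction network
#'
#' Genes whose degree strictly exceeds the threshold, sorted by decreasing
#' degree and then by gene id.
#'
#' @param net an [build_network()] result.
#' @param threshold degree threshold (default: the network's own).
#' @return data.frame with columns `gene` and `degree` (possibly 0 rows).
#' @export
find_hubs <- function(net, threshold = net$hub_threshold) {
  stopifnot(inherits(net, "interaction_network"))
  threshold <- check_count(threshold, "threshold")
  h <- net$nodes[net$nodes$degree > threshold, c("gene", "degree")]
  h <- h[order(-h$degree, h$gene), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Export an interaction network for Cytoscape
#'
#' Writes the network as SIF (`geneA<TAB>pp<TAB>geneB`, one line per edge),
#' GraphML (carrying `degree`, `hub` and, when available, `regulation`
#' vertex attributes) or a plain TSV edge list that round-trips through
#' [read_interactions()]. Node and edge order are lexicographic, so repeated
#' exports are byte-identical.
#'
#' @param net an [build_network()] result.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @param min_degree_display drop nodes below this degree before export
#'   (a display filter echoing "more than two associations"-style figure
#'   pruning; 0 keeps everything).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv"),
                           min_degree_display = 0L) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  min_degree_display <- check_count(min_degree_display, "min_degree_display")
  nodes <- net$nodes
  edges <- net$edges
  if (min_degree_display > 0L) {
    keep <- nodes$gene[nodes$degree >= min_degree_display]
    nodes <- nodes[nodes$gene %in% keep, , drop = FALSE]
    edges <- edges[edges$geneA %in% keep & edges$geneB %in% keep, , drop = FALSE]
  }
  if (format == "sif") {
    lines <- if (nrow(edges)) paste(edges$geneA, "pp", edges$geneB, sep = "\t")
             else character()
    writeLines(lines, path)
  } else if (format == "tsv") {
    write_interactions(edges, path)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes$gene))
    igraph::V(g)$degree <- nodes$degree[match(igraph::V(g)$name, nodes$gene)]
    igraph::V(g)$hub <- nodes$hub[match(igraph::V(g)$name, nodes$gene)]
    if (!is.null(nodes$regulation)) {
      igraph::V(g)$regulation <- nodes$regulation[match(igraph::V(g)$name,
                                                        nodes$gene)]
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
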