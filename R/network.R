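#' Select optimal ceRNA pairs
#'
#' The optimal regulatory conditions are the conjunction of the four
#' factor states under which coexpression is strongest: top quartile of
#' miRP size (Q4), top quartile of binding-site count (Q4), third quartile
#' of miRP expression (Q3; intermediate miRNA abundance competes best), and
#' both genes in the high expression state (H-H).
#'
#' @param annotation a `factor_annotation` from [annotate_pairs()].
#' @return the selected rows of `annotation` (possibly zero rows).
#' @export
select_optimal_pairs <- function(annotation) {
  req <- c("size_group", "sites_group", "mirp_expr_group", "state_pair")
  if (!all(req %in% names(annotation))) {
    abort_input("annotation must carry all four factor labels")
  }
  keep <- !is.na(annotation$size_group) & annotation$size_group == "Q4" &
    !is.na(annotation$sites_group) & annotation$sites_group == "Q4" &
    !is.na(annotation$mirp_expr_group) & annotation$mirp_expr_group == "Q3" &
    annotation$state_pair == "H-H"
  out <- annotation[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a ceRNA network from a pair table
#'
#' Nodes are ceRNAs, edges are regulation pairs; the correlation `r` is
#' attached as an edge attribute when present. Self-loops and duplicate
#' edges indicate an upstream bug and raise an error.
#'
#' @param pairs data.frame with canonical `gene_a`, `gene_b` (and
#'   optionally `r`) columns.
#' @return object of class `cerna_network`: list with the `igraph` graph,
#'   `nodes`, `n_nodes`, `n_edges`, and the named `degree` vector.
#' @export
build_network <- function(pairs) {
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    abort_input("pairs must have gene_a and gene_b columns")
  }
  if (nrow(pairs) > 0L && any(pairs$gene_a == pairs$gene_b)) {
    abort_input("self-loop in pair table")
  }
  if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b))) {
    abort_input("duplicate edge in pair table")
  }
  edges <- pairs[, intersect(c("gene_a", "gene_b", "r"), names(pairs)),
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  deg <- igraph::degree(g)
  structure(
    list(graph = g,
         nodes = sort(names(deg)),
         n_nodes = igraph::vcount(g),
         n_edges = igraph::ecount(g),
         degree = deg[order(names(deg))]),
    class = "cerna_network"
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d ceRNAs, %d regulation pairs, mean degree %.1f\n",
              x$n_nodes, x$n_edges,
              if (x$n_nodes > 0) 2 * x$n_edges / x$n_nodes else 0))
  invisible(x)
}

#' Hub table of a ceRNA network
#'
#' Ranks genes by their number of first-order neighbours; each hub's share
#' of the network's regulation pairs is `100 * degree / n_edges` percent.
#' Ties in degree are broken by gene id.
#'
#' @param net a `cerna_network`.
#' @param top_k number of hubs to report (default 20). Values above the
#'   node count return all nodes with a warning.
#' @return data.frame `gene`, `degree`, `pct_of_pairs`.
#' @export
hub_table <- function(net, top_k = 20L) {
  if (!inherits(net, "cerna_network")) abort_input("not a cerna_network")
  if (!is_count(top_k) || top_k < 1) abort_input("top_k must be a positive integer")
  if (top_k > net$n_nodes) {
    warning("top_k exceeds node count; returning all nodes", call. = FALSE)
    top_k <- net$n_nodes
  }
  d <- net$degree
  ord <- order(-d, names(d))
  sel <- ord[seq_len(top_k)]
  data.frame(gene = names(d)[sel],
             degree = as.integer(d[sel]),
             pct_of_pairs = pct_share(as.numeric(d[sel]), net$n_edges),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Induced subnetwork on a gene set
#'
#' Restricts the network to the genes of a functional set (e.g. a GO term)
#' and the regulation pairs internal to it. Each retained node also gets
#' its share of the intra-function pairs (`pct_of_intra_pairs`) and a
#' `label` flag marking nodes that account for more than 1% of them, the
#' rule used to annotate function subnetworks.
#'
#' @param net a `cerna_network`.
#' @param gene_set non-empty character vector of gene ids.
#' @return a `cerna_network` with an extra `node_table` data.frame
#'   (`gene`, `degree`, `pct_of_intra_pairs`, `label`).
#' @export
induced_subnetwork <- function(net, gene_set) {
  if (!inherits(net, "cerna_network")) abort_input("not a cerna_network")
  if (length(gene_set) == 0L) abort_input("empty gene set")
  keep <- intersect(net$nodes, unique(as.character(gene_set)))
  if (length(keep) == 0L) {
    warning("gene set disjoint from network: empty subnetwork", call. = FALSE)
  }
  sg <- igraph::induced_subgraph(net$graph, keep)
  deg <- igraph::degree(sg)
  e_sub <- igraph::ecount(sg)
  node_table <- data.frame(
    gene = names(deg),
    degree = as.integer(deg),
    pct_of_intra_pairs = if (e_sub > 0) pct_share(as.numeric(deg), e_sub) else
      rep(0, length(deg)),
    stringsAsFactors = FALSE
  )
  node_table$label <- node_table$pct_of_intra_pairs > 1
  node_table <- node_table[order(-node_table$degree, node_table$gene), ]
  rownames(node_table) <- NULL
  out <- structure(
    list(graph = sg,
         nodes = sort(names(deg)),
         n_nodes = igraph::vcount(sg),
         n_edges = e_sub,
         degree = deg[order(names(deg))],
         node_table = node_table),
    class = "cerna_network"
  )
  out
}
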