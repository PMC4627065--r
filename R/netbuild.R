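## Assembly of the TF / motif-bearing-gene regulatory network from a
## typed protein-interaction edge list, and per-TF connectivity.

#' Build the motif-anchored regulatory network
#'
#' Nodes are the transcription factors mapped from annotated motifs plus
#' the genes bearing those motifs; undirected interaction edges (typed
#' \code{physical}, \code{colocalization} or \code{genetic}) are kept
#' when both endpoints are in the node set, with duplicate edges of the
#' same type collapsed.  Motif-implied TF-to-target \code{binding} edges
#' are recorded separately from the interaction evidence.
#'
#' @param motif_gene_table logical matrix genes x motifs.
#' @param motif_tf_map data.frame with columns \code{consensus},
#'   \code{tf} mapping annotated motifs to TF node names.
#' @param edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{evidence}.
#' @return A \code{regulatory_network}: an \code{igraph} graph
#'   (\code{graph}; edge attribute \code{evidence}, node attribute
#'   \code{role} in \code{\{"TF", "gene"\}}), the retained
#'   \code{interaction_edges}, the implied \code{binding_edges}, and
#'   counts.
#' @export
build_network <- function(motif_gene_table, motif_tf_map, edges) {
  motif_tf_map <- motif_tf_map[motif_tf_map$consensus %in%
                                 colnames(motif_gene_table), , drop = FALSE]
  tfs <- unique(motif_tf_map$tf)
  binding <- list()
  bearing_genes <- character(0L)
  for (i in seq_len(nrow(motif_tf_map))) {
    cons <- motif_tf_map$consensus[i]
    genes <- rownames(motif_gene_table)[motif_gene_table[, cons]]
    bearing_genes <- union(bearing_genes, genes)
    if (length(genes)) {
      binding[[i]] <- data.frame(tf = motif_tf_map$tf[i], gene = genes,
                                 motif = cons, stringsAsFactors = FALSE)
    }
  }
  binding <- if (length(binding)) do.call(rbind, binding) else
    data.frame(tf = character(), gene = character(), motif = character())
  nodes <- union(tfs, bearing_genes)
  keep <- edges$node_a %in% nodes & edges$node_b %in% nodes &
    edges$node_a != edges$node_b
  if (any(!keep)) {
    warning(sum(!keep), " edge(s) dropped (unknown endpoint or self-loop)")
  }
  ie <- edges[keep, , drop = FALSE]
  if (nrow(ie)) {
    # collapse duplicates of the same type, order-insensitive
    a <- pmin(ie$node_a, ie$node_b); b <- pmax(ie$node_a, ie$node_b)
    ie <- unique(data.frame(node_a = a, node_b = b, evidence = ie$evidence,
                            stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    ie[c("node_a", "node_b", "evidence")],
    directed = FALSE,
    vertices = data.frame(name = nodes,
                          role = ifelse(nodes %in% tfs, "TF", "gene")))
  structure(list(graph = g, interaction_edges = ie, binding_edges = binding,
                 tfs = tfs, n_nodes = length(nodes),
                 n_interaction_edges = nrow(ie),
                 n_binding_edges = nrow(binding)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", x$n_nodes, "nodes (", length(x$tfs), "TFs ),",
      x$n_interaction_edges, "interaction edges,",
      x$n_binding_edges, "motif-implied binding edges\n")
  invisible(x)
}

#' Per-TF connectivity
#'
#' Number of distinct interaction edges incident to each TF node.
#' Motif-implied binding edges are excluded by default, since the
#' connectivity of interest is the protein/gene interaction evidence;
#' set \code{include_binding = TRUE} to count them too.
#'
#' @param network a \code{regulatory_network}.
#' @param include_binding also count motif-implied TF-target edges.
#' @return Named integer vector, TFs sorted by decreasing degree.
#' @export
tf_degree <- function(network, include_binding = FALSE) {
  deg <- igraph::degree(network$graph)[network$tfs]
  deg[is.na(deg)] <- 0
  deg <- as.integer(round(deg))
  names(deg) <- network$tfs
  if (include_binding && nrow(network$binding_edges)) {
    extra <- table(network$binding_edges$tf)
    deg[names(extra)] <- deg[names(extra)] + as.integer(extra)
  }
  sort(deg, decreasing = TRUE)
}

#' Write a regulatory network to GraphML and TSV
#' @param network a \code{regulatory_network}.
#' @param prefix output path prefix; writes \code{<prefix>.graphml},
#'   \code{<prefix>_nodes.tsv}, \code{<prefix>_edges.tsv}.
#' @return The GraphML path, invisibly.
#' @export
write_network <- function(network, prefix) {
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(network$graph, gml, format = "graphml")
  nodes <- data.frame(name = igraph::V(network$graph)$name,
                      role = igraph::V(network$graph)$role)
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$interaction_edges, paste0(prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gml)
}
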