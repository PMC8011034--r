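#' Build the directed 5'->3' domain co-occurrence network
#'
#' For each anchor window (the anchor gene included), genes are laid out in
#' raw contig 5'->3' order and labeled by their distinct domain families
#' (or by their OG label when the product has no domain hit). Consecutive
#' gene labels produce a directed edge; a gene with several families
#' contributes all of them, so every label of gene i connects to every
#' label of gene i+1. Genes with neither a domain nor an OG label are
#' bridged over by default (`bridgeGaps = FALSE` makes adjacency strict).
#' Edges are weighted by the number of distinct genera in which the
#' adjacency was observed; after assembly only R-M-classified nodes and
#' nodes with at least one R-M-classified neighbor are retained (see
#' [retainRMNeighborhood()]).
#'
#' @param windows list of [NeighborhoodWindow-class] (typically k = 3).
#' @param domains domain-hit data.frame.
#' @param ogmap OG assignment data.frame.
#' @param rmref R-M reference data.frame.
#' @param taxonomy taxonomy data.frame providing a genus per genome;
#'   genomes without a genus are skipped with a warning.
#' @param bridgeGaps bridge over label-less genes (default TRUE).
#' @param allDomains contribute all families of a multi-domain gene
#'   (default); `FALSE` keeps only the best-e-value family per gene.
#' @param filter apply the R-M neighborhood retention filter (default).
#' @return A directed igraph with vertex attributes `name` and `rm_types`
#'   (comma-separated, `""` for non-R-M) and edge attributes `weight`
#'   (number of genera) and `genera` (list of genus sets).
#' @export
buildNetwork <- function(windows, domains, ogmap, rmref, taxonomy,
                         bridgeGaps = TRUE, allDomains = TRUE,
                         filter = TRUE) {
  if (is(windows, "NeighborhoodWindow")) windows <- list(windows)
  adj <- list()
  for (w in windows) {
    gid <- w@anchor$genome_id
    genus <- taxonomy$genus[match(gid, taxonomy$genome_id)]
    if (is.na(gid) || is.na(genus)) {
      warnf("no genus for genome '%s'; its windows are skipped", gid)
      next
    }
    g <- rbind(w@upstream, w@anchor, w@downstream)
    g <- g[order(g$rank), , drop = FALSE]   # raw contig 5'->3'
    labs <- lapply(seq_len(nrow(g)), function(i)
      networkGeneLabels(g$protein_id[i], domains, ogmap, allDomains))
    if (bridgeGaps) labs <- labs[lengths(labs) > 0L]
    if (length(labs) < 2L) next
    for (i in seq_len(length(labs) - 1L)) {
      from <- labs[[i]]; to <- labs[[i + 1L]]
      if (!length(from) || !length(to)) next
      pairs <- expand.grid(source = from, target = to,
                           stringsAsFactors = FALSE)
      pairs$genus <- genus
      adj[[length(adj) + 1L]] <- pairs
    }
  }
  if (!length(adj))
    return(emptyNetwork())
  adj <- do.call(rbind, adj)
  key <- paste(adj$source, adj$target, sep = "\r")
  genera <- lapply(split(adj$genus, key), function(g) sort(unique(g)))
  first <- !duplicated(key)
  edges <- data.frame(source = adj$source[first], target = adj$target[first],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  ekey <- paste(edges$source, edges$target, sep = "\r")
  edges$genera <- genera[ekey]
  edges$weight <- lengths(edges$genera)
  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g <- igraph::set_edge_attr(g, "weight", value = edges$weight)
  g <- igraph::set_edge_attr(g, "genera", value = edges$genera)
  g <- igraph::set_vertex_attr(g, "rm_types",
    value = vapply(rmTypesOf(rmref, nodes), paste, character(1),
                   collapse = ","))
  if (filter) retainRMNeighborhood(g) else g
}

emptyNetwork <- function() {
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::set_vertex_attr(g, "rm_types", value = character())
  g <- igraph::set_edge_attr(igraph::set_edge_attr(g, "weight",
                                                   value = numeric()),
                             "genera", value = list())
  g
}

## labels of one gene for the network: domain families (all, or best by
## e-value), else OG label, else none
networkGeneLabels <- function(protein_id, domains, ogmap, allDomains) {
  if (is.na(protein_id)) return(character())
  hits <- domains[domains$protein_id == protein_id, , drop = FALSE]
  if (nrow(hits)) {
    if (allDomains) return(unique(hits$domain_name))
    return(hits$domain_name[which.min(hits$evalue)])
  }
  og <- ogmap$og_label[match(protein_id, ogmap$protein_id)]
  if (!is.na(og)) og else character()
}

#' Retain the R-M neighborhood of a network
#'
#' Keeps R-M-classified nodes and any node with at least one R-M-classified
#' neighbor (in either direction); returns the induced subgraph. The filter
#' is idempotent.
#'
#' @param graph igraph with an `rm_types` vertex attribute.
#' @return The filtered igraph.
#' @export
retainRMNeighborhood <- function(graph) {
  if (igraph::vcount(graph) == 0L) return(graph)
  isRM <- nzchar(igraph::vertex_attr(graph, "rm_types"))
  hasRMNeighbor <- vapply(seq_len(igraph::vcount(graph)), function(v) {
    nb <- igraph::neighbors(graph, v, mode = "all")
    any(isRM[as.integer(nb)])
  }, logical(1))
  igraph::induced_subgraph(graph, which(isRM | hasRMNeighbor))
}

#' Collapse non-R-M leaf neighbors of a hub into one aggregate node
#'
#' Merges every non-R-M neighbor of `hub_label` whose only connection in
#' the network is the hub into a single aggregate node (emulating the
#' single shape summarizing dozens of unrelated domains around a
#' methylase hub). The aggregate records the number of merged labels in
#' the `merged_count` vertex attribute; aggregated edges carry the union
#' of the merged genera sets per direction.
#'
#' @param graph igraph as from [buildNetwork()].
#' @param hub_label node name to collapse around.
#' @param aggregate_label name of the aggregate node (default
#'   `"non-RM (<n>)"`).
#' @return The modified igraph (unchanged when there are no such leaves).
#' @export
collapseNonRMNeighbors <- function(graph, hub_label,
                                   aggregate_label = NULL) {
  names_v <- igraph::vertex_attr(graph, "name")
  hub <- match(hub_label, names_v)
  if (is.na(hub)) stopf("hub node '%s' not present in network", hub_label)
  isRM <- nzchar(igraph::vertex_attr(graph, "rm_types"))
  nb <- as.integer(igraph::neighbors(graph, hub, mode = "all"))
  adjacentOnlyToHub <- vapply(nb, function(v) {
    others <- setdiff(as.integer(igraph::neighbors(graph, v, mode = "all")),
                      hub)
    length(others) == 0L
  }, logical(1))
  leaves <- nb[!isRM[nb] & adjacentOnlyToHub]
  leaves <- setdiff(leaves, hub)
  if (!length(leaves)) return(graph)
  nmerged <- length(unique(names_v[leaves]))
  label <- aggregate_label %||% sprintf("non-RM (%d)", nmerged)
  generaUnion <- function(vs, mode) {
    gen <- character()
    for (v in vs) {
      es <- igraph::incident(graph, v, mode = mode)
      for (e in as.integer(es))
        gen <- union(gen, igraph::edge_attr(graph, "genera")[[e]])
    }
    sort(gen)
  }
  genOut <- generaUnion(leaves, "out")   # leaf -> hub edges
  genIn <- generaUnion(leaves, "in")     # hub -> leaf edges
  g <- igraph::delete_vertices(graph, leaves)
  g <- igraph::add_vertices(g, 1, name = label, rm_types = "",
                            merged_count = nmerged)
  agg <- igraph::vcount(g)
  hub2 <- match(hub_label, igraph::vertex_attr(g, "name"))
  if (length(genOut))
    g <- igraph::add_edges(g, c(agg, hub2),
                           attr = list(weight = length(genOut),
                                       genera = list(genOut)))
  if (length(genIn))
    g <- igraph::add_edges(g, c(hub2, agg),
                           attr = list(weight = length(genIn),
                                       genera = list(genIn)))
  g
}
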