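#' Build a typed term co-occurrence network
#'
#' Each matched MeSH term (disease or digital-health term) becomes a node
#' and an edge between two nodes represents co-occurrence of the two terms
#' within the same records. Node attributes: `label` (display casing),
#' `node_type` (the term's vocabulary category) and `count` (occurrence
#' count — drives node sizing downstream); edge attribute `weight` (the
#' co-occurrence count — drives edge width). Layout, colouring and sizing
#' are attribute-driven downstream concerns (e.g. in Cytoscape); no
#' coordinates are computed.
#'
#' @param occ_tables A `count_table` or list of them (one per vocabulary);
#'   every term in `cooc` must appear in one of them. A term present in
#'   several tables keeps the category of the first.
#' @param cooc A `cooccurrence_table`.
#' @param edge_threshold Keep pairs with count >= this (default 1).
#' @param include_isolated Also include matched terms (occurrence count >= 1)
#'   that end up with no retained edge (default `FALSE`).
#' @return An undirected [igraph::igraph] with vertices ordered by term and
#'   edges in canonical pair order; no self-loops, one edge per unordered
#'   pair.
#' @export
build_network <- function(occ_tables, cooc, edge_threshold = 1L,
                          include_isolated = FALSE) {
  if (inherits(occ_tables, "count_table")) occ_tables <- list(occ_tables)
  stopifnot(
    length(occ_tables) > 0,
    all(vapply(occ_tables, inherits, logical(1), "count_table")),
    inherits(cooc, "cooccurrence_table"),
    edge_threshold >= 1
  )
  occ <- integer(0)
  node_type <- character(0)
  label <- character(0)
  for (tab in occ_tables) {
    labs <- attr(tab, "labels")
    new <- setdiff(tab$term, names(occ))
    occ[new] <- tab$count[match(new, tab$term)]
    node_type[new] <- attr(tab, "category") %||% "term"
    label[new] <- unname(labs[new])
  }
  missing <- setdiff(unique(c(cooc$term_a, cooc$term_b)), names(occ))
  if (length(missing)) {
    rlang::abort(paste0(
      "co-occurrence term(s) missing from all occurrence tables: ",
      paste(missing, collapse = ", ")
    ))
  }
  edges <- cooc[cooc$count >= edge_threshold, , drop = FALSE]
  nodes <- unique(c(edges$term_a, edges$term_b))
  if (include_isolated) nodes <- unique(c(nodes, names(occ)[occ >= 1]))
  nodes <- sort_c(nodes)
  edges <- edges[order(edges$term_a, edges$term_b, method = "radix"), , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(
    g, length(nodes),
    name = nodes,
    label = unname(label[nodes]),
    node_type = unname(node_type[nodes]),
    count = unname(occ[nodes])
  )
  if (nrow(edges)) {
    g <- igraph::add_edges(
      g, rbind(match(edges$term_a, nodes), match(edges$term_b, nodes)),
      weight = as.numeric(edges$count)
    )
  }
  g
}

#' First-degree-neighbour subnetwork
#'
#' Selects the seed nodes plus their direct neighbours and returns the
#' induced subgraph on that node set: every edge of the parent network whose
#' endpoints are both retained is present (including neighbour–neighbour
#' edges, matching Cytoscape's "first neighbors -> new network from
#' selection"). Seed nodes are re-typed `"selected"` in the output; the
#' input network is unmodified.
#'
#' @param net A network from [build_network()].
#' @param seed_nodes Character vector of node ids (normalized terms).
#' @return The induced subnetwork, vertices in parent order.
#' @export
first_degree_subnetwork <- function(net, seed_nodes) {
  seed_nodes <- unique(as.character(seed_nodes))
  known <- igraph::V(net)$name
  unknown <- setdiff(seed_nodes, known)
  if (length(unknown)) {
    rlang::abort(paste0(
      "seed node(s) not in network: ", paste(unknown, collapse = ", ")
    ))
  }
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(net, seed_nodes),
    function(v) v$name
  ), use.names = FALSE))
  keep <- known[known %in% union(seed_nodes, nbrs)]
  sub <- igraph::induced_subgraph(net, vids = keep)
  sel <- igraph::V(sub)$name %in% seed_nodes
  sub <- igraph::set_vertex_attr(sub, "node_type",
    index = which(sel), value = "selected"
  )
  sub
}

#' Export a network for Cytoscape
#'
#' `export_graphml()` writes GraphML with `label`, `node_type` and `count`
#' node attributes and the `weight` edge attribute declared as typed keys.
#' `export_sif()` writes a simple-interaction-format file with relation tag
#' `cooccurs_with`, tab-delimited because MeSH terms contain spaces.
#' `export_attributes()` writes node and edge attribute TSVs keyed by term /
#' term pair. All element orders follow the network's deterministic vertex
#' and edge order, so re-exporting an identical network is byte-identical.
#'
#' @param net A network from [build_network()].
#' @param path,node_path,edge_path Output paths.
#' @return The output path(s), invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_sif <- function(net, path) {
  el <- igraph::as_edgelist(net)
  lines <- if (nrow(el)) {
    paste(el[, 1], "cooccurs_with", el[, 2], sep = "\t")
  } else {
    character(0)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_attributes <- function(net, node_path, edge_path) {
  nodes <- tibble::tibble(
    node = igraph::V(net)$name,
    label = igraph::V(net)$label,
    node_type = igraph::V(net)$node_type,
    count = igraph::V(net)$count
  )
  el <- igraph::as_edgelist(net)
  edges <- tibble::tibble(
    term_a = if (nrow(el)) el[, 1] else character(0),
    term_b = if (nrow(el)) el[, 2] else character(0),
    weight = if (igraph::ecount(net)) igraph::E(net)$weight else numeric(0)
  )
  readr::write_tsv(nodes, node_path)
  readr::write_tsv(edges, edge_path)
  invisible(c(node_path, edge_path))
}
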