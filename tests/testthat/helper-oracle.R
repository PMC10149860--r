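# Independent brute-force oracles, deliberately written with plain loops
# and without reusing the package's matching/counting internals.

oracle_normalize <- function(x) {
  x <- sub("/.*$", "", as.character(x))
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

oracle_matched <- function(descriptors, terms) {
  norm <- oracle_normalize(descriptors)
  res <- character(0)
  for (t in terms) {
    for (d in norm) {
      if (identical(d, t)) {
        res <- c(res, t)
        break
      }
    }
  }
  res
}

oracle_occurrences <- function(corpus, terms) {
  counts <- stats::setNames(integer(length(terms)), terms)
  for (i in seq_len(nrow(corpus))) {
    for (t in oracle_matched(corpus$descriptors[[i]], terms)) {
      counts[t] <- counts[t] + 1L
    }
  }
  counts
}

oracle_by_year <- function(corpus, terms, years) {
  counts <- matrix(0L,
    nrow = length(terms), ncol = length(years),
    dimnames = list(terms, as.character(years))
  )
  for (i in seq_len(nrow(corpus))) {
    y <- corpus$year[i]
    if (is.na(y) || !(y %in% years)) next
    for (t in oracle_matched(corpus$descriptors[[i]], terms)) {
      counts[t, as.character(y)] <- counts[t, as.character(y)] + 1L
    }
  }
  counts
}

oracle_cooccurrences <- function(corpus, terms_a, terms_b) {
  counts <- list()
  for (i in seq_len(nrow(corpus))) {
    a_hits <- oracle_matched(corpus$descriptors[[i]], terms_a)
    b_hits <- oracle_matched(corpus$descriptors[[i]], terms_b)
    seen <- character(0)
    for (a in a_hits) {
      for (b in b_hits) {
        if (a == b) next
        lo <- if (a < b) a else b
        hi <- if (a < b) b else a
        key <- paste0(lo, "\r", hi)
        if (key %in% seen) next
        seen <- c(seen, key)
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

# Compare a cooccurrence_table to the oracle's keyed list.
cooc_matches_oracle <- function(tab, oracle) {
  keys <- if (nrow(tab) == 0) character(0) else paste0(tab$term_a, "\r", tab$term_b)
  got <- stats::setNames(as.integer(tab$count), keys)
  if (length(got) != length(oracle)) {
    return(FALSE)
  }
  all(names(oracle) %in% names(got)) &&
    all(vapply(names(oracle), function(k) got[[k]] == oracle[[k]], logical(1)))
}

# Brute-force first-degree neighbourhood: seeds plus any node sharing an
# edge with a seed, and every edge with both endpoints retained.
oracle_subnetwork <- function(edges, seeds) {
  keep_nodes <- seeds
  for (i in seq_len(nrow(edges))) {
    if (edges$a[i] %in% seeds) keep_nodes <- c(keep_nodes, edges$b[i])
    if (edges$b[i] %in% seeds) keep_nodes <- c(keep_nodes, edges$a[i])
  }
  keep_nodes <- unique(keep_nodes)
  keep_edges <- edges[edges$a %in% keep_nodes & edges$b %in% keep_nodes, , drop = FALSE]
  list(nodes = sort(keep_nodes), edges = keep_edges)
}

# Minimal GraphML reader on xml2, independent of igraph's parser.
read_graphml_simple <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(
    xml2::xml_attr(keys, "attr.name"),
    xml2::xml_attr(keys, "id")
  )
  get_data <- function(node) {
    data <- xml2::xml_find_all(node, "./data")
    stats::setNames(
      xml2::xml_text(data),
      unname(key_name[xml2::xml_attr(data, "key")])
    )
  }
  node_els <- xml2::xml_find_all(doc, ".//node")
  nodes <- lapply(node_els, get_data)
  names(nodes) <- vapply(nodes, function(d) d[["name"]], character(1))
  edge_els <- xml2::xml_find_all(doc, ".//edge")
  node_ids <- xml2::xml_attr(node_els, "id")
  edges <- lapply(edge_els, function(e) {
    d <- get_data(e)
    list(
      a = nodes[[match(xml2::xml_attr(e, "source"), node_ids)]][["name"]],
      b = nodes[[match(xml2::xml_attr(e, "target"), node_ids)]][["name"]],
      weight = as.numeric(d[["weight"]])
    )
  })
  list(nodes = nodes, edges = edges)
}
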