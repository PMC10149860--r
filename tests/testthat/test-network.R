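# Networks are built from tiny hand-made tables plus random corpora; the
# subnetwork rule is checked against a brute-force neighbourhood oracle.

occ_table_for <- function(counts, category = "digital_health") {
  v <- vocabulary("tab", category, names(counts))
  corpus <- pm_corpus(
    pmid = sprintf("z%04d", seq_len(max(counts))),
    year = 2015L, has_abstract = TRUE,
    descriptors = lapply(seq_len(max(counts)), function(i) {
      names(counts)[counts >= i]
    }),
    affiliations = rep(list("UK"), max(counts))
  )
  count_occurrences(corpus, v)
}

cooc_table_for <- function(pairs) {
  # pairs: data.frame term_a, term_b, count (already canonical)
  out <- tibble::new_tibble(
    tibble::as_tibble(pairs),
    class = "cooccurrence_table", nrow = nrow(pairs)
  )
  attr(out, "left_vocab") <- "tab"
  attr(out, "right_vocab") <- "tab"
  out
}

test_that("a single co-occurring pair becomes two nodes and one weighted edge", {
  occ <- occ_table_for(c(alpha = 3L, xray = 2L))
  cooc <- cooc_table_for(data.frame(term_a = "alpha", term_b = "xray", count = 2L))
  net <- build_network(occ, cooc, edge_threshold = 1)
  expect_equal(igraph::vcount(net), 2)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$weight, 2)
  expect_equal(sort(igraph::V(net)$name), c("alpha", "xray"))
  expect_equal(igraph::V(net)$count[igraph::V(net)$name == "alpha"], 3)
  expect_equal(unique(igraph::V(net)$node_type), "digital_health")
})

test_that("edges below the threshold vanish; isolated nodes are opt-in", {
  occ <- occ_table_for(c(alpha = 3L, xray = 2L))
  cooc <- cooc_table_for(data.frame(term_a = "alpha", term_b = "xray", count = 2L))
  empty <- build_network(occ, cooc, edge_threshold = 3, include_isolated = FALSE)
  expect_equal(igraph::vcount(empty), 0)
  expect_equal(igraph::ecount(empty), 0)
  nodes_only <- build_network(occ, cooc, edge_threshold = 3, include_isolated = TRUE)
  expect_equal(igraph::vcount(nodes_only), 2)
  expect_equal(igraph::ecount(nodes_only), 0)
})

test_that("a pair term absent from every occurrence table is an error", {
  occ <- occ_table_for(c(alpha = 1L))
  cooc <- cooc_table_for(data.frame(term_a = "alpha", term_b = "ghost", count = 1L))
  expect_error(build_network(occ, cooc), "ghost")
})

test_that("edge weights equal the pair counts exactly", {
  set.seed(51)
  corpus <- random_corpus(80)
  v <- vocabulary("toy", "digital_health", LETTERS[1:6])
  occ <- count_occurrences(corpus, v)
  cooc <- count_cooccurrences(corpus, v)
  net <- build_network(occ, cooc, edge_threshold = 1)
  el <- igraph::as_edgelist(net)
  for (k in seq_len(nrow(el))) {
    lo <- min(el[k, ])
    hi <- max(el[k, ])
    expect_equal(
      igraph::E(net)$weight[k],
      cooc$count[cooc$term_a == lo & cooc$term_b == hi]
    )
  }
  expect_equal(igraph::ecount(net), nrow(cooc))
})

test_that("raising the edge threshold never adds nodes or edges", {
  set.seed(52)
  corpus <- random_corpus(80)
  v <- vocabulary("toy", "digital_health", LETTERS[1:6])
  occ <- count_occurrences(corpus, v)
  cooc <- count_cooccurrences(corpus, v)
  prev_nodes <- Inf
  prev_edges <- Inf
  for (thr in 1:6) {
    net <- build_network(occ, cooc, edge_threshold = thr)
    expect_lte(igraph::vcount(net), prev_nodes)
    expect_lte(igraph::ecount(net), prev_edges)
    prev_nodes <- igraph::vcount(net)
    prev_edges <- igraph::ecount(net)
  }
})

star_network <- function() {
  occ <- occ_table_for(c(centre = 5L, leaf1 = 1L, leaf2 = 1L, leaf3 = 1L, leaf4 = 1L))
  cooc <- cooc_table_for(data.frame(
    term_a = rep("centre", 4),
    term_b = paste0("leaf", 1:4),
    count = 1L
  ))
  build_network(occ, cooc)
}

test_that("seeding the centre of a star keeps the whole star", {
  net <- star_network()
  sub <- first_degree_subnetwork(net, "centre")
  expect_equal(igraph::vcount(sub), 5)
  expect_equal(igraph::ecount(sub), 4)
  expect_equal(
    igraph::V(sub)$node_type[igraph::V(sub)$name == "centre"],
    "selected"
  )
  expect_true(all(
    igraph::V(sub)$node_type[igraph::V(sub)$name != "centre"] == "digital_health"
  ))
})

test_that("on a path a-b-c, seeding a excludes c and the far edge", {
  occ <- occ_table_for(c(a = 1L, b = 1L, c = 1L))
  cooc <- cooc_table_for(data.frame(
    term_a = c("a", "b"), term_b = c("b", "c"), count = 1L
  ))
  net <- build_network(occ, cooc)
  sub <- first_degree_subnetwork(net, "a")
  expect_setequal(igraph::V(sub)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub), 1)
})

test_that("seeding every node returns the full network recoloured", {
  net <- star_network()
  sub <- first_degree_subnetwork(net, igraph::V(net)$name)
  expect_equal(igraph::vcount(sub), igraph::vcount(net))
  expect_equal(igraph::ecount(sub), igraph::ecount(net))
  expect_true(all(igraph::V(sub)$node_type == "selected"))
  # input unmodified
  expect_false(any(igraph::V(net)$node_type == "selected"))
})

test_that("unknown seed nodes are reported by id", {
  expect_error(first_degree_subnetwork(star_network(), c("centre", "ghost")), "ghost")
})

test_that("subnetworks equal the brute-force induced neighbourhood on random graphs", {
  set.seed(53)
  for (rep in 1:15) {
    n_nodes <- sample(5:30, 1)
    ids <- sprintf("n%02d", seq_len(n_nodes))
    all_pairs <- t(utils::combn(ids, 2))
    pick <- stats::runif(nrow(all_pairs)) < 0.15
    edges <- data.frame(
      a = all_pairs[pick, 1], b = all_pairs[pick, 2],
      stringsAsFactors = FALSE
    )
    occ <- occ_table_for(stats::setNames(rep(1L, n_nodes), ids))
    cooc <- cooc_table_for(data.frame(
      term_a = edges$a, term_b = edges$b,
      count = sample(1:5, nrow(edges), replace = TRUE)
    ))
    net <- build_network(occ, cooc, include_isolated = TRUE)
    seeds <- sample(ids, sample(1:3, 1))
    sub <- first_degree_subnetwork(net, seeds)
    want <- oracle_subnetwork(edges, seeds)
    expect_setequal(igraph::V(sub)$name, want$nodes)
    got_edges <- igraph::as_edgelist(sub)
    got_keys <- sort(paste(pmin(got_edges[, 1], got_edges[, 2]),
      pmax(got_edges[, 1], got_edges[, 2]),
      sep = "~"
    ))
    want_keys <- sort(paste(pmin(want$edges$a, want$edges$b),
      pmax(want$edges$a, want$edges$b),
      sep = "~"
    ))
    expect_equal(got_keys, want_keys)
  }
})

test_that("GraphML round trip preserves structure and all attributes", {
  net <- star_network()
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, path)
  parsed <- read_graphml_simple(path) # independent xml2-based reader
  expect_length(parsed$nodes, igraph::vcount(net))
  expect_length(parsed$edges, igraph::ecount(net))
  for (nm in igraph::V(net)$name) {
    i <- match(nm, igraph::V(net)$name)
    expect_equal(parsed$nodes[[nm]][["label"]], igraph::V(net)$label[i])
    expect_equal(parsed$nodes[[nm]][["node_type"]], igraph::V(net)$node_type[i])
    expect_equal(as.numeric(parsed$nodes[[nm]][["count"]]), igraph::V(net)$count[i])
  }
  weights <- vapply(parsed$edges, function(e) e$weight, numeric(1))
  expect_equal(sort(weights), sort(igraph::E(net)$weight))
})

test_that("SIF output is one tagged line per edge", {
  occ <- occ_table_for(c(alpha = 3L, xray = 2L))
  cooc <- cooc_table_for(data.frame(term_a = "alpha", term_b = "xray", count = 2L))
  net <- build_network(occ, cooc)
  path <- withr::local_tempfile(fileext = ".sif")
  export_sif(net, path)
  expect_equal(readLines(path), "alpha\tcooccurs_with\txray")
})

test_that("attribute tables carry node typing, counts and edge weights", {
  net <- star_network()
  node_path <- withr::local_tempfile(fileext = ".tsv")
  edge_path <- withr::local_tempfile(fileext = ".tsv")
  export_attributes(net, node_path, edge_path)
  nodes <- readr::read_tsv(node_path, show_col_types = FALSE)
  edges <- readr::read_tsv(edge_path, show_col_types = FALSE)
  expect_equal(names(nodes), c("node", "label", "node_type", "count"))
  expect_equal(names(edges), c("term_a", "term_b", "weight"))
  expect_equal(nodes$count[nodes$node == "centre"], 5)
  expect_equal(nrow(edges), 4)
})

test_that("exporting the same network twice is byte-identical", {
  net <- star_network()
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, p1)
  export_graphml(net, p2)
  expect_identical(readLines(p1), readLines(p2))
  s1 <- withr::local_tempfile(fileext = ".sif")
  s2 <- withr::local_tempfile(fileext = ".sif")
  export_sif(net, s1)
  export_sif(net, s2)
  expect_identical(readLines(s1), readLines(s2))
})
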