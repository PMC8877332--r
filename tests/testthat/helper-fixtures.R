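# shared in-code fixtures for the test suite

# named Erdos-Renyi graph
er_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# igraph from an edge string like "A-B,B-C"
mini_graph <- function(edges, isolates = character(0)) {
  prs <- strsplit(strsplit(edges, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  el <- do.call(rbind, prs)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (length(isolates)) g <- igraph::add_vertices(g, length(isolates), name = isolates)
  g
}

# signed GI network from edge specs like c("A-B" = "positive", ...)
mini_gi <- function(signed_edges) {
  prs <- do.call(rbind, strsplit(names(signed_edges), "-", fixed = TRUE))
  df <- data.frame(from = prs[, 1], to = prs[, 2],
                   score = ifelse(signed_edges == "positive", 1, -1),
                   sign = unname(signed_edges), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# sorted comparable key of an occurrence table
occ_key <- function(d) {
  sort(paste(d$source, d$node_set, d$layers, d$composition, d$graph6))
}

# adjacency matrix of a small named graph
adj_of <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  storage.mode(a) <- "integer"
  a
}
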