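# internal: hash index of a network's edges, key "A|B" with A < B -> sign
.gi_index <- function(net) {
  e <- new.env(parent = emptyenv(), hash = TRUE)
  gk <- .gi_keys(net)
  for (i in seq_along(gk$key)) e[[gk$key[i]]] <- gk$sign[i]
  e
}

# internal: map a gene through the complex annotation
#  -> list(id, type) or NULL when the gene must be dropped (multi-complex)
.map_gene <- function(gene, cmap) {
  if (gene %in% cmap$multi) return(NULL)
  cid <- cmap$gene2complex[gene]
  if (!is.na(cid)) list(id = unname(cid), type = "complex")
  else list(id = gene, type = "auxiliary")
}

#' Build the complex-merged interaction network from FNMs
#'
#' Every PPI and GI edge occurring inside any input FNM is mapped through the
#' complex annotation: single-complex genes collapse to their complex node,
#' unannotated genes become auxiliary nodes, and multi-complex genes are
#' omitted. Repeated occurrences of the same gene-level edge in different
#' FNMs each count, so edge attributes accumulate interaction multiplicities.
#'
#' @param fnms deduplicated FNM table ([dedup_fnms()]) or list of node sets.
#' @param cmap complex map ([read_complexes()]).
#' @param ppi PPI network used for enumeration (provides the PPI edges inside
#'   each FNM).
#' @param gi signed GI network (provides GI edges and signs).
#' @return an [igraph::igraph] with vertex attribute `type`
#'   (`"complex"`/`"auxiliary"`) and edge attributes `n_ppi`, `n_gi_pos`,
#'   `n_gi_neg`.
#' @export
build_complex_network <- function(fnms, cmap, ppi, gi) {
  if (is.data.frame(fnms)) fnms <- strsplit(fnms$node_set, ";", fixed = TRUE)
  ppi_idx <- .gi_index(ppi)   # same hash structure; sign values unused
  gi_idx <- .gi_index(gi)
  acc <- new.env(parent = emptyenv(), hash = TRUE)
  bump <- function(a, b, field) {
    if (a == b) return(invisible())   # no complex/aux self-edges
    k <- paste(min(a, b), max(a, b), sep = "\t")
    cur <- acc[[k]]
    if (is.null(cur)) cur <- c(n_ppi = 0L, n_gi_pos = 0L, n_gi_neg = 0L)
    cur[field] <- cur[field] + 1L
    acc[[k]] <- cur
  }
  node_type <- new.env(parent = emptyenv(), hash = TRUE)
  for (nodes in fnms) {
    nodes <- sort(unique(nodes))
    mapped <- lapply(nodes, .map_gene, cmap = cmap)
    kept <- !vapply(mapped, is.null, logical(1L))
    nodes <- nodes[kept]; mapped <- mapped[kept]
    for (m in mapped) node_type[[m$id]] <- m$type
    nn <- length(nodes)
    if (nn < 2L) next
    for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn) {
      key <- paste(nodes[i], nodes[j], sep = "|")
      a <- mapped[[i]]$id; b <- mapped[[j]]$id
      if (!is.null(ppi_idx[[key]])) bump(a, b, "n_ppi")
      sg <- gi_idx[[key]]
      if (!is.null(sg)) bump(a, b, if (sg == "positive") "n_gi_pos" else "n_gi_neg")
    }
  }
  keys <- sort(ls(acc))
  ids <- sort(ls(node_type))
  if (!length(ids)) return(igraph::make_empty_graph(directed = FALSE))
  if (length(keys)) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    cnts <- do.call(rbind, lapply(keys, function(k) acc[[k]]))
    df <- data.frame(from = vapply(parts, `[[`, character(1L), 1L),
                     to = vapply(parts, `[[`, character(1L), 2L),
                     n_ppi = as.integer(cnts[, "n_ppi"]),
                     n_gi_pos = as.integer(cnts[, "n_gi_pos"]),
                     n_gi_neg = as.integer(cnts[, "n_gi_neg"]),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      df, directed = FALSE,
      vertices = data.frame(name = ids,
                            type = vapply(ids, function(i) node_type[[i]],
                                          character(1L)),
                            stringsAsFactors = FALSE))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, length(ids), name = ids,
                              type = vapply(ids, function(i) node_type[[i]],
                                            character(1L)))
  }
  g
}

#' Consensus genetic interactions between complex pairs
#'
#' For each pair of complex nodes with at least one GI, the consensus score
#' is `(n_pos - n_neg) / (n_pos + n_neg)` in `[-1, 1]`; `|score| = 1` iff all
#' aggregated interactions share one sign. Also returns the three-way
#' partition of complex-complex edges into both-PPI-and-GI, PPI-only and
#' GI-only fractions.
#'
#' @param cnet complex network ([build_complex_network()]).
#' @return list with `scores` (data.frame `complex_a`, `complex_b`, `n_pos`,
#'   `n_neg`, `score`) and `overlap` (named fractions `both`, `ppi_only`,
#'   `gi_only`).
#' @export
consensus_gi <- function(cnet) {
  empty <- list(scores = data.frame(complex_a = character(0),
                                    complex_b = character(0),
                                    n_pos = integer(0), n_neg = integer(0),
                                    score = numeric(0)),
                overlap = c(both = NA_real_, ppi_only = NA_real_,
                            gi_only = NA_real_),
                n_complex_edges = 0L)
  if (igraph::ecount(cnet) == 0L) return(empty)
  el <- igraph::as_edgelist(cnet)
  type <- igraph::vertex_attr(cnet, "type")
  names(type) <- igraph::V(cnet)$name
  cc <- type[el[, 1L]] == "complex" & type[el[, 2L]] == "complex"
  n_ppi <- igraph::edge_attr(cnet, "n_ppi")
  n_pos <- igraph::edge_attr(cnet, "n_gi_pos")
  n_neg <- igraph::edge_attr(cnet, "n_gi_neg")
  if (!any(cc)) return(empty)
  a <- pmin(el[cc, 1L], el[cc, 2L]); b <- pmax(el[cc, 1L], el[cc, 2L])
  p <- n_pos[cc]; q <- n_neg[cc]; pp <- n_ppi[cc]
  has_gi <- (p + q) > 0L
  scores <- data.frame(complex_a = a[has_gi], complex_b = b[has_gi],
                       n_pos = p[has_gi], n_neg = q[has_gi],
                       score = (p[has_gi] - q[has_gi]) / (p[has_gi] + q[has_gi]),
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$complex_a, scores$complex_b), ]
  rownames(scores) <- NULL
  both <- pp > 0L & has_gi
  ppi_only <- pp > 0L & !has_gi
  gi_only <- pp == 0L & has_gi
  n_edges <- sum(cc)
  list(scores = scores,
       overlap = c(both = sum(both) / n_edges,
                   ppi_only = sum(ppi_only) / n_edges,
                   gi_only = sum(gi_only) / n_edges),
       n_complex_edges = as.integer(n_edges))
}

#' Betweenness centrality restricted to complex-pair shortest paths
#'
#' For every node v outside the endpoint set, sums over unordered endpoint
#' pairs (s, t) the fraction of shortest s-t paths passing through v
#' (unweighted paths, raw unnormalized pair dependencies; disconnected pairs
#' contribute 0). This highlights auxiliary genes mediating communication
#' between protein complexes.
#'
#' @param net an [igraph::igraph] network.
#' @param endpoints character vector of endpoint (complex) node names.
#' @return named numeric vector over all non-endpoint nodes.
#' @export
restricted_betweenness <- function(net, endpoints) {
  nm <- sort(igraph::V(net)$name)
  endpoints <- intersect(unique(endpoints), nm)
  idx <- .network_index(net)
  n <- idx$n
  ep <- match(endpoints, idx$names)
  is_ep <- rep(FALSE, n); is_ep[ep] <- TRUE
  B <- numeric(n)
  for (s in ep) {
    # Brandes single-source stage with targets restricted to endpoints
    dist <- rep(-1L, n); sigma <- numeric(n); preds <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    order_v <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_v <- c(order_v, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in idx$adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_v)) {
      if (w == s) next
      coeff <- (if (is_ep[w]) 1 else 0) + delta[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] / sigma[w] * coeff
    }
    keep <- !is_ep & delta > 0
    B[keep] <- B[keep] + delta[keep]
  }
  B <- B / 2
  out <- B[!is_ep]
  names(out) <- idx$names[!is_ep]
  out
}

#' Rank auxiliary nodes by restricted betweenness across networks
#'
#' Computes the complex-pair-restricted betweenness distribution of auxiliary
#' nodes for each supplied network, reports total and effective (non-zero
#' centrality) auxiliary node counts, a top-N ranking, and pairwise
#' Wilcoxon-Mann-Whitney comparisons of the distributions.
#'
#' @param networks named list; each element a list with `net` (igraph) and
#'   `endpoints` (complex node names).
#' @param top_n number of top-ranked nodes to report per network.
#' @return list with `values` (per-network named centrality vectors),
#'   `sizes` (data.frame: network, n_aux, n_effective), `top` (data.frame of
#'   top-ranked nodes), `comparisons` (data.frame of pairwise WMW tests).
#' @export
rank_auxiliary <- function(networks, top_n = 10) {
  stopifnot(is.list(networks), length(networks) >= 1, !is.null(names(networks)))
  values <- lapply(networks, function(x) restricted_betweenness(x$net, x$endpoints))
  sizes <- data.frame(network = names(networks),
                      n_aux = vapply(values, length, integer(1L)),
                      n_effective = vapply(values, function(v) sum(v > 0), integer(1L)),
                      stringsAsFactors = FALSE)
  top <- do.call(rbind, lapply(names(values), function(nw) {
    v <- sort(values[[nw]], decreasing = TRUE)
    v <- utils::head(v, top_n)
    if (!length(v)) return(NULL)
    data.frame(network = nw, rank = seq_along(v), gene = names(v),
               betweenness = unname(v), stringsAsFactors = FALSE)
  }))
  comps <- NULL
  nws <- names(values)
  if (length(nws) >= 2L) {
    prs <- utils::combn(nws, 2L)
    comps <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- prs[1L, i]; b <- prs[2L, i]
      if (!length(values[[a]]) || !length(values[[b]])) return(NULL)
      mw <- mann_whitney_u(values[[a]], values[[b]])
      data.frame(network_a = a, network_b = b, U = mw$U, p = mw$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(values = values, sizes = sizes, top = top, comparisons = comps)
}

#' Merge complex subunits into joint nodes on a plain PPI network
#'
#' Comparison-network constructor for [rank_auxiliary()]: collapses
#' single-complex genes of a PPI network into complex nodes (multi-complex
#' genes dropped), keeping remaining genes as auxiliary nodes; parallel edges
#' and self-edges from the merge are removed.
#'
#' @param net PPI network.
#' @param cmap complex map.
#' @return list with `net` (merged igraph with `type` vertex attribute) and
#'   `endpoints` (complex node names).
#' @export
merge_complex_nodes <- function(net, cmap) {
  el <- igraph::as_edgelist(net)
  map1 <- lapply(el[, 1L], .map_gene, cmap = cmap)
  map2 <- lapply(el[, 2L], .map_gene, cmap = cmap)
  keep <- !vapply(map1, is.null, logical(1L)) & !vapply(map2, is.null, logical(1L))
  a <- vapply(map1[keep], `[[`, character(1L), "id")
  b <- vapply(map2[keep], `[[`, character(1L), "id")
  ta <- vapply(map1[keep], `[[`, character(1L), "type")
  tb <- vapply(map2[keep], `[[`, character(1L), "type")
  ids <- unique(c(a, b))
  types <- c(stats::setNames(ta, a), stats::setNames(tb, b))
  types <- types[ids]
  sel <- a != b
  g <- .make_network(a[sel], b[sel])
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  igraph::V(g)$type <- unname(types[igraph::V(g)$name])
  list(net = g, endpoints = sort(names(types)[types == "complex"]))
}

#' FNMs bridging two gene systems
#'
#' Selects FNMs containing at least one gene of each input set (e.g.
#' transcription factors and metabolic enzymes) and groups the selected FNMs
#' into connected components by shared genes ("interlinked" FNMs).
#'
#' @param fnms deduplicated FNM table or list of node sets.
#' @param set_a,set_b character gene sets.
#' @return list of groups; each a list with `members` (indices into the
#'   selected FNMs), `fnm_ids` (indices into the input), `genes` (union).
#' @export
bridging_fnms <- function(fnms, set_a, set_b) {
  if (is.data.frame(fnms)) fnms <- strsplit(fnms$node_set, ";", fixed = TRUE)
  set_a <- toupper(set_a); set_b <- toupper(set_b)
  sel <- which(vapply(fnms, function(g) any(g %in% set_a) && any(g %in% set_b),
                      logical(1L)))
  if (!length(sel)) return(list())
  sets <- fnms[sel]
  ns <- length(sets)
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    if (any(sets[[i]] %in% sets[[j]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1L))
  lapply(unname(split(seq_len(ns), roots)), function(ix) {
    list(members = ix, fnm_ids = sel[ix],
         genes = sort(unique(unlist(sets[ix]))))
  })
}
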