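#' Layer compositions of a motif size
#'
#' Every connected graphlet rooted at a source node has a unique layering by
#' BFS distance from the source; the layer sizes form an integer composition
#' (1, c_1, ..., c_L) of k with a singleton first layer. These compositions
#' are the enumeration classes of the layered depth-first search.
#'
#' @param k motif size, 2 <= k <= 8.
#' @return list of integer vectors in lexicographic order; length `2^(k-2)`.
#' @export
#' @examples
#' layer_compositions(3)  # (1,1,1), (1,2)
layer_compositions <- function(k) {
  if (!is.numeric(k) || k < 2) stop("k must be an integer >= 2")
  if (k > 8) stop("k must be <= 8")
  k <- as.integer(k)
  comp <- function(m) {
    if (m == 0L) return(list(integer(0)))
    out <- list()
    for (a in seq_len(m)) {
      for (rest in comp(m - a)) out[[length(out) + 1L]] <- c(a, rest)
    }
    out
  }
  lapply(comp(k - 1L), function(x) c(1L, x))
}

# internal: indexed adjacency view of an igraph network, nodes sorted by name;
# the dense logical matrix `amat` doubles as a fast induced-subgraph extractor
.network_index <- function(net) {
  nm <- sort(igraph::V(net)$name)
  n <- length(nm)
  adj <- rep(list(integer(0)), max(n, 1L))
  el <- igraph::as_edgelist(net)
  amat <- if (n <= 3000L) matrix(FALSE, n, n) else NULL
  if (nrow(el)) {
    a <- match(el[, 1L], nm); b <- match(el[, 2L], nm)
    for (r in seq_len(nrow(el))) {
      adj[[a[r]]] <- c(adj[[a[r]]], b[r])
      adj[[b[r]]] <- c(adj[[b[r]]], a[r])
    }
    adj <- lapply(adj, function(x) sort.int(unique(x)))
    if (!is.null(amat)) {
      amat[cbind(a, b)] <- TRUE
      amat[cbind(b, a)] <- TRUE
    }
  }
  list(names = nm, adj = adj, n = n, amat = amat)
}

# internal: induced adjacency among node indices `ord` (sorted)
.induced_adj <- function(idx, ord) {
  if (!is.null(idx$amat)) return(idx$amat[ord, ord, drop = FALSE])
  k <- length(ord)
  adjm <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    nb <- idx$adj[[ord[i]]]
    for (j in (i + 1L):k) if (ord[j] %in% nb) adjm[i, j] <- adjm[j, i] <- TRUE
  }
  adjm
}

# internal: row accumulator with doubling growth
.new_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$cap <- 256L
  e$source <- character(256L); e$k <- integer(256L)
  e$composition <- character(256L); e$layers <- character(256L)
  e$node_set <- character(256L); e$graph6 <- character(256L)
  e
}

.acc_push <- function(e, source, k, composition, layers, node_set, graph6) {
  if (e$n == e$cap) {
    e$cap <- e$cap * 2L
    for (f in c("source", "composition", "layers", "node_set", "graph6"))
      e[[f]] <- c(e[[f]], character(e$cap / 2L))
    e$k <- c(e$k, integer(e$cap / 2L))
  }
  i <- e$n + 1L
  e$source[i] <- source; e$k[i] <- k; e$composition[i] <- composition
  e$layers[i] <- layers; e$node_set[i] <- node_set; e$graph6[i] <- graph6
  e$n <- i
}

.acc_df <- function(e) {
  i <- seq_len(e$n)
  data.frame(source = e$source[i], k = e$k[i], composition = e$composition[i],
             layers = e$layers[i], node_set = e$node_set[i],
             graph6 = e$graph6[i], stringsAsFactors = FALSE)
}

# internal: full-record emitter used by the public enumeration functions
.make_table_emitter <- function(acc, idx) {
  function(layers, k) {
    nodes <- unlist(layers, use.names = FALSE)
    ord <- sort.int(nodes)
    g6 <- canonical_topology(.induced_adj(idx, ord))
    depth <- integer(k)
    depth[match(nodes, ord)] <- rep(seq_along(layers) - 1L, lengths(layers))
    nm <- idx$names[ord]
    .acc_push(acc,
              source = idx$names[layers[[1L]]],
              k = k,
              composition = paste(lengths(layers), collapse = ","),
              layers = paste(nm, depth, sep = ":", collapse = ";"),
              node_set = paste(nm, collapse = ";"),
              graph6 = g6)
  }
}

# internal: topology-count emitter (used by null-model replicates, where the
# per-occurrence strings are never consumed)
.make_count_emitter <- function(counter, idx) {
  function(layers, k) {
    ord <- sort.int(unlist(layers, use.names = FALSE))
    g6 <- canonical_topology(.induced_adj(idx, ord))
    cur <- counter[[g6]]
    counter[[g6]] <- if (is.null(cur)) 1L else cur + 1L
  }
}

# internal: recursive layered DFS from one source (integer index); calls
# emit(layers, k) once per connected induced k-subgraph containing the source
.enumerate_source <- function(idx, s, k, emit) {
  n <- idx$n
  recurse <- function(layers, used, nbr_prev, remaining) {
    last <- layers[[length(layers)]]
    cand <- unique(unlist(idx$adj[last], use.names = FALSE))
    cand <- cand[!used[cand] & !nbr_prev[cand]]
    if (!length(cand)) return(invisible())
    cand <- sort.int(cand)
    nbr_next <- nbr_prev
    nbr_next[last] <- TRUE
    for (v in last) nbr_next[idx$adj[[v]]] <- TRUE
    maxc <- min(remaining, length(cand))
    for (csize in seq_len(maxc)) {
      subsets <- if (csize == length(cand)) matrix(cand, ncol = 1L)
                 else utils::combn(cand, csize)
      for (ci in seq_len(ncol(subsets))) {
        layer <- subsets[, ci]
        new_layers <- c(layers, list(layer))
        if (csize == remaining) {
          emit(new_layers, k)
        } else {
          used2 <- used
          used2[layer] <- TRUE
          recurse(new_layers, used2, nbr_next, remaining - csize)
        }
      }
    }
    invisible()
  }
  used <- rep(FALSE, n); used[s] <- TRUE
  if (k == 1L) {
    emit(list(s), 1L)
  } else {
    recurse(list(s), used, rep(FALSE, n), k - 1L)
  }
  invisible()
}

#' Enumerate all graphlets of size k rooted at one source node
#'
#' Exhaustive layered depth-first search: starting from the source, each
#' subsequent layer is chosen among the neighbours of the previous layer that
#' are neither already placed nor adjacent to any earlier layer, so the layers
#' realise the BFS distances of the induced subgraph. Every connected induced
#' k-node subgraph containing the source is produced exactly once.
#'
#' @param net an [igraph::igraph] network.
#' @param source source gene identifier (must be a node of `net`).
#' @param k motif size.
#' @return occurrence data.frame with columns `source`, `k`, `composition`
#'   (layer sizes, comma-separated), `layers` (gene:depth assignments),
#'   `node_set` (sorted, `;`-joined), `graph6` (canonical induced topology).
#' @export
enumerate_from_source <- function(net, source, k) {
  idx <- .network_index(net)
  source <- toupper(source)
  s <- match(source, idx$names)
  if (is.na(s)) stop("source node not in network: ", source)
  acc <- .new_acc()
  .enumerate_source(idx, s, as.integer(k), .make_table_emitter(acc, idx))
  .acc_df(acc)
}

#' Enumerate all graphlets of size k from every source node
#'
#' Runs the layered DFS with every node as source. Each unique connected
#' induced k-subgraph appears exactly once per member node used as source, so
#' the per-source occurrence count is k times the number of unique subgraphs.
#' Use [dedup_occurrences()] for the node-set view.
#'
#' @param net an [igraph::igraph] network.
#' @param k motif size (the study uses k = 3, 4, 5, 6).
#' @return per-source occurrence data.frame (see [enumerate_from_source()]).
#' @export
enumerate_graphlets <- function(net, k) {
  idx <- .network_index(net)
  acc <- .new_acc()
  k <- as.integer(k)
  emit <- .make_table_emitter(acc, idx)
  for (s in seq_len(idx$n)) .enumerate_source(idx, s, k, emit)
  .acc_df(acc)
}

#' Per-topology occurrence counts without occurrence records
#'
#' Same census as [enumerate_graphlets()] but tallies only the canonical
#' topology of each occurrence, skipping all per-occurrence bookkeeping.
#' Used for null-model replicates where only counts are needed.
#'
#' @param net an [igraph::igraph] network.
#' @param k motif size.
#' @return named integer vector: canonical graph6 string -> per-source count.
#' @export
count_topologies <- function(net, k) {
  idx <- .network_index(net)
  counter <- new.env(parent = emptyenv(), hash = TRUE)
  k <- as.integer(k)
  emit <- .make_count_emitter(counter, idx)
  for (s in seq_len(idx$n)) .enumerate_source(idx, s, k, emit)
  keys <- sort(ls(counter))
  stats::setNames(vapply(keys, function(x) counter[[x]], integer(1L)), keys)
}

#' Deduplicated node-set view of an occurrence table
#'
#' @param occ per-source occurrence table.
#' @return one row per unique node set, with `n_sources` (number of sources
#'   that produced it) and `sources` (`;`-joined); `source`, `composition` and
#'   `layers` describe the first (lexicographically smallest) source.
#' @export
dedup_occurrences <- function(occ) {
  if (!nrow(occ)) {
    return(cbind(occ, data.frame(n_sources = integer(0), sources = character(0))))
  }
  o <- order(occ$node_set, occ$source)
  occ <- occ[o, , drop = FALSE]
  first <- !duplicated(occ$node_set)
  out <- occ[first, , drop = FALSE]
  out$n_sources <- as.integer(table(occ$node_set)[out$node_set])
  srcs <- split(occ$source, occ$node_set)
  out$sources <- vapply(srcs[out$node_set], paste, character(1L), collapse = ";")
  rownames(out) <- NULL
  out
}

#' Brute-force graphlet census (test oracle)
#'
#' Enumerates all k-node subsets, keeps those inducing a connected subgraph,
#' and layers each by BFS distance from every member source. Quadratic in
#' `choose(n, k)`; intended for small verification networks (n <= 40).
#'
#' @param net an [igraph::igraph] network with at most 40 nodes.
#' @param k motif size.
#' @return occurrence data.frame in the same format as [enumerate_graphlets()].
#' @export
brute_force_census <- function(net, k) {
  idx <- .network_index(net)
  n <- idx$n
  if (n > 40L) stop("brute_force_census is limited to networks with <= 40 nodes")
  k <- as.integer(k)
  acc <- .new_acc()
  emit <- .make_table_emitter(acc, idx)
  if (n < k) return(.acc_df(acc))
  adjm <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adjm[i, idx$adj[[i]]] <- TRUE
  subsets <- utils::combn(n, k)
  for (ci in seq_len(ncol(subsets))) {
    ss <- subsets[, ci]
    a <- adjm[ss, ss, drop = FALSE]
    reach <- c(TRUE, rep(FALSE, k - 1L))
    repeat {
      nxt <- reach | (colSums(a[reach, , drop = FALSE]) > 0L)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    if (!all(reach)) next
    for (si in seq_len(k)) {
      d <- rep(NA_integer_, k)
      d[si] <- 0L
      frontier <- si
      depth <- 0L
      while (length(frontier)) {
        depth <- depth + 1L
        nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0L & is.na(d))
        d[nxt] <- depth
        frontier <- nxt
      }
      layers <- lapply(0L:max(d, na.rm = TRUE), function(dd) ss[which(d == dd)])
      emit(layers, k)
    }
  }
  .acc_df(acc)
}
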