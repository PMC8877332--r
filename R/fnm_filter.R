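# internal: GI edge keys ("A|B", A < B) and signs from a signed GI network
.gi_keys <- function(gi) {
  if (!igraph::ecount(gi)) return(list(key = character(0), sign = character(0)))
  el <- igraph::as_edgelist(gi)
  sg <- igraph::edge_attr(gi, "sign")
  if (is.null(sg)) sg <- rep("negative", nrow(el))
  list(key = paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "|"),
       sign = sg)
}

#' Count genetic-interaction edges among a set of genes
#'
#' Examines all `k(k-1)/2` unordered pairs of the given genes and reports
#' those present in the signed GI network.
#'
#' @param nodes character vector of gene identifiers.
#' @param gi signed GI network ([threshold_gi()]).
#' @return list with `gi_edges` (data.frame `gene_a`, `gene_b`, `sign`),
#'   `pos_count`, `neg_count`.
#' @export
count_gi_edges <- function(nodes, gi) {
  gk <- .gi_keys(gi)
  nodes <- sort(unique(toupper(nodes)))
  k <- length(nodes)
  if (k < 2L) {
    return(list(gi_edges = data.frame(gene_a = character(0), gene_b = character(0),
                                      sign = character(0)),
                pos_count = 0L, neg_count = 0L))
  }
  prs <- utils::combn(nodes, 2L)
  key <- paste(prs[1L, ], prs[2L, ], sep = "|")
  hit <- match(key, gk$key)
  sel <- !is.na(hit)
  sg <- gk$sign[hit[sel]]
  list(gi_edges = data.frame(gene_a = prs[1L, sel], gene_b = prs[2L, sel],
                             sign = sg, stringsAsFactors = FALSE),
       pos_count = sum(sg == "positive"),
       neg_count = sum(sg == "negative"))
}

# internal: precompute, per occurrence row, the node-pair keys and the
# source-to-distant-layer keys, so FNM status can be re-evaluated cheaply
# against many (e.g. rewired) GI networks
.prepare_fnm_eval <- function(occ) {
  nr <- nrow(occ)
  node_lists <- strsplit(occ$node_set, ";", fixed = TRUE)
  kv <- lengths(node_lists)
  # pair index template per k (combn computed once per size)
  tmpl <- lapply(stats::setNames(nm = sort(unique(kv[kv >= 2L]))), function(k)
    utils::combn(as.integer(k), 2L))
  pa <- vector("list", nr); pb <- vector("list", nr)
  sk <- vector("list", nr)
  for (r in seq_len(nr)) {
    nodes <- node_lists[[r]]   # already sorted
    if (kv[r] >= 2L) {
      tp <- tmpl[[as.character(kv[r])]]
      pa[[r]] <- nodes[tp[1L, ]]
      pb[[r]] <- nodes[tp[2L, ]]
    }
    depth <- .parse_layers(occ$layers[r])
    distant <- names(depth)[depth == max(depth)]
    src <- occ$source[r]
    sk[[r]] <- paste(pmin(src, distant), pmax(src, distant), sep = "|")
  }
  pair_a <- unlist(pa, use.names = FALSE)
  pair_b <- unlist(pb, use.names = FALSE)
  list(nr = nr,
       pair_row = rep.int(seq_len(nr), vapply(pa, length, integer(1L))),
       pair_key = paste(pair_a, pair_b, sep = "|"),
       pair_a = pair_a, pair_b = pair_b,
       span_row = rep.int(seq_len(nr), vapply(sk, length, integer(1L))),
       span_key = unlist(sk, use.names = FALSE))
}

# internal: evaluate FNM status for prepared occurrences against one GI net
.eval_fnm <- function(prep, occ, gk, threshold, require_span, annotate = TRUE) {
  hit <- match(prep$pair_key, gk$key)
  present <- !is.na(hit)
  sg <- character(length(hit))
  sg[present] <- gk$sign[hit[present]]
  nr <- prep$nr
  gi_count <- tabulate(prep$pair_row[present], nbins = nr)
  pos <- tabulate(prep$pair_row[sg == "positive"], nbins = nr)
  neg <- tabulate(prep$pair_row[sg == "negative"], nbins = nr)
  span_miss <- is.na(match(prep$span_key, gk$key))
  span_ok <- tabulate(prep$span_row[span_miss], nbins = nr) == 0L
  possible <- (occ$k * (occ$k - 1L)) %/% 2L
  need <- ceiling(threshold * possible)
  out <- occ
  out$gi_count <- gi_count
  out$gi_possible <- possible
  out$pos_count <- pos
  out$neg_count <- neg
  out$gi_fraction <- ifelse(possible > 0L, gi_count / possible, 0)
  out$span_ok <- span_ok
  out$is_fnm <- gi_count >= need & (!require_span | span_ok)
  if (annotate) {
    es <- character(prep$nr)
    if (any(present)) {
      lab <- paste0(prep$pair_a[present], "|", prep$pair_b[present], ":",
                    ifelse(sg[present] == "positive", "+", "-"))
      by_row <- split(lab, prep$pair_row[present])
      es[as.integer(names(by_row))] <- vapply(by_row, paste, character(1L),
                                              collapse = ";")
    }
    out$gi_edges <- es
  }
  out
}

# internal: parse a "gene:depth;..." layer string into a named integer vector
.parse_layers <- function(layers) {
  parts <- strsplit(strsplit(layers, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  depth <- vapply(parts, function(p) as.integer(p[2L]), integer(1L))
  names(depth) <- vapply(parts, `[[`, character(1L), 1L)
  depth
}

#' Classify graphlet occurrences as functional network motifs
#'
#' A graphlet occurrence is a functional network motif (FNM) when (i) at
#' least `threshold` of all possible non-self GI edges among its k nodes are
#' present, implemented as `gi_count >= ceiling(threshold * k(k-1)/2)`, and
#' (ii) the source node has a direct GI with every node of the most distant
#' layer (`require_span`). GI sign does not enter the decision; signs are
#' carried as annotations.
#'
#' @param occ per-source occurrence table ([enumerate_graphlets()]).
#' @param gi signed GI network.
#' @param threshold GI density threshold, default 0.5.
#' @param require_span require source-to-distant-layer GIs, default `TRUE`.
#' @return `occ` with columns `gi_count`, `gi_possible`, `pos_count`,
#'   `neg_count`, `gi_fraction`, `span_ok`, `is_fnm`, `gi_edges`
#'   (serialized `"a|b:+;..."`).
#' @export
find_fnms <- function(occ, gi, threshold = 0.5, require_span = TRUE) {
  if (!nrow(occ)) {
    for (col in c("gi_count", "gi_possible", "pos_count", "neg_count"))
      occ[[col]] <- integer(0)
    occ$gi_fraction <- numeric(0)
    occ$span_ok <- logical(0); occ$is_fnm <- logical(0)
    occ$gi_edges <- character(0)
    return(occ)
  }
  prep <- .prepare_fnm_eval(occ)
  .eval_fnm(prep, occ, .gi_keys(gi), threshold, require_span, annotate = TRUE)
}

#' Deduplicated node-set view of the FNM table
#'
#' Keeps node sets with at least one qualifying source and records all
#' qualifying sources.
#'
#' @param fnm_table output of [find_fnms()].
#' @return one row per unique FNM node set with `n_sources` and `sources`.
#' @export
dedup_fnms <- function(fnm_table) {
  dedup_occurrences(fnm_table[fnm_table$is_fnm, , drop = FALSE])
}
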