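#' @importFrom igraph graph_from_data_frame simplify V E degree delete_vertices
#'   delete_edges vcount ecount as_edgelist edge_attr vertex_attr gcount
#'   make_empty_graph add_vertices write_graph read_graph components induced_subgraph
#' @importFrom stats quantile sd rnorm
#' @importFrom utils combn read.delim write.table head
NULL

# internal: build a simple undirected igraph from a two-column character matrix
.make_network <- function(from, to, extra = NULL) {
  from <- toupper(trimws(as.character(from)))
  to <- toupper(trimws(as.character(to)))
  keep <- from != to & nzchar(from) & nzchar(to)
  from <- from[keep]; to <- to[keep]
  if (!is.null(extra)) extra <- extra[keep, , drop = FALSE]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\t")
  first <- !duplicated(key)
  df <- data.frame(from = a[first], to = b[first], stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra[first, , drop = FALSE])
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g
}

#' Read a protein-protein interaction network
#'
#' Reads either a generic two-column tab-delimited edge list or a BioGRID
#' tab-style file (keyed by column names). Gene identifiers are upper-cased;
#' self-loops and duplicate edges are removed. With `physical_only = TRUE`
#' (BioGRID preset) only rows whose experimental system type is "physical"
#' are kept.
#'
#' @param path input file path.
#' @param preset `"edge_list"` (two tab-separated columns, no header required)
#'   or `"biogrid_tab"` (header with columns
#'   `Systematic Name Interactor A`, `Systematic Name Interactor B`,
#'   `Experimental System Type`).
#' @param physical_only drop non-physical interaction rows (biogrid_tab).
#' @return an undirected simple [igraph::igraph] object.
#' @export
read_ppi <- function(path, preset = c("edge_list", "biogrid_tab"),
                     physical_only = FALSE) {
  preset <- match.arg(preset)
  if (!file.exists(path)) stop("file not found: ", path)
  if (preset == "edge_list") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 2L) stop("edge list requires two tab-separated columns")
    from <- df[[1L]]; to <- df[[2L]]
    # tolerate a header row
    if (nrow(df) && tolower(from[1L]) %in% c("gene_a", "from", "source")) {
      from <- from[-1L]; to <- to[-1L]
    }
  } else {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("Systematic Name Interactor A", "Systematic Name Interactor B",
              "Experimental System Type")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("biogrid_tab file is missing column(s): ",
                           paste(miss, collapse = ", "))
    if (physical_only) df <- df[tolower(df[["Experimental System Type"]]) == "physical", ]
    from <- df[[need[1L]]]; to <- df[[need[2L]]]
  }
  g <- .make_network(from, to)
  if (igraph::ecount(g) == 0L) warning("no edges after filtering: empty network")
  g
}

#' Read a genetic-interaction score table
#'
#' Expects tab-delimited columns `gene_a`, `gene_b`, `score` (header optional
#' in that order). Self-pairs are dropped; duplicate unordered pairs are
#' collapsed to the score of maximal absolute value (strongest evidence).
#'
#' @param path input file path.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, one row per
#'   unordered pair.
#' @export
read_gi_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("GI score table requires columns gene_a, gene_b, score")
  if (tolower(as.character(df[1L, 1L])) %in% c("gene_a", "from", "source"))
    df <- df[-1L, , drop = FALSE]
  out <- data.frame(gene_a = toupper(trimws(df[[1L]])),
                    gene_b = toupper(trimws(df[[2L]])),
                    score = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$score)) stop("non-numeric GI score at line ",
                             which(is.na(out$score))[1L])
  dedup_gi_scores(out)
}

#' Collapse duplicate GI pair measurements
#'
#' Keeps, per unordered gene pair, the score of maximal absolute value; drops
#' self-pairs.
#'
#' @param gi data.frame with columns `gene_a`, `gene_b`, `score`.
#' @return deduplicated data.frame, pairs stored with `gene_a < gene_b`.
#' @export
dedup_gi_scores <- function(gi) {
  a <- pmin(gi$gene_a, gi$gene_b); b <- pmax(gi$gene_a, gi$gene_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- gi$score[keep]
  key <- paste(a, b, sep = "\t")
  o <- order(key, -abs(s))
  first <- !duplicated(key[o])
  out <- data.frame(gene_a = a[o][first], gene_b = b[o][first],
                    score = s[o][first], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Threshold GI scores into a signed genetic-interaction network
#'
#' The top and bottom `tail_fraction` of all pairwise scores are considered
#' significant: pairs with score at or below the lower empirical quantile
#' become negative edges, pairs at or above the upper quantile positive edges.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile`, type 7); comparisons are inclusive.
#'
#' @param gi deduplicated GI score table (see [read_gi_scores()]).
#' @param tail_fraction fraction in (0, 0.5); default 0.05.
#' @return an undirected [igraph::igraph] with edge attributes `score` and
#'   `sign` (`"positive"`/`"negative"`).
#' @export
threshold_gi <- function(gi, tail_fraction = 0.05) {
  stopifnot(is.data.frame(gi), nrow(gi) > 0L,
            tail_fraction > 0, tail_fraction < 0.5)
  if (length(unique(gi$score)) == 1L)
    stop("all GI scores identical: quantile thresholds are degenerate")
  lo <- stats::quantile(gi$score, tail_fraction, names = FALSE)
  hi <- stats::quantile(gi$score, 1 - tail_fraction, names = FALSE)
  neg <- gi$score <= lo
  pos <- gi$score >= hi
  keep <- neg | pos
  g <- .make_network(gi$gene_a[keep], gi$gene_b[keep],
                     data.frame(score = gi$score[keep],
                                sign = ifelse(neg[keep], "negative", "positive"),
                                stringsAsFactors = FALSE))
  g
}

#' Read protein-complex annotations
#'
#' Accepts tab-delimited `(complex_id, gene)` rows (header optional). Returns
#' the complex membership map together with the derived gene-to-complex
#' mapping restricted to genes annotated to exactly one complex; genes in
#' several complexes are listed separately.
#'
#' @param path input file path.
#' @return list with elements `complexes` (named list of gene vectors),
#'   `gene2complex` (named character vector, single-complex genes only), and
#'   `multi` (genes annotated to more than one complex).
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("complex table requires columns (complex_id, gene)")
  if (tolower(as.character(df[1L, 1L])) %in% c("complex_id", "complex"))
    df <- df[-1L, , drop = FALSE]
  bad <- which(!nzchar(trimws(df[[1L]])) | !nzchar(trimws(df[[2L]])))
  if (length(bad)) stop("malformed complex row at line ", bad[1L])
  cid <- trimws(df[[1L]]); gene <- toupper(trimws(df[[2L]]))
  complexes <- lapply(split(gene, cid), function(x) sort(unique(x)))
  complex_map(complexes)
}

#' Build a complex map from a membership list
#'
#' @param complexes named list: complex id -> character vector of member genes.
#' @return complex map list as documented in [read_complexes()].
#' @export
complex_map <- function(complexes) {
  complexes <- lapply(complexes, function(x) sort(unique(toupper(x))))
  genes <- unlist(complexes, use.names = FALSE)
  ids <- rep(names(complexes), lengths(complexes))
  multi <- sort(unique(genes[genes %in% genes[duplicated(genes)]]))
  single <- !(genes %in% multi)
  g2c <- stats::setNames(as.character(ids[single]), genes[single])
  if (length(g2c)) g2c <- g2c[order(names(g2c))]
  structure(list(complexes = complexes,
                 gene2complex = g2c,
                 multi = multi),
            class = "complex_map")
}

#' Read a flat gene list
#'
#' One gene per line; blank lines and `#` comments are ignored.
#' @param path input file path.
#' @return sorted character vector of upper-cased gene identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  sort(unique(toupper(x)))
}

#' Read unordered gene pairs (e.g. suppressor interactions)
#'
#' Two tab-separated columns; `(a, b)` and `(b, a)` collapse to one pair.
#' @param path input file path.
#' @return data.frame with columns `gene_a`, `gene_b` (`gene_a < gene_b`).
#' @export
read_gene_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("pair table requires two tab-separated columns")
  if (tolower(as.character(df[1L, 1L])) %in% c("gene_a", "from"))
    df <- df[-1L, , drop = FALSE]
  a0 <- toupper(trimws(df[[1L]])); b0 <- toupper(trimws(df[[2L]]))
  a <- pmin(a0, b0); b <- pmax(a0, b0)
  keep <- a != b & !duplicated(paste(a, b))
  data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
}

#' Read a gene-by-condition expression matrix
#'
#' Tab-delimited with a header of condition names and gene identifiers in the
#' first column; empty cells become `NA` (log-ratio values, missing allowed).
#'
#' @param path input file path.
#' @return numeric matrix with genes as rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("expression matrix requires at least one condition column")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- toupper(rownames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers in expression matrix")
  m
}

#' Remove intra-complex edges from a network
#'
#' Drops every edge whose two endpoints share membership in any annotated
#' complex (multi-complex genes included), retaining all nodes. This restricts
#' downstream motif search to interactions between, not within, complexes.
#'
#' @param net an [igraph::igraph] network.
#' @param cmap a complex map ([read_complexes()]).
#' @return the network without intra-complex edges.
#' @export
remove_intracomplex_edges <- function(net, cmap) {
  if (igraph::ecount(net) == 0L || !length(cmap$complexes)) return(net)
  el <- igraph::as_edgelist(net)
  in_same <- rep(FALSE, nrow(el))
  for (members in cmap$complexes) {
    in_same <- in_same | (el[, 1L] %in% members & el[, 2L] %in% members)
  }
  igraph::delete_edges(net, which(in_same))
}

#' Remove high-degree hub nodes
#'
#' Deletes every node whose degree (computed once, before any deletion) is
#' `>= d_max`, together with incident edges. Hubs rarely act in specific
#' feedback circuits, and their removal makes exhaustive graphlet enumeration
#' tractable.
#'
#' @param net an [igraph::igraph] network.
#' @param d_max retain nodes with degree strictly below this bound; default 50.
#' @return the filtered network.
#' @export
filter_degree <- function(net, d_max = 50) {
  stopifnot(d_max >= 2)
  deg <- igraph::degree(net)
  igraph::delete_vertices(net, which(deg >= d_max))
}

#' Write a network as a two-column edge list
#' @param net an [igraph::igraph] network.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
    o <- order(a, b)
    el <- cbind(a, b)[o, , drop = FALSE]
  }
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#' @param net an [igraph::igraph] network.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a signed GI network as TSV
#'
#' Columns `gene_a`, `gene_b`, `score`, `sign`, sorted for reproducibility.
#' @param gi signed GI network ([threshold_gi()]).
#' @param path output path.
#' @export
write_signed_gi <- function(gi, path) {
  el <- igraph::as_edgelist(gi)
  df <- data.frame(gene_a = pmin(el[, 1L], el[, 2L]),
                   gene_b = pmax(el[, 1L], el[, 2L]),
                   score = igraph::edge_attr(gi, "score"),
                   sign = igraph::edge_attr(gi, "sign"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
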