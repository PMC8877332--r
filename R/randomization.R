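#' Degree-preserving network randomization by edge switching
#'
#' Repeated random double-edge swaps (u-v, x-y) -> (u-x, v-y); a swap is
#' rejected when it would create a self-loop or a duplicate edge. The
#' per-node degree sequence is invariant, and for signed GI networks each
#' edge keeps its `sign`/`score` attributes while its endpoints change, so
#' the sign multiset is conserved.
#'
#' @param net an [igraph::igraph] network (PPI or signed GI).
#' @param swaps_per_edge attempted swaps per edge; total attempts are
#'   `ceiling(swaps_per_edge * ecount(net))`. Default 10.
#' @param seed optional integer seed (sets the R RNG).
#' @return a rewired network of the same type.
#' @export
rewire_network <- function(net, swaps_per_edge = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- igraph::ecount(net)
  if (m < 2L) {
    warning("fewer than 2 edges: returning input unchanged")
    return(net)
  }
  el <- igraph::as_edgelist(net)
  attrs <- lapply(igraph::edge_attr(net), identity)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")
  eh <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(m)) eh[[key(el[i, 1L], el[i, 2L])]] <- TRUE
  attempts <- ceiling(swaps_per_edge * m)
  pick <- matrix(sample.int(m, 2L * attempts, replace = TRUE), ncol = 2L)
  flip <- stats::runif(attempts) < 0.5
  for (t in seq_len(attempts)) {
    i <- pick[t, 1L]; j <- pick[t, 2L]
    if (i == j) next
    u <- el[i, 1L]; v <- el[i, 2L]
    x <- el[j, 1L]; y <- el[j, 2L]
    if (flip[t]) { tmp <- x; x <- y; y <- tmp }
    # proposed: u-x, v-y
    if (u == x || v == y) next
    k1 <- key(u, x); k2 <- key(v, y)
    if (!is.null(eh[[k1]]) || !is.null(eh[[k2]])) next
    if (k1 == k2) next
    rm(list = c(key(u, v), key(x, y)), envir = eh)
    eh[[k1]] <- TRUE; eh[[k2]] <- TRUE
    el[i, ] <- c(u, x); el[j, ] <- c(v, y)
  }
  df <- data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
  for (a in names(attrs)) df[[a]] <- attrs[[a]]
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = sort(igraph::V(net)$name))
  g
}

# internal: per-topology occurrence counts as a named integer vector
.topology_counts <- function(occ) {
  if (!nrow(occ)) return(integer(0))
  tab <- table(occ$graph6)
  stats::setNames(as.integer(tab), names(tab))
}

#' Motif counts against degree-preserving null models
#'
#' Compares observed per-topology motif counts with counts from R rewired
#' networks. Mode `"ppi_random"` re-enumerates graphlets on rewired PPI
#' networks; mode `"gi_random"` keeps the PPI occurrences fixed and
#' recomputes FNM status against rewired GI networks. Replicate r uses seed
#' `seed + r`, so runs are reproducible across machines.
#'
#' @param net PPI network (already filtered as for enumeration).
#' @param gi signed GI network (required for `"gi_random"`).
#' @param k motif size.
#' @param mode `"ppi_random"` or `"gi_random"`.
#' @param R number of randomizations; the study found 30 sufficient for
#'   converging reference values.
#' @param swaps_per_edge passed to [rewire_network()].
#' @param seed base seed.
#' @param threshold,require_span FNM parameters (gi_random mode).
#' @return data.frame per topology: `graph6`, `k`, `observed`, `null_mean`,
#'   `null_sd`, `z`, `R`, `mode`; the per-replicate count matrix is attached
#'   as attribute `"replicates"`.
#' @export
randomized_motif_summary <- function(net, gi = NULL, k,
                                     mode = c("ppi_random", "gi_random"),
                                     R = 30, swaps_per_edge = 10, seed = 1,
                                     threshold = 0.5, require_span = TRUE) {
  mode <- match.arg(mode)
  stopifnot(R >= 1)
  reps <- vector("list", R)
  if (mode == "ppi_random") {
    observed <- count_topologies(net, k)
    for (r in seq_len(R)) {
      rnet <- rewire_network(net, swaps_per_edge, seed = seed + r)
      reps[[r]] <- count_topologies(rnet, k)
    }
  } else {
    if (is.null(gi)) stop("gi network required for mode 'gi_random'")
    occ <- enumerate_graphlets(net, k)
    prep <- .prepare_fnm_eval(occ)
    fnm <- .eval_fnm(prep, occ, .gi_keys(gi), threshold, require_span,
                     annotate = FALSE)
    observed <- .topology_counts(fnm[fnm$is_fnm, , drop = FALSE])
    for (r in seq_len(R)) {
      rgi <- rewire_network(gi, swaps_per_edge, seed = seed + r)
      fnm_r <- .eval_fnm(prep, occ, .gi_keys(rgi), threshold, require_span,
                         annotate = FALSE)
      reps[[r]] <- .topology_counts(fnm_r[fnm_r$is_fnm, , drop = FALSE])
    }
  }
  topos <- sort(unique(c(names(observed), unlist(lapply(reps, names)))))
  cnt <- matrix(0, nrow = length(topos), ncol = R,
                dimnames = list(topos, NULL))
  for (r in seq_len(R)) cnt[names(reps[[r]]), r] <- reps[[r]]
  obs <- stats::setNames(rep(0L, length(topos)), topos)
  obs[names(observed)] <- observed
  mu <- rowMeans(cnt)
  sdv <- apply(cnt, 1L, stats::sd)
  if (R == 1L) sdv <- rep(0, length(topos))
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  nt <- length(topos)
  out <- data.frame(graph6 = topos, k = rep(as.integer(k), nt),
                    observed = as.integer(obs), null_mean = as.numeric(mu),
                    null_sd = as.numeric(sdv), z = as.numeric(z),
                    R = rep(as.integer(R), nt), mode = rep(mode, nt),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- cnt
  out
}
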