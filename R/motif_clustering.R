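#' Cluster FNMs by node-set overlap
#'
#' Greedy agglomeration: repeatedly find the pair of current clusters whose
#' gene-set intersection is largest and merge it while the intersection has
#' at least `min_overlap` genes; ties are broken by the smallest
#' lexicographic pair of cluster indices. Clusters that never merge remain
#' singletons ("non-clustered" motifs).
#'
#' @param fnm_sets list of character vectors (deduplicated FNM node sets) or
#'   a deduplicated FNM table ([dedup_fnms()]).
#' @param min_overlap minimum shared-gene count to merge; default 2 (the
#'   weakest non-trivial overlap).
#' @return list of clusters, each a list with `members` (integer indices into
#'   the input), `genes` (union gene set), `size` (motif count); ordered by
#'   decreasing size, then by first member index.
#' @export
cluster_fnms <- function(fnm_sets, min_overlap = 2) {
  stopifnot(min_overlap >= 1)
  if (is.data.frame(fnm_sets)) fnm_sets <- strsplit(fnm_sets$node_set, ";", fixed = TRUE)
  nm <- length(fnm_sets)
  if (!nm) return(list())
  genes <- lapply(fnm_sets, function(x) sort(unique(x)))
  members <- as.list(seq_len(nm))
  repeat {
    nc <- length(genes)
    if (nc < 2L) break
    best <- 0L; bi <- 0L; bj <- 0L
    for (i in seq_len(nc - 1L)) {
      gi_ <- genes[[i]]
      for (j in (i + 1L):nc) {
        ov <- sum(gi_ %in% genes[[j]])
        if (ov > best) { best <- ov; bi <- i; bj <- j }
      }
    }
    if (best < min_overlap) break
    genes[[bi]] <- sort(unique(c(genes[[bi]], genes[[bj]])))
    members[[bi]] <- c(members[[bi]], members[[bj]])
    genes[[bj]] <- NULL
    members[[bj]] <- NULL
  }
  out <- lapply(seq_along(genes), function(i) {
    list(members = sort(members[[i]]), genes = genes[[i]],
         size = length(members[[i]]))
  })
  sizes <- vapply(out, `[[`, integer(1L), "size")
  firsts <- vapply(out, function(cl) cl$members[1L], integer(1L))
  out[order(-sizes, firsts)]
}

#' Cluster statistics for FNMs
#'
#' Summarizes clustered versus non-clustered motifs: counts and fractions,
#' gene counts in all FNMs versus non-clustered FNMs only, and per-gene
#' motif-membership counts alongside the PPI degree, split by whether the
#' gene occurs in any clustered motif.
#'
#' @param clusters output of [cluster_fnms()].
#' @param fnm_sets the list/table clustered (same indexing).
#' @param net the PPI network (for degrees); optional.
#' @return list with `summary` (data.frame of counts and fractions) and
#'   `genes` (per-gene data.frame: `gene`, `n_motifs`, `degree`, `clustered`).
#' @export
cluster_stats <- function(clusters, fnm_sets, net = NULL) {
  if (is.data.frame(fnm_sets)) fnm_sets <- strsplit(fnm_sets$node_set, ";", fixed = TRUE)
  n_fnm <- length(fnm_sets)
  sizes <- vapply(clusters, `[[`, integer(1L), "size")
  clustered_motifs <- unlist(lapply(clusters[sizes > 1L], `[[`, "members"))
  non_clustered <- setdiff(seq_len(n_fnm), clustered_motifs)
  all_genes <- sort(unique(unlist(fnm_sets)))
  nc_genes <- sort(unique(unlist(fnm_sets[non_clustered])))
  gene_in_clustered <- sort(unique(unlist(fnm_sets[clustered_motifs])))
  n_motifs <- table(factor(unlist(fnm_sets), levels = all_genes))
  deg <- rep(NA_real_, length(all_genes))
  if (!is.null(net)) {
    d <- igraph::degree(net)
    hit <- match(all_genes, names(d))
    deg[!is.na(hit)] <- d[hit[!is.na(hit)]]
  }
  genes_df <- data.frame(gene = all_genes,
                         n_motifs = as.integer(n_motifs),
                         degree = deg,
                         clustered = all_genes %in% gene_in_clustered,
                         stringsAsFactors = FALSE)
  summary_df <- data.frame(
    n_fnms = n_fnm,
    n_clusters = sum(sizes > 1L),
    n_clustered = length(clustered_motifs),
    n_non_clustered = length(non_clustered),
    frac_clustered = if (n_fnm) length(clustered_motifs) / n_fnm else NA_real_,
    frac_non_clustered = if (n_fnm) length(non_clustered) / n_fnm else NA_real_,
    n_genes_all = length(all_genes),
    n_genes_non_clustered = length(nc_genes),
    frac_genes_non_clustered = if (length(all_genes))
      length(nc_genes) / length(all_genes) else NA_real_)
  list(summary = summary_df, genes = genes_df)
}
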