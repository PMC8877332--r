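#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the minimum-likelihood method
#' (sum of all tables, at fixed margins, with probability not exceeding the
#' observed table's), with the conditional maximum-likelihood odds ratio.
#' A table with a zero margin carries no information: p = 1, odds ratio `NA`.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' U statistic for the first sample with midrank tie handling. The two-sided
#' p-value is exact (full enumeration of rank assignments) when the combined
#' sample size is at most `exact_limit`, and otherwise uses the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit combined-size cutoff for exact enumeration; default 12.
#' @return list with `U` (for `x`), `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= exact_limit) {
    idx <- utils::combn(n, n1)
    r1 <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(rk[idx], nrow = n1)) - r1
    mu <- n1 * n2 / 2
    p_lo <- mean(us <= U); p_hi <- mean(us >= U)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  list(U = U, p = min(1, p), method = "normal")
}

#' Sample non-FNM control motifs matched on GI content
#'
#' Draws motifs from the non-FNM pool stratified on `(k, gi_count)` so the
#' sampled histogram matches the FNM profile (proportional allocation).
#' Strata are sampled with replacement when exhausted; empty strata with no
#' candidates trigger a warning and renormalized allocation over the
#' remaining strata.
#'
#' @param candidates occurrence table with `k` and `gi_count` columns and
#'   `is_fnm` flags (FNMs are excluded from the pool).
#' @param fnm_profile data.frame with columns `k`, `gi_count`, `count` (the
#'   FNM histogram), e.g. from [gi_content_profile()].
#' @param n number of control motifs to draw.
#' @param seed integer seed.
#' @return row-subset of `candidates` of length `n` (row indices may repeat).
#' @export
matched_control_motifs <- function(candidates, fnm_profile, n, seed = 1) {
  stopifnot(nrow(fnm_profile) > 0L, n >= 1L)
  set.seed(seed)
  pool <- candidates
  if (!is.null(pool$is_fnm)) pool <- pool[!pool$is_fnm, , drop = FALSE]
  pool_key <- paste(pool$k, pool$gi_count, sep = ":")
  prof_key <- paste(fnm_profile$k, fnm_profile$gi_count, sep = ":")
  w <- fnm_profile$count
  available <- prof_key %in% pool_key
  if (any(!available)) {
    warning("no control candidates for strata: ",
            paste(prof_key[!available], collapse = ", "),
            "; allocation renormalized")
    w[!available] <- 0
  }
  if (sum(w) == 0) stop("no control candidates available for any stratum")
  alloc <- floor(n * w / sum(w))
  rem <- n - sum(alloc)
  if (rem > 0) {
    frac <- n * w / sum(w) - alloc
    extra <- order(-frac, prof_key)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  rows <- integer(0)
  for (i in seq_along(prof_key)) {
    if (alloc[i] == 0L) next
    cand <- which(pool_key == prof_key[i])
    rows <- c(rows, sample(cand, alloc[i], replace = alloc[i] > length(cand)))
  }
  pool[rows, , drop = FALSE]
}

#' GI-content histogram of a motif table
#'
#' @param motifs table with `k` and `gi_count` columns (typically FNM rows).
#' @return data.frame `k`, `gi_count`, `count`.
#' @export
gi_content_profile <- function(motifs) {
  tab <- table(motifs$k, motifs$gi_count)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("k", "gi_count", "count")
  df$k <- as.integer(df$k); df$gi_count <- as.integer(df$gi_count)
  df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(df$k, df$gi_count), ]
  rownames(df) <- NULL
  df
}

#' Per-motif fractions of genes with a property
#'
#' @param motifs deduplicated motif table or list of node sets.
#' @param gene_property character gene set (e.g. essential genes).
#' @return numeric vector: per motif, `|genes in property| / k`.
#' @export
motif_gene_fractions <- function(motifs, gene_property) {
  if (is.data.frame(motifs)) motifs <- strsplit(motifs$node_set, ";", fixed = TRUE)
  gene_property <- toupper(gene_property)
  vapply(motifs, function(g) sum(g %in% gene_property) / length(g), numeric(1L))
}

#' Fraction of motifs containing a full gene pair
#'
#' A motif "contains" a pair (e.g. a suppressor interaction) when both
#' members are in its node set.
#'
#' @param motifs deduplicated motif table or list of node sets.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return list with `fraction`, `n_with_pair`, `n_motifs`, and per-motif
#'   logical vector `has_pair`.
#' @export
suppressor_fraction <- function(motifs, pairs) {
  if (is.data.frame(motifs)) motifs <- strsplit(motifs$node_set, ";", fixed = TRUE)
  has <- vapply(motifs, function(g) {
    any(pairs$gene_a %in% g & pairs$gene_b %in% g)
  }, logical(1L))
  list(fraction = if (length(has)) mean(has) else NA_real_,
       n_with_pair = sum(has), n_motifs = length(has), has_pair = has)
}
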