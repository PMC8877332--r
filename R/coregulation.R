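#' Cosine similarity of two expression profiles
#'
#' Computed over the conditions where both values are present
#' (pairwise-complete mask); undefined (`NA`) with fewer than two shared
#' conditions or a zero vector.
#'
#' @param u,v numeric condition vectors (log-ratio profiles), `NA` allowed.
#' @return cosine similarity in `[-1, 1]`, or `NA`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  ok <- !is.na(u) & !is.na(v)
  if (sum(ok) < 2L) return(NA_real_)
  u <- u[ok]; v <- v[ok]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

#' Transcriptional co-regulation score of one motif
#'
#' Mean pairwise cosine similarity of the expression profiles of the motif's
#' genes; genes without expression data are excluded, and the score is
#' undefined when fewer than one defined gene pair remains.
#'
#' @param genes character vector of motif genes.
#' @param expr expression matrix ([read_expression()]).
#' @return list with `score`, `n_genes_with_data`, `n_pairs`.
#' @export
motif_coregulation <- function(genes, expr) {
  genes <- unique(toupper(genes))
  genes <- genes[genes %in% rownames(expr)]
  ng <- length(genes)
  if (ng < 2L) return(list(score = NA_real_, n_genes_with_data = ng, n_pairs = 0L))
  sims <- numeric(0)
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    s <- cosine_similarity(expr[genes[i], ], expr[genes[j], ])
    if (!is.na(s)) sims <- c(sims, s)
  }
  if (!length(sims)) return(list(score = NA_real_, n_genes_with_data = ng, n_pairs = 0L))
  list(score = mean(sims), n_genes_with_data = ng, n_pairs = length(sims))
}

#' Co-regulation scores and top-quantile flags for all FNMs
#'
#' Scores every FNM, flags motifs at or above the stated empirical quantiles
#' of the pooled score distribution (inclusive comparison), and returns
#' per-size empirical cumulative distributions.
#'
#' @param fnms deduplicated FNM table or list of node sets.
#' @param expr expression matrix.
#' @param quantiles quantile levels for flags; default `c(0.95, 0.99)`
#'   (the "top 5%" / "top 1%" of the study).
#' @return list with `scores` (data.frame: `motif_id`, `k`, `score`,
#'   `n_genes_with_data`, plus one logical flag column per quantile, e.g.
#'   `top5`, `top1`), `thresholds` (named numeric), `cdf` (data.frame per-k
#'   empirical CDF: `k`, `score`, `cum_frac`).
#' @export
coregulation_table <- function(fnms, expr, quantiles = c(0.95, 0.99)) {
  if (is.data.frame(fnms)) fnms <- strsplit(fnms$node_set, ";", fixed = TRUE)
  nmot <- length(fnms)
  score <- rep(NA_real_, nmot); ngd <- integer(nmot)
  for (i in seq_len(nmot)) {
    r <- motif_coregulation(fnms[[i]], expr)
    score[i] <- r$score; ngd[i] <- r$n_genes_with_data
  }
  kvec <- lengths(fnms)
  out <- data.frame(motif_id = seq_len(nmot), k = kvec, score = score,
                    n_genes_with_data = ngd, stringsAsFactors = FALSE)
  defined <- !is.na(score)
  thr <- stats::setNames(rep(NA_real_, length(quantiles)),
                         paste0("top", round(100 * (1 - quantiles))))
  if (any(defined)) {
    thr[] <- stats::quantile(score[defined], quantiles, names = FALSE)
  }
  for (qi in seq_along(quantiles)) {
    out[[names(thr)[qi]]] <- defined & score >= thr[qi]
  }
  cdf <- NULL
  for (kk in sort(unique(kvec))) {
    s <- sort(score[defined & kvec == kk])
    if (!length(s)) next
    cdf <- rbind(cdf, data.frame(k = kk, score = s,
                                 cum_frac = seq_along(s) / length(s)))
  }
  list(scores = out, thresholds = thr, cdf = cdf)
}
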