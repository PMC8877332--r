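#' Pipeline configuration
#'
#' Collects all tunable parameters of the FNM pipeline. Defaults follow the
#' study settings: motif sizes k = 3..6, hub threshold d_max = 50 (25 and 100
#' as tested variants), GI significance tails of 5%, FNM GI-density threshold
#' 50%, and 30 degree-preserving randomizations.
#'
#' @param paths named list of input file paths: `ppi`, `gi`, `complexes`,
#'   and optionally `essential`, `tf`, `metabolic`, `suppressors`,
#'   `expression` (as written by [generate_fixture()]).
#' @param k motif sizes; default `3:6`.
#' @param d_max hub degree threshold; default 50.
#' @param tail_fraction GI significance tail; default 0.05.
#' @param threshold FNM GI-density threshold; default 0.5.
#' @param require_span require source-to-distant-layer GIs; default TRUE.
#' @param R number of randomizations; default 30.
#' @param swaps_per_edge rewiring intensity; default 10.
#' @param seed base seed; default 1.
#' @param min_overlap cluster merge threshold (shared genes); default 2.
#' @param quantiles co-regulation flag quantiles; default `c(0.95, 0.99)`.
#' @param dmax_before_intracomplex apply the degree filter before removing
#'   intra-complex edges; default FALSE (filter order: physical dedup,
#'   intra-complex removal, then degree filter, so d_max acts on the network
#'   actually searched).
#' @param filter_gi_degree also degree-filter the GI network used for the
#'   FNM test; default FALSE (unfiltered GI).
#' @return a `fnm_config` list.
#' @export
pipeline_config <- function(paths, k = 3:6, d_max = 50, tail_fraction = 0.05,
                            threshold = 0.5, require_span = TRUE, R = 30,
                            swaps_per_edge = 10, seed = 1, min_overlap = 2,
                            quantiles = c(0.95, 0.99),
                            dmax_before_intracomplex = FALSE,
                            filter_gi_degree = FALSE) {
  cfg <- list(paths = paths, k = as.integer(k), d_max = d_max,
              tail_fraction = tail_fraction, threshold = threshold,
              require_span = require_span, R = as.integer(R),
              swaps_per_edge = swaps_per_edge, seed = as.integer(seed),
              min_overlap = min_overlap, quantiles = quantiles,
              dmax_before_intracomplex = dmax_before_intracomplex,
              filter_gi_degree = filter_gi_degree)
  class(cfg) <- "fnm_config"
  cfg
}

# internal: deterministic digest of a config (for refusing mixed intermediates)
.config_hash <- function(config) {
  cfg <- config
  cfg$paths <- NULL   # intermediates are path-independent
  s <- paste(deparse(cfg, control = "all"), collapse = "")
  v <- as.integer(charToRaw(s))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%010d", as.integer(h))
}

# internal: write a TSV with a config-hash header line
.write_stage <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full FNM pipeline
#'
#' Executes build -> enumerate -> FNM filter -> randomization -> clustering
#' -> complex network -> co-regulation -> enrichment on the configured
#' inputs, writing TSV/GraphML outputs and a deterministic summary report to
#' `out_dir`. Every output carries the configuration hash; re-running with
#' the same config and inputs is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param verbose print stage progress to stderr; default FALSE.
#' @return (invisibly) list of in-memory stage results: `networks`,
#'   `occurrences`, `fnms`, `fnm_dedup`, `random_summaries`, `clusters`,
#'   `cluster_stats`, `complex_net`, `consensus`, `betweenness`,
#'   `bridging`, `coregulation`, `enrichment`, `summary_path`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "fnm_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- .config_hash(config)
  existing <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  for (f in existing) {
    l1 <- readLines(f, n = 1L)
    if (startsWith(l1, "# config_hash=") && l1 != paste0("# config_hash=", hash))
      stop("output directory contains intermediates from a different config: ", f)
  }
  say <- function(...) if (verbose) message("[fnm] ", ...)
  p <- config$paths

  say("reading inputs")
  ppi_raw <- read_ppi(p$ppi, preset = "edge_list")
  gi_tab <- read_gi_scores(p$gi)
  cmap <- read_complexes(p$complexes)
  essential <- if (!is.null(p$essential)) read_gene_set(p$essential) else character(0)
  tf <- if (!is.null(p$tf)) read_gene_set(p$tf) else character(0)
  metabolic <- if (!is.null(p$metabolic)) read_gene_set(p$metabolic) else character(0)
  suppressors <- if (!is.null(p$suppressors)) read_gene_pairs(p$suppressors) else NULL
  expr <- if (!is.null(p$expression)) read_expression(p$expression) else NULL

  say("building networks")
  gi_net <- threshold_gi(gi_tab, config$tail_fraction)
  if (config$dmax_before_intracomplex) {
    enum_net <- remove_intracomplex_edges(filter_degree(ppi_raw, config$d_max), cmap)
  } else {
    enum_net <- filter_degree(remove_intracomplex_edges(ppi_raw, cmap), config$d_max)
  }
  gi_for_test <- if (config$filter_gi_degree) filter_degree(gi_net, config$d_max) else gi_net

  say("enumerating graphlets, k = ", paste(config$k, collapse = ","))
  occ <- NULL; fnm <- NULL
  for (kk in config$k) {
    o <- enumerate_graphlets(enum_net, kk)
    f <- find_fnms(o, gi_for_test, config$threshold, config$require_span)
    occ <- rbind(occ, o); fnm <- rbind(fnm, f)
  }
  fnm_dd <- dedup_fnms(fnm)
  .write_stage(fnm, file.path(out_dir, "fnm_table.tsv"), hash)
  .write_stage(fnm_dd, file.path(out_dir, "fnm_dedup.tsv"), hash)

  say("randomization, R = ", config$R)
  rand <- list()
  for (kk in config$k) {
    rand[[paste0("ppi_k", kk)]] <- randomized_motif_summary(
      enum_net, gi_for_test, kk, "ppi_random", R = config$R,
      swaps_per_edge = config$swaps_per_edge, seed = config$seed)
    rand[[paste0("gi_k", kk)]] <- randomized_motif_summary(
      enum_net, gi_for_test, kk, "gi_random", R = config$R,
      swaps_per_edge = config$swaps_per_edge, seed = config$seed,
      threshold = config$threshold, require_span = config$require_span)
  }
  rand_df <- do.call(rbind, c(rand, list(make.row.names = FALSE)))
  .write_stage(rand_df, file.path(out_dir, "randomization.tsv"), hash)

  say("clustering FNMs")
  clusters <- cluster_fnms(fnm_dd, config$min_overlap)
  cstats <- cluster_stats(clusters, fnm_dd, enum_net)
  .write_stage(cstats$genes, file.path(out_dir, "cluster_genes.tsv"), hash)

  say("complex-merged network")
  cnet <- build_complex_network(fnm_dd, cmap, enum_net, gi_for_test)
  cons <- consensus_gi(cnet)
  .write_stage(cons$scores, file.path(out_dir, "consensus_gi.tsv"), hash)
  write_graphml(cnet, file.path(out_dir, "complex_network.graphml"))
  cmp <- list(
    fnm = list(net = cnet,
               endpoints = igraph::V(cnet)$name[igraph::V(cnet)$type == "complex"]),
    ppi_dmax = merge_complex_nodes(enum_net, cmap),
    ppi_all = merge_complex_nodes(ppi_raw, cmap))
  btw <- rank_auxiliary(cmp)
  .write_stage(btw$sizes, file.path(out_dir, "betweenness_sizes.tsv"), hash)
  if (!is.null(btw$top))
    .write_stage(btw$top, file.path(out_dir, "betweenness_top.tsv"), hash)
  bridging <- if (length(tf) && length(metabolic))
    bridging_fnms(fnm_dd, tf, metabolic) else list()

  say("co-regulation")
  coreg <- if (!is.null(expr)) coregulation_table(fnm_dd, expr, config$quantiles) else NULL
  if (!is.null(coreg)) {
    .write_stage(coreg$scores, file.path(out_dir, "coregulation.tsv"), hash)
    if (!is.null(coreg$cdf))
      .write_stage(coreg$cdf, file.path(out_dir, "coregulation_cdf.tsv"), hash)
  }

  say("enrichment tests")
  occ_dd <- dedup_occurrences(fnm)
  non_fnm_dd <- occ_dd[!occ_dd$is_fnm, , drop = FALSE]
  enrich <- list()
  if (!is.null(suppressors) && nrow(fnm_dd)) {
    sf_fnm <- suppressor_fraction(fnm_dd, suppressors)
    sf_ppi <- suppressor_fraction(occ_dd, suppressors)
    tab <- matrix(c(sf_fnm$n_with_pair, sf_fnm$n_motifs - sf_fnm$n_with_pair,
                    sf_ppi$n_with_pair, sf_ppi$n_motifs - sf_ppi$n_with_pair),
                  2L, byrow = TRUE)
    fish <- fisher_exact_2x2(tab)
    ctrl <- NULL
    prof <- gi_content_profile(fnm_dd)
    if (nrow(non_fnm_dd) && nrow(prof)) {
      ctrl_m <- tryCatch(
        matched_control_motifs(non_fnm_dd, prof,
                               n = min(1000L, max(100L, nrow(fnm_dd))),
                               seed = config$seed),
        error = function(e) NULL)
      if (!is.null(ctrl_m)) ctrl <- suppressor_fraction(ctrl_m, suppressors)
    }
    enrich$suppressor <- list(fnm = sf_fnm$fraction, ppi = sf_ppi$fraction,
                              ctrl = if (!is.null(ctrl)) ctrl$fraction else NA_real_,
                              odds_ratio = fish$odds_ratio, p = fish$p)
  }
  if (length(essential) && nrow(fnm_dd) && nrow(non_fnm_dd)) {
    fr_f <- motif_gene_fractions(fnm_dd, essential)
    fr_p <- motif_gene_fractions(occ_dd, essential)
    mw <- mann_whitney_u(fr_f, fr_p)
    enrich$essential <- list(fnm_mean = mean(fr_f), ppi_mean = mean(fr_p),
                             U = mw$U, p = mw$p)
    subunits <- names(cmap$gene2complex)
    fr_fc <- motif_gene_fractions(fnm_dd, subunits)
    fr_pc <- motif_gene_fractions(occ_dd, subunits)
    mwc <- mann_whitney_u(fr_fc, fr_pc)
    enrich$complex_subunit <- list(fnm_mean = mean(fr_fc), ppi_mean = mean(fr_pc),
                                   U = mwc$U, p = mwc$p)
  }

  say("summary")
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  lines <- c(paste0("# config_hash=", hash),
             "section\tkey\tvalue")
  per_k_occ <- table(factor(occ$k, levels = config$k))
  per_k_fnm <- table(factor(fnm$k[fnm$is_fnm], levels = config$k))
  for (kk in as.character(config$k)) {
    lines <- c(lines,
               paste("counts", paste0("occurrences_k", kk), per_k_occ[kk], sep = "\t"),
               paste("counts", paste0("fnm_k", kk), per_k_fnm[kk], sep = "\t"))
  }
  lines <- c(lines,
             paste("counts", "fnm_dedup_total", nrow(fnm_dd), sep = "\t"),
             paste("clusters", "frac_clustered",
                   fmt(cstats$summary$frac_clustered), sep = "\t"),
             paste("clusters", "n_non_clustered",
                   cstats$summary$n_non_clustered, sep = "\t"),
             paste("clusters", "frac_genes_non_clustered",
                   fmt(cstats$summary$frac_genes_non_clustered), sep = "\t"))
  if (!all(is.na(cons$overlap))) {
    lines <- c(lines,
               paste("complexes", "frac_both", fmt(cons$overlap["both"]), sep = "\t"),
               paste("complexes", "frac_ppi_only", fmt(cons$overlap["ppi_only"]), sep = "\t"),
               paste("complexes", "frac_gi_only", fmt(cons$overlap["gi_only"]), sep = "\t"))
  }
  lines <- c(lines, paste("complexes", "n_bridging_groups", length(bridging), sep = "\t"))
  if (!is.null(coreg)) {
    for (nm in names(coreg$thresholds)) {
      lines <- c(lines, paste("coregulation", paste0(nm, "_threshold"),
                              fmt(coreg$thresholds[nm]), sep = "\t"))
    }
  }
  if (!is.null(enrich$suppressor)) {
    lines <- c(lines,
               paste("enrichment", "suppressor_frac_fnm",
                     fmt(enrich$suppressor$fnm), sep = "\t"),
               paste("enrichment", "suppressor_frac_ppi",
                     fmt(enrich$suppressor$ppi), sep = "\t"),
               paste("enrichment", "suppressor_p", fmt(enrich$suppressor$p), sep = "\t"))
  }
  if (!is.null(enrich$essential)) {
    lines <- c(lines,
               paste("enrichment", "essential_p", fmt(enrich$essential$p), sep = "\t"),
               paste("enrichment", "complex_subunit_p",
                     fmt(enrich$complex_subunit$p), sep = "\t"))
  }
  summary_path <- file.path(out_dir, "summary.tsv")
  writeLines(lines, summary_path)

  invisible(list(networks = list(ppi_raw = ppi_raw, enum = enum_net,
                                 gi = gi_net, gi_for_test = gi_for_test),
                 occurrences = occ, fnms = fnm, fnm_dedup = fnm_dd,
                 random_summaries = rand_df, clusters = clusters,
                 cluster_stats = cstats, complex_net = cnet,
                 consensus = cons, betweenness = btw, bridging = bridging,
                 coregulation = coreg, enrichment = enrich,
                 summary_path = summary_path))
}
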