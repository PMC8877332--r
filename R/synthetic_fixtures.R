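#' Specification of a synthetic PPI + GI fixture
#'
#' Describes a paired synthetic data bundle emulating the pipeline's inputs:
#' a background PPI network, protein complexes added as cliques, planted
#' functional network motifs whose GI content satisfies the FNM criteria by
#' construction, suppressor pairs enriched inside planted motifs, essential
#' genes, TF/metabolic gene labels, and an expression matrix in which planted
#' co-expressed groups share a latent condition response.
#'
#' @param n_genes number of genes; default 90 (sized so the full pipeline
#'   with 30 randomizations runs in about two minutes).
#' @param ppi_p Erdos-Renyi background edge probability; default 0.008
#'   (a sparse background, as after hub filtering).
#' @param n_complexes number of complexes (cliques); default 4.
#' @param complex_size size range of complexes; default `c(3, 5)`.
#' @param planted_k motif sizes of planted FNMs, one entry per motif;
#'   default `c(3, 3, 4, 4, 5, 6)`.
#' @param gi_density GI density of planted motifs as a fraction of all node
#'   pairs; default 0.5 (the FNM threshold: planted motifs sit exactly at the
#'   ceiling `ceiling(0.5 * k(k-1)/2)`).
#' @param pos_fraction fraction of positive signs among planted GI edges;
#'   default 0.35 (negative GIs predominate in FNMs).
#' @param background_gi_pairs number of random background GI score pairs;
#'   default 400.
#' @param tail_fraction significance tail used downstream; default 0.05.
#' @param suppressor_multiplier enrichment of suppressor pairs inside planted
#'   motifs versus background; default 3.
#' @param essential_rate background essential-gene rate; default 0.15.
#' @param n_conditions expression conditions; default 20.
#' @param expr_effect latent-response effect size for co-expressed planted
#'   groups; default 2.
#' @param expr_noise_sd expression noise standard deviation; default 1.
#' @param seed integer seed; default 1.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 90, ppi_p = 0.008, n_complexes = 4,
                         complex_size = c(3, 5),
                         planted_k = c(3, 3, 4, 4, 5, 6),
                         gi_density = 0.5, pos_fraction = 0.35,
                         background_gi_pairs = 400, tail_fraction = 0.05,
                         suppressor_multiplier = 3, essential_rate = 0.15,
                         n_conditions = 20, expr_effect = 2, expr_noise_sd = 1,
                         seed = 1) {
  spec <- list(n_genes = n_genes, ppi_p = ppi_p, n_complexes = n_complexes,
               complex_size = complex_size, planted_k = as.integer(planted_k),
               gi_density = gi_density, pos_fraction = pos_fraction,
               background_gi_pairs = background_gi_pairs,
               tail_fraction = tail_fraction,
               suppressor_multiplier = suppressor_multiplier,
               essential_rate = essential_rate, n_conditions = n_conditions,
               expr_effect = expr_effect, expr_noise_sd = expr_noise_sd,
               seed = as.integer(seed))
  need <- sum(pmax(spec$planted_k - 2L, 1L)) + n_complexes * complex_size[2L]
  if (need > n_genes) stop("infeasible spec: planted motifs and complexes need ",
                           need, " genes but n_genes = ", n_genes)
  if (any(spec$planted_k > n_genes)) stop("infeasible spec: k exceeds n_genes")
  class(spec) <- "fixture_spec"
  spec
}

# internal: random connected graph on nodes 1..k (spanning tree + extras);
# `forbid` is an optional pair that must stay a non-edge
.random_connected <- function(k, extra_p = 0.3, forbid = NULL) {
  banned <- function(i, j) !is.null(forbid) && i == forbid[1L] && j == forbid[2L]
  edges <- NULL
  if (k >= 2L) {
    for (v in 2L:k) {
      parents <- seq_len(v - 1L)
      if (!is.null(forbid) && v == forbid[2L]) parents <- setdiff(parents, forbid[1L])
      p <- if (length(parents) == 1L) parents else sample(parents, 1L)
      edges <- rbind(edges, c(p, v))
    }
    if (k >= 3L) {
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        if (!banned(i, j) && !any(edges[, 1L] == i & edges[, 2L] == j) &&
            stats::runif(1L) < extra_p)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  edges
}

#' Generate a synthetic fixture bundle
#'
#' Writes all input files the pipeline reads (PPI edge list, GI score table,
#' complexes, essential/TF/metabolic gene lists, suppressor pairs, expression
#' matrix) plus a ground-truth manifest, and returns them in memory.
#'
#' Planted motifs use genes disjoint from each other and from complex
#' cliques, and background PPI edges between two genes of the same planted
#' motif are suppressed, so each planted occurrence keeps its designed
#' induced topology and BFS layering. Planted GI scores are placed beyond
#' the empirical tails of the background score distribution by rejection,
#' guaranteeing significance at the spec's tail fraction.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory; created if missing. `NULL` skips writing.
#' @return list with `paths` (named file paths or `NULL`), `ppi` (igraph),
#'   `gi_scores` (data.frame), `cmap`, `gene_sets` (essential, tf,
#'   metabolic), `suppressor_pairs`, `expression`, and `manifest`
#'   (data.frame: planted motif id, k, source, node_set, layers, gi edges,
#'   expected FNM status, co-expressed flag).
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  n_planted <- length(spec$planted_k)

  # reserve gene blocks: complexes first, then fresh genes for planted motifs
  cursor <- 0L
  complexes <- list()
  for (i in seq_len(spec$n_complexes)) {
    sz <- sample(spec$complex_size[1L]:spec$complex_size[2L], 1L)
    complexes[[sprintf("CPLX%02d", i)]] <- genes[(cursor + 1L):(cursor + sz)]
    cursor <- cursor + sz
  }
  cmap <- complex_map(complexes)
  # each planted motif embeds two subunits of two distinct complexes (when
  # available), so FNMs carry inter-complex PPI/GI edges as in real data;
  # the motif source and remaining genes are fresh. Same-complex pairs are
  # never placed inside one motif, so intra-complex edge removal cannot
  # break a planted topology.
  # pair_state records subunit pairs that earlier motifs constrained to be a
  # PPI edge ("edge") or a non-edge ("nonedge"), so motifs sharing a complex
  # pair can never impose contradictory designs on the same gene pair
  pair_state <- new.env(parent = emptyenv(), hash = TRUE)
  planted <- vector("list", n_planted)
  planted_cx <- logical(n_planted)
  for (i in seq_len(n_planted)) {
    k <- spec$planted_k[i]
    direct_i <- i %% 2L == 0L
    want <- if (direct_i) "edge" else "nonedge"
    cx_genes <- character(0)
    if (spec$n_complexes >= 2L && k >= 3L) {
      ca <- complexes[[(i - 1L) %% spec$n_complexes + 1L]]
      cb <- complexes[[i %% spec$n_complexes + 1L]]
      for (try in 1:50) {
        cx_genes <- c(sample(ca, 1L), sample(cb, 1L))
        key <- paste(min(cx_genes), max(cx_genes), sep = "|")
        st <- pair_state[[key]]
        if (is.null(st) || st == want) break
        cx_genes <- character(0)
      }
      if (length(cx_genes)) {
        pair_state[[paste(min(cx_genes), max(cx_genes), sep = "|")]] <- want
      }
    }
    n_fresh <- k - length(cx_genes)
    fresh <- genes[(cursor + 1L):(cursor + n_fresh)]
    cursor <- cursor + n_fresh
    planted[[i]] <- c(fresh, cx_genes)   # index 1 (source) is always fresh
    planted_cx[i] <- length(cx_genes) > 0L
  }

  # background PPI edges, avoiding pairs inside one planted motif
  planted_pair <- new.env(parent = emptyenv(), hash = TRUE)
  for (pg in planted) {
    for (i in seq_len(length(pg) - 1L)) for (j in (i + 1L):length(pg))
      planted_pair[[paste(pg[i], pg[j], sep = "|")]] <- TRUE
  }
  from <- character(0); to <- character(0)
  for (i in seq_len(spec$n_genes - 1L)) {
    hits <- which(stats::runif(spec$n_genes - i) < spec$ppi_p)
    for (j in i + hits) {
      if (is.null(planted_pair[[paste(genes[i], genes[j], sep = "|")]])) {
        from <- c(from, genes[i]); to <- c(to, genes[j])
      }
    }
  }
  # complex cliques (intra-complex edges; removed again by the filter step)
  for (members in complexes) {
    for (i in seq_len(length(members) - 1L)) for (j in (i + 1L):length(members)) {
      from <- c(from, members[i]); to <- c(to, members[j])
    }
  }

  # planted motif topologies and GI edges
  manifest <- NULL
  gi_a <- character(0); gi_b <- character(0); gi_sign <- character(0)
  coexpr_groups <- list()
  for (i in seq_len(n_planted)) {
    pg <- planted[[i]]
    k <- length(pg)
    has_cx <- planted_cx[i]
    # alternate motif designs: "direct" motifs wire the two complex subunits
    # (last two indices) by a PPI, populating the PPI-and-GI overlap class;
    # "mediated" motifs keep that pair a non-edge so the complexes
    # communicate only through fresh auxiliary genes (non-zero restricted
    # betweenness)
    direct <- has_cx && i %% 2L == 0L
    edges <- .random_connected(k, forbid = if (has_cx && !direct) c(k - 1L, k))
    if (direct && !any(edges[, 1L] == k - 1L & edges[, 2L] == k))
      edges <- rbind(edges, c(k - 1L, k))
    from <- c(from, pg[edges[, 1L]]); to <- c(to, pg[edges[, 2L]])
    # BFS layering from source pg[1]
    adj <- vector("list", k)
    for (r in seq_len(nrow(edges))) {
      adj[[edges[r, 1L]]] <- c(adj[[edges[r, 1L]]], edges[r, 2L])
      adj[[edges[r, 2L]]] <- c(adj[[edges[r, 2L]]], edges[r, 1L])
    }
    d <- rep(NA_integer_, k); d[1L] <- 0L
    frontier <- 1L
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), which(!is.na(d)))
      d[nxt] <- d[frontier[1L]] + 1L
      frontier <- nxt
    }
    distant <- which(d == max(d))
    need <- ceiling(spec$gi_density * k * (k - 1L) / 2L)
    pick_a <- rep(1L, length(distant)); pick_b <- distant
    all_pairs <- utils::combn(k, 2L)
    pk <- paste(all_pairs[1L, ], all_pairs[2L, ])
    have <- paste(pmin(pick_a, pick_b), pmax(pick_a, pick_b))
    extra_needed <- need - length(distant)
    if (extra_needed > 0L && k >= 3L && spec$n_complexes >= 2L &&
        !(paste(k - 1L, k) %in% have)) {
      # give the complex-subunit pair a GI first (consensus-score signal)
      pick_a <- c(pick_a, k - 1L); pick_b <- c(pick_b, k)
      have <- c(have, paste(k - 1L, k))
      extra_needed <- extra_needed - 1L
    }
    if (extra_needed > 0L) {
      cand <- which(!(pk %in% have))
      sel <- sample(cand, extra_needed)
      pick_a <- c(pick_a, all_pairs[1L, sel]); pick_b <- c(pick_b, all_pairs[2L, sel])
    }
    sgn <- ifelse(stats::runif(length(pick_a)) < spec$pos_fraction,
                  "positive", "negative")
    gi_a <- c(gi_a, pg[pick_a]); gi_b <- c(gi_b, pg[pick_b])
    gi_sign <- c(gi_sign, sgn)
    co <- i <= ceiling(n_planted / 2)   # first half of planted motifs co-expressed
    if (co) coexpr_groups[[length(coexpr_groups) + 1L]] <- pg
    depth_named <- stats::setNames(d, pg)
    depth_named <- depth_named[order(names(depth_named))]
    manifest <- rbind(manifest, data.frame(
      motif_id = i, k = k, source = pg[1L],
      node_set = paste(sort(pg), collapse = ";"),
      layers = paste(names(depth_named), depth_named, sep = ":", collapse = ";"),
      n_gi = length(pick_a),
      gi_edges = paste(pmin(pg[pick_a], pg[pick_b]),
                       pmax(pg[pick_a], pg[pick_b]),
                       sep = "|", collapse = ";"),
      expected_fnm = TRUE, coexpressed = co, stringsAsFactors = FALSE))
  }

  ppi <- .make_network(from, to)
  missing <- setdiff(genes, igraph::V(ppi)$name)
  if (length(missing)) ppi <- igraph::add_vertices(ppi, length(missing), name = missing)

  # background GI scores on random pairs (excluding planted GI pairs). The
  # planted edges must all survive the empirical tail threshold downstream:
  # each sign class has to fit inside its tail, so the background is topped
  # up beyond the requested size whenever the planted edges would overflow
  # a tail of the total score table.
  planted_gi_key <- paste(pmin(gi_a, gi_b), pmax(gi_a, gi_b), sep = "|")
  n_pos_planted <- sum(gi_sign == "positive")
  n_neg_planted <- sum(gi_sign == "negative")
  min_total <- ceiling((max(n_pos_planted, n_neg_planted) + 2) / spec$tail_fraction)
  n_bg <- max(spec$background_gi_pairs, min_total - length(gi_sign))
  bg_a <- character(0); bg_b <- character(0)
  tries <- 0L
  while (length(bg_a) < n_bg && tries < 50L * n_bg) {
    tries <- tries + 1L
    ij <- sample.int(spec$n_genes, 2L)
    a <- min(genes[ij]); b <- max(genes[ij])
    key <- paste(a, b, sep = "|")
    if (key %in% planted_gi_key) next
    if (any(bg_a == a & bg_b == b)) next
    bg_a <- c(bg_a, a); bg_b <- c(bg_b, b)
  }
  bg_score <- stats::rnorm(length(bg_a))
  # planted scores beyond the empirical background tails
  lo <- min(bg_score); hi <- max(bg_score)
  pl_score <- ifelse(gi_sign == "positive",
                     hi + abs(stats::rnorm(length(gi_sign), 1, 0.25)),
                     lo - abs(stats::rnorm(length(gi_sign), 1, 0.25)))
  gi_scores <- dedup_gi_scores(data.frame(
    gene_a = c(bg_a, gi_a), gene_b = c(bg_b, gi_b),
    score = c(bg_score, pl_score), stringsAsFactors = FALSE))

  # suppressor pairs: enriched among planted GI pairs vs random background
  n_bg_supp <- 10L
  base_rate <- 0.1
  supp_a <- character(0); supp_b <- character(0)
  take <- stats::runif(length(gi_a)) < base_rate * spec$suppressor_multiplier
  supp_a <- c(supp_a, pmin(gi_a, gi_b)[take]); supp_b <- c(supp_b, pmax(gi_a, gi_b)[take])
  for (t in seq_len(n_bg_supp)) {
    ij <- sample.int(spec$n_genes, 2L)
    supp_a <- c(supp_a, min(genes[ij])); supp_b <- c(supp_b, max(genes[ij]))
  }
  keep <- !duplicated(paste(supp_a, supp_b)) & supp_a != supp_b
  suppressor_pairs <- data.frame(gene_a = supp_a[keep], gene_b = supp_b[keep],
                                 stringsAsFactors = FALSE)

  essential <- sort(genes[stats::runif(spec$n_genes) < spec$essential_rate])
  # TF and metabolic labels partly overlap planted-motif genes, so some FNMs
  # bridge the two systems (the regulatory-crosstalk surface)
  planted_pool <- unique(unlist(planted))
  n_tf <- max(3L, spec$n_genes %/% 20L)
  tf_genes <- unique(c(sample(vapply(planted, `[[`, character(1L), 1L),
                              min(2L, n_planted)),
                       sample(setdiff(genes, planted_pool), n_tf)))
  n_met <- max(5L, spec$n_genes %/% 10L)
  met_pool <- setdiff(planted_pool, tf_genes)
  metabolic <- unique(c(sample(met_pool, min(4L, length(met_pool))),
                        sample(setdiff(genes, c(tf_genes, planted_pool)), n_met)))
  tf_genes <- sort(tf_genes)
  metabolic <- sort(metabolic)

  expression <- generate_expression(genes, coexpr_groups, spec$n_conditions,
                                    spec$expr_effect, spec$expr_noise_sd,
                                    seed = spec$seed + 1L)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      ppi = file.path(dir, "ppi_edges.tsv"),
      gi = file.path(dir, "gi_scores.tsv"),
      complexes = file.path(dir, "complexes.tsv"),
      essential = file.path(dir, "essential_genes.txt"),
      tf = file.path(dir, "tf_genes.txt"),
      metabolic = file.path(dir, "metabolic_genes.txt"),
      suppressors = file.path(dir, "suppressor_pairs.tsv"),
      expression = file.path(dir, "expression.tsv"),
      manifest = file.path(dir, "manifest.tsv"))
    write_edge_list(ppi, paths$ppi)
    gi_out <- gi_scores[order(gi_scores$gene_a, gi_scores$gene_b), ]
    utils::write.table(format(gi_out, digits = 15, trim = TRUE), paths$gi,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    cx <- data.frame(complex_id = rep(names(complexes), lengths(complexes)),
                     gene = unlist(complexes, use.names = FALSE))
    cx <- cx[order(cx$complex_id, cx$gene), ]
    utils::write.table(cx, paths$complexes, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(essential, paths$essential)
    writeLines(tf_genes, paths$tf)
    writeLines(metabolic, paths$metabolic)
    sp <- suppressor_pairs[order(suppressor_pairs$gene_a, suppressor_pairs$gene_b), ]
    utils::write.table(sp, paths$suppressors, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    em <- cbind(gene = rownames(expression),
                as.data.frame(format(expression, digits = 15, trim = TRUE)))
    utils::write.table(em, paths$expression, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(paths = paths, ppi = ppi, gi_scores = gi_scores, cmap = cmap,
       gene_sets = list(essential = essential, tf = tf_genes,
                        metabolic = metabolic),
       suppressor_pairs = suppressor_pairs, expression = expression,
       manifest = manifest, spec = spec)
}

#' Generate a synthetic expression matrix with planted co-expression
#'
#' Genes of a planted group share a latent condition response scaled by
#' `effect`, plus independent Gaussian noise; background genes are pure
#' noise. Values emulate log-ratio expression changes over conditions.
#'
#' @param genes all gene identifiers (matrix rows).
#' @param planted_groups list of character vectors (co-expressed groups).
#' @param n_conditions number of condition columns; default 20.
#' @param effect latent response effect size; default 2.
#' @param noise_sd noise standard deviation (> 0); default 1.
#' @param seed integer seed.
#' @return numeric matrix, genes x conditions.
#' @export
generate_expression <- function(genes, planted_groups = list(),
                                n_conditions = 20, effect = 2, noise_sd = 1,
                                seed = 1) {
  stopifnot(noise_sd > 0)
  set.seed(seed)
  m <- matrix(stats::rnorm(length(genes) * n_conditions, 0, noise_sd),
              nrow = length(genes),
              dimnames = list(toupper(genes),
                              sprintf("cond%02d", seq_len(n_conditions))))
  for (grp in planted_groups) {
    latent <- stats::rnorm(n_conditions)
    for (g in toupper(grp)) {
      if (g %in% rownames(m)) m[g, ] <- effect * latent + stats::rnorm(n_conditions, 0, noise_sd)
    }
  }
  m
}
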