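test_that("fixture generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 42), dir = d1)
  generate_fixture(fixture_spec(seed = 42), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seed differs somewhere
  d3 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 43), dir = d3)
  same <- vapply(list.files(d1), function(f)
    identical(readLines(file.path(d1, f)), readLines(file.path(d3, f))),
    logical(1))
  expect_false(all(same))
})

test_that("every planted motif satisfies the FNM criteria by construction", {
  for (seed in c(1, 17)) {
    fx <- generate_fixture(fixture_spec(seed = seed))
    gi <- threshold_gi(fx$gi_scores, fx$spec$tail_fraction)
    gi_el <- igraph::as_edgelist(gi)
    gi_keys <- paste(pmin(gi_el[, 1], gi_el[, 2]),
                     pmax(gi_el[, 1], gi_el[, 2]), sep = "|")
    for (i in seq_len(nrow(fx$manifest))) {
      m <- fx$manifest[i, ]
      # all planted GI edges survive thresholding
      planted_keys <- strsplit(m$gi_edges, ";")[[1]]
      expect_true(all(planted_keys %in% gi_keys), label = paste("motif", i))
      # GI count sits exactly at the ceiling
      expect_equal(m$n_gi, ceiling(0.5 * m$k * (m$k - 1) / 2))
      # re-derive FNM status from the written layering
      occ <- data.frame(source = m$source, k = m$k, composition = "x",
                        layers = m$layers, node_set = m$node_set,
                        graph6 = "x", stringsAsFactors = FALSE)
      expect_true(find_fnms(occ, gi)$is_fnm, label = paste("motif", i))
    }
  }
})

test_that("planted layerings match BFS distances in the emitted PPI network", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  net <- remove_intracomplex_edges(fx$ppi, fx$cmap)
  for (i in seq_len(nrow(fx$manifest))) {
    m <- fx$manifest[i, ]
    nodes <- strsplit(m$node_set, ";")[[1]]
    sub <- igraph::induced_subgraph(net, nodes)
    d <- igraph::distances(sub, v = m$source)[1, nodes]
    parts <- strsplit(strsplit(m$layers, ";")[[1]], ":")
    got <- stats::setNames(as.integer(vapply(parts, `[[`, character(1), 2)),
                           vapply(parts, `[[`, character(1), 1))
    expect_equal(got[nodes], d[nodes], ignore_attr = TRUE,
                 label = paste("motif", i))
  }
})

test_that("written fixture files parse back to the in-memory objects", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 11), dir = d)
  ppi2 <- read_ppi(fx$paths$ppi, preset = "edge_list")
  expect_equal(igraph::ecount(ppi2), igraph::ecount(fx$ppi))
  gi2 <- read_gi_scores(fx$paths$gi)
  expect_equal(nrow(gi2), nrow(fx$gi_scores))
  expect_equal(sort(gi2$score), sort(fx$gi_scores$score), tolerance = 1e-12)
  cm2 <- read_complexes(fx$paths$complexes)
  expect_equal(cm2$gene2complex, fx$cmap$gene2complex)
  ex2 <- read_expression(fx$paths$expression)
  expect_equal(dim(ex2), dim(fx$expression))
  expect_equal(unname(ex2), unname(fx$expression), tolerance = 1e-10)
  sp2 <- read_gene_pairs(fx$paths$suppressors)
  expect_equal(nrow(sp2), nrow(fx$suppressor_pairs))
})

test_that("expression generator produces the designed co-expression signal", {
  genes <- sprintf("G%03d", 1:60)
  grp <- list(genes[1:4], genes[5:8])
  # strong effect, vanishing noise: within-group cosine approaches 1
  e_strong <- generate_expression(genes, grp, n_conditions = 30,
                                  effect = 2, noise_sd = 1e-4, seed = 21)
  expect_gt(motif_coregulation(grp[[1]], e_strong)$score, 0.999)
  # no effect: group scores center near zero
  e_null <- generate_expression(genes, grp, n_conditions = 30,
                                effect = 0, noise_sd = 1, seed = 22)
  expect_lt(abs(motif_coregulation(grp[[1]], e_null)$score), 0.4)
})

test_that("infeasible specs are rejected", {
  expect_error(fixture_spec(n_genes = 10, planted_k = rep(6, 10)), "infeasible")
})
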