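test_that("edge-list reader deduplicates, drops self-loops, upper-cases", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "a\ta", "b\tc"), f)
  g <- read_ppi(f, preset = "edge_list")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("A B", "B C"))
})

test_that("biogrid preset filters to physical rows and validates columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("Systematic Name Interactor A",
                     "Systematic Name Interactor B",
                     "Experimental System Type", sep = "\t"),
               "YAL001C\tYBR001C\tphysical",
               "YAL002W\tYBR002C\tphysical",
               "YAL003W\tYBR003C\tgenetic"), f)
  g <- read_ppi(f, preset = "biogrid_tab", physical_only = TRUE)
  expect_equal(igraph::ecount(g), 2)
  g_all <- read_ppi(f, preset = "biogrid_tab", physical_only = FALSE)
  expect_equal(igraph::ecount(g_all), 3)

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("colA\tcolB", "x\ty"), f2)
  expect_error(read_ppi(f2, preset = "biogrid_tab"), "Systematic Name")
})

test_that("GI thresholding keeps only the score tails with correct signs", {
  gi <- data.frame(gene_a = sprintf("A%03d", 1:100),
                   gene_b = sprintf("B%03d", 1:100),
                   score = 1:100)
  net <- threshold_gi(gi, 0.05)
  sg <- igraph::edge_attr(net, "sign")
  sc <- igraph::edge_attr(net, "score")
  expect_true(all(sc[sg == "negative"] < min(sc[sg == "positive"])))
  expect_lte(igraph::ecount(net), 2 * 0.05 * 100 + 2)
  # sign is a function of score only: ordered by score, all negatives
  # precede all positives
  expect_true(!is.unsorted(sg[order(sc)]))

  net3 <- threshold_gi(data.frame(gene_a = c("A", "B", "C"),
                                  gene_b = c("X", "Y", "Z"),
                                  score = c(-1, 0, 1)), 1 / 3)
  expect_equal(igraph::ecount(net3), 2)
  expect_setequal(igraph::edge_attr(net3, "sign"), c("negative", "positive"))

  expect_error(threshold_gi(data.frame(gene_a = "A", gene_b = "B", score = 1),
                            0.05), "identical")
})

test_that("duplicate GI pairs collapse to the strongest score", {
  gi <- dedup_gi_scores(data.frame(gene_a = c("A", "B", "A"),
                                   gene_b = c("B", "A", "A"),
                                   score = c(-3, 2, 9)))
  expect_equal(nrow(gi), 1)
  expect_equal(gi$score, -3)
})

test_that("intra-complex edge removal honors shared membership in any complex", {
  g <- mini_graph("A-B,A-C")
  cmap <- complex_map(list(C1 = c("A", "B")))
  out <- remove_intracomplex_edges(g, cmap)
  el <- igraph::as_edgelist(out)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("A", "C"))
  expect_equal(igraph::vcount(out), 3)   # nodes retained
  # no annotations: identity
  expect_equal(igraph::ecount(remove_intracomplex_edges(g, complex_map(list()))), 2)
  # multi-complex gene still triggers removal
  cmap2 <- complex_map(list(C1 = c("A", "B"), C2 = c("B", "Z")))
  expect_equal(igraph::ecount(remove_intracomplex_edges(g, cmap2)), 1)
})

test_that("degree filter removes nodes at or above d_max in a single pass", {
  hub <- igraph::make_star(61, mode = "undirected", center = 1)
  igraph::V(hub)$name <- sprintf("S%02d", 1:61)
  out <- filter_degree(hub, 50)
  expect_equal(igraph::vcount(out), 60)
  expect_equal(igraph::ecount(out), 0)
  # exactly d_max is removed (strict < retained)
  star50 <- igraph::make_star(51, mode = "undirected", center = 1)
  igraph::V(star50)$name <- sprintf("T%02d", 1:51)
  expect_equal(igraph::vcount(filter_degree(star50, 50)), 50)
  # all below: unchanged
  tri <- mini_graph("A-B,B-C,C-A")
  expect_equal(igraph::vcount(filter_degree(tri, 50)), 3)
  filtered <- filter_degree(er_graph(40, 0.1, 3), 5)
  expect_true(igraph::vcount(filtered) > 0 && max(igraph::degree(filtered)) < 5)
})

test_that("complex map flags multi-complex genes and single-valued mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("C1\ta", "C1\tb", "C2\tb", "C2\tc"), f)
  cm <- read_complexes(f)
  expect_equal(cm$gene2complex, c(A = "C1", C = "C2"))
  expect_equal(cm$multi, "B")
})

test_that("pair and expression readers satisfy their invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta"), f)
  expect_equal(nrow(read_gene_pairs(f)), 1)

  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2\tc3\tc4",
               "g1\t0.5\t-1\t\t2",
               "g2\t1\t1\t1\t1",
               "g3\t0\t0\t0.2\t-0.1"), fe)
  m <- read_expression(fe)
  expect_equal(dim(m), c(3, 4))
  expect_equal(sum(is.na(m)), 1)
  expect_equal(rownames(m), c("G1", "G2", "G3"))
})

test_that("edge-list writer round-trips node and edge sets", {
  g <- er_graph(20, 0.2, 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  g2 <- read_ppi(f, preset = "edge_list")
  expect_setequal(igraph::V(g2)$name,
                  igraph::V(g)$name[igraph::degree(g) > 0])
  key <- function(gg) {
    el <- igraph::as_edgelist(gg)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(key(g2), key(g))
})

test_that("GraphML writer round-trips a signed GI network", {
  gi <- mini_gi(c("A-B" = "positive", "B-C" = "negative", "C-D" = "negative"))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(gi, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g2), 3)
  expect_setequal(igraph::edge_attr(g2, "sign"),
                  igraph::edge_attr(gi, "sign"))
})
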