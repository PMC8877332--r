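test_that("complex network maps genes to complex/auxiliary nodes with counts", {
  cmap <- complex_map(list(C1 = c("A", "Z1"), C2 = c("C", "Z2")))
  ppi <- mini_graph("A-B,B-C")
  gi <- mini_gi(c("A-C" = "negative", "A-B" = "negative"))
  # one FNM over {A, B, C}: A in C1, C in C2, B auxiliary
  cnet <- build_complex_network(list(c("A", "B", "C")), cmap, ppi, gi)
  types <- stats::setNames(igraph::V(cnet)$type, igraph::V(cnet)$name)
  expect_equal(types[["C1"]], "complex")
  expect_equal(types[["B"]], "auxiliary")
  el <- igraph::as_edgelist(cnet)
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_setequal(keys, c("B C1", "B C2", "C1 C2"))
  # C1-B edge carries the PPI count
  i <- which(keys == "B C1")
  expect_equal(igraph::edge_attr(cnet, "n_ppi")[i], 1)
  expect_equal(igraph::edge_attr(cnet, "n_gi_neg")[i], 1)
})

test_that("repeated gene-level edges in different FNMs accumulate counts", {
  cmap <- complex_map(list(C1 = c("A"), C2 = c("C")))
  ppi <- mini_graph("A-B,B-C,A-D,D-C")
  gi <- mini_gi(c("A-C" = "negative"))
  cnet <- build_complex_network(list(c("A", "B", "C"), c("A", "C", "D")),
                                cmap, ppi, gi)
  el <- igraph::as_edgelist(cnet)
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  i <- which(keys == "C1 C2")
  expect_equal(igraph::edge_attr(cnet, "n_gi_neg")[i], 2)   # stated double count
})

test_that("multi-complex genes are dropped from the merged network", {
  cmap <- complex_map(list(C1 = c("A", "B"), C2 = c("B", "Z")))
  ppi <- mini_graph("A-B,B-C")
  gi <- igraph::make_empty_graph(directed = FALSE)
  cnet <- build_complex_network(list(c("A", "B", "C")), cmap, ppi, gi)
  expect_false("B" %in% igraph::V(cnet)$name)
})

test_that("consensus score follows (pos - neg) / (pos + neg)", {
  cmap <- complex_map(list(C1 = "A", C2 = "B", C3 = "C"))
  ppi <- mini_graph("A-B")
  gi <- mini_gi(c("A-B" = "positive", "A-C" = "negative", "B-C" = "negative"))
  # three FNM-ish sets to populate pairs; score checked by direct construction
  cnet <- build_complex_network(
    list(c("A", "B", "X"), c("A", "C", "X"), c("B", "C", "X"),
         c("A", "B", "Y")),
    cmap, ppi, gi)
  cons <- consensus_gi(cnet)
  s <- cons$scores
  ab <- s[s$complex_a == "C1" & s$complex_b == "C2", ]
  expect_equal(ab$score, 1)          # both contributions positive
  expect_equal(ab$n_pos, 2)
  ac <- s[s$complex_a == "C1" & s$complex_b == "C3", ]
  expect_equal(ac$score, -1)
  expect_true(all(s$score >= -1 & s$score <= 1))
  # antisymmetry of the formula
  expect_equal((3 - 1) / (3 + 1), 0.5)
  expect_equal((1 - 3) / (1 + 3), -0.5)
})

test_that("edge overlap partition counts PPI-and-GI, PPI-only, GI-only", {
  cmap <- complex_map(list(C1 = "A", C2 = "B", C3 = "C"))
  ppi <- mini_graph("A-B,B-C")
  gi <- mini_gi(c("A-C" = "negative", "B-C" = "positive"))
  cnet <- build_complex_network(
    list(c("A", "B", "C")), cmap, ppi, gi)
  cons <- consensus_gi(cnet)
  expect_equal(unname(cons$overlap),
               c(1 / 3, 1 / 3, 1 / 3))   # B-C both, A-B ppi-only, A-C gi-only
})

test_that("restricted betweenness hand cases are exact", {
  # single path C1-x-C2
  g1 <- mini_graph("C1-X,X-C2")
  b1 <- restricted_betweenness(g1, c("C1", "C2"))
  expect_equal(b1[["X"]], 1)

  # star: three complexes adjacent to x
  g2 <- mini_graph("C1-X,C2-X,C3-X")
  b2 <- restricted_betweenness(g2, c("C1", "C2", "C3"))
  expect_equal(b2[["X"]], 3)

  # two parallel mediators split the dependency
  g3 <- mini_graph("C1-X,X-C2,C1-Y,Y-C2")
  b3 <- restricted_betweenness(g3, c("C1", "C2"))
  expect_equal(b3[["X"]], 0.5)
  expect_equal(b3[["Y"]], 0.5)
})

test_that("restricted betweenness matches exhaustive path enumeration", {
  oracle <- function(g, endpoints) {
    nm <- sort(igraph::V(g)$name)
    aux <- setdiff(nm, endpoints)
    B <- stats::setNames(numeric(length(aux)), aux)
    eps <- intersect(endpoints, nm)
    if (length(eps) < 2) return(B)
    prs <- utils::combn(sort(eps), 2)
    for (c1 in seq_len(ncol(prs))) {
      s <- prs[1, c1]; t <- prs[2, c1]
      d <- igraph::distances(g, v = s, to = t)[1, 1]
      if (!is.finite(d)) next
      paths <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
      np <- length(paths)
      for (p in paths) {
        inner <- setdiff(igraph::V(g)$name[p], c(s, t))
        inner <- intersect(inner, aux)
        B[inner] <- B[inner] + 1 / np
      }
    }
    B
  }
  set.seed(200)
  for (trial in 1:10) {
    g <- er_graph(12, 0.25, 200 + trial)
    eps <- sample(igraph::V(g)$name, 4)
    got <- restricted_betweenness(g, eps)
    want <- oracle(g, eps)
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 tolerance = 1e-12)
  }
})

test_that("auxiliary ranking reports effective sizes and top nodes", {
  g <- mini_graph("C1-X,X-C2,C2-Y,Y-C3,C1-Z", isolates = "W")
  r <- rank_auxiliary(list(net1 = list(net = g, endpoints = c("C1", "C2", "C3"))))
  expect_equal(r$sizes$n_aux, 4)          # X, Y, Z, W
  expect_equal(r$sizes$n_effective, 2)    # X and Y mediate
  expect_equal(r$top$gene[1], "X")
})

test_that("bridging FNMs require both systems and group by shared genes", {
  fnms <- list(c("TF1", "E1", "X"),      # bridges
               c("TF1", "A", "B"),       # TF only
               c("E2", "C", "D"),        # metabolic only
               c("TF2", "E2", "X"),      # bridges, shares X with first
               c("TF3", "E3", "Q"))      # bridges, separate
  grp <- bridging_fnms(fnms, c("TF1", "TF2", "TF3"), c("E1", "E2", "E3"))
  expect_length(grp, 2)
  sizes <- sort(vapply(grp, function(g) length(g$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))
})
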