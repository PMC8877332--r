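# brute-force hypergeometric oracle: two-sided p as the sum of probabilities
# of all tables (at fixed margins) no more likely than the observed one
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  }, numeric(1))
  obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("Fisher exact p matches the hypergeometric enumeration oracle", {
  tables <- list(matrix(c(5, 5, 5, 5), 2),
                 matrix(c(10, 0, 0, 10), 2),
                 matrix(c(2, 7, 8, 3), 2),
                 matrix(c(1, 4, 6, 1), 2),
                 matrix(c(3, 3, 0, 6), 2))
  for (tab in tables) {
    expect_equal(fisher_exact_2x2(tab)$p, fisher_oracle(tab), tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
})

test_that("Fisher p is invariant under transposition and row/col swaps", {
  set.seed(400)
  for (trial in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)$p
    expect_equal(fisher_exact_2x2(t(tab))$p, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p, p, tolerance = 1e-12)
  }
})

test_that("zero-margin tables return p = 1 with undefined odds ratio", {
  r <- fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2))
  expect_equal(r$p, 1)
  expect_true(is.na(r$odds_ratio))
})

test_that("U statistic handles separation, identity, and midrank ties", {
  expect_equal(mann_whitney_u(1:3, 4:6)$U, 0)
  x <- c(2, 4, 6)
  expect_equal(mann_whitney_u(x, x)$U, length(x)^2 / 2)
  # tied values share midranks: U must be symmetric
  r <- mann_whitney_u(c(1, 2, 2), c(2, 3))
  expect_equal(r$U + mann_whitney_u(c(2, 3), c(1, 2, 2))$U, 6)
})

test_that("exact WMW p agrees with wilcox.test on tie-free small samples", {
  set.seed(401)
  for (trial in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:100, n1); y <- sample(setdiff(1:100, x), n2)
    got <- mann_whitney_u(x, y)
    want <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$U, unname(want$statistic))
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
    expect_equal(got$method, "exact")
  }
})

test_that("exact WMW p agrees with direct enumeration under ties", {
  enum_oracle <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    rk <- rank(c(x, y))
    Uobs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(utils::combn(n, n1), 2, function(ix)
      sum(rk[ix]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= Uobs), mean(us >= Uobs)))
  }
  cases <- list(list(x = c(1, 2, 2, 5), y = c(2, 3, 3)),
                list(x = c(0, 0, 1), y = c(0, 1, 1, 2)),
                list(x = c(1, 3, 5), y = c(2, 4)))
  for (cs in cases) {
    got <- mann_whitney_u(cs$x, cs$y)
    expect_equal(got$p, enum_oracle(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("large-sample WMW uses the tie-corrected normal approximation", {
  set.seed(402)
  x <- rnorm(30); y <- rnorm(35, 0.8)
  got <- mann_whitney_u(x, y)
  want <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p, want$p.value, tolerance = 1e-9)
  expect_equal(got$method, "normal")
})

test_that("matched controls reproduce the target (k, gi_count) histogram", {
  set.seed(403)
  pool <- data.frame(
    k = rep(c(3L, 4L), c(3000, 3000)),
    gi_count = c(sample(0:2, 3000, TRUE), sample(0:3, 3000, TRUE)),
    is_fnm = FALSE)
  prof <- data.frame(k = c(3L, 4L), gi_count = c(2L, 3L),
                     count = c(70L, 30L))
  ctrl <- matched_control_motifs(pool, prof, n = 1000, seed = 9)
  expect_equal(nrow(ctrl), 1000)
  shares <- table(ctrl$k) / 1000
  expect_lt(abs(shares[["3"]] - 0.70), 0.03)
  expect_lt(abs(shares[["4"]] - 0.30), 0.03)
  expect_true(all(ctrl$gi_count[ctrl$k == 3] == 2))
  # determinism
  ctrl2 <- matched_control_motifs(pool, prof, n = 1000, seed = 9)
  expect_identical(ctrl, ctrl2)
  # single-stratum profile
  prof1 <- data.frame(k = 3L, gi_count = 2L, count = 10L)
  c1 <- matched_control_motifs(pool, prof1, n = 50, seed = 2)
  expect_true(all(c1$k == 3 & c1$gi_count == 2))
})

test_that("empty strata trigger renormalized allocation with a warning", {
  pool <- data.frame(k = 3L, gi_count = 2L, is_fnm = FALSE)
  pool <- pool[rep(1, 100), ]
  prof <- data.frame(k = c(3L, 6L), gi_count = c(2L, 8L), count = c(50L, 50L))
  expect_warning(ctrl <- matched_control_motifs(pool, prof, n = 40, seed = 1),
                 "renormalized")
  expect_equal(nrow(ctrl), 40)
  expect_true(all(ctrl$k == 3))
})

test_that("per-motif property fractions and pair containment follow definitions", {
  motifs <- list(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(motif_gene_fractions(motifs, c("A", "C")), c(2 / 3, 1 / 3))
  pairs <- data.frame(gene_a = "A", gene_b = "C")
  sf <- suppressor_fraction(motifs, pairs)
  expect_equal(sf$fraction, 0.5)       # both members needed
  pairs2 <- data.frame(gene_a = "A", gene_b = "D")
  expect_equal(suppressor_fraction(motifs, pairs2)$fraction, 0)
})

test_that("planted suppressor enrichment is detected at alpha = 0.01", {
  set.seed(404)
  genes <- sprintf("G%03d", 1:120)
  pairs <- data.frame(gene_a = genes[seq(1, 60, 2)],
                      gene_b = genes[seq(2, 60, 2)])
  n <- 500
  # FNM-like motifs contain a suppressor pair at 3x the background rate
  make_motifs <- function(rate) {
    lapply(seq_len(n), function(i) {
      if (runif(1) < rate) {
        j <- sample(nrow(pairs), 1)
        c(pairs$gene_a[j], pairs$gene_b[j], sample(genes, 1))
      } else sample(genes, 3)
    })
  }
  fnm_m <- make_motifs(0.45)
  ppi_m <- make_motifs(0.15)
  a <- suppressor_fraction(fnm_m, pairs)
  b <- suppressor_fraction(ppi_m, pairs)
  tab <- matrix(c(a$n_with_pair, a$n_motifs - a$n_with_pair,
                  b$n_with_pair, b$n_motifs - b$n_with_pair), 2, byrow = TRUE)
  expect_lt(fisher_exact_2x2(tab)$p, 0.01)
})
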