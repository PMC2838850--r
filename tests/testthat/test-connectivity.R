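# toy world: two cross-A QTLs (3 + 2 genes) and two cross-B QTLs (4 + 1),
# plus one gene outside all QTLs
toy <- make_disjoint_genome(c(3, 2), c(4, 1), n_outside = 1)
toy_genes <- split(toy$catalog$symbol, rep(c("QA01", "QA02", "QB01", "QB02",
                                             "out"), c(3, 2, 4, 1, 1)))

test_that("build_connection_graph dedups, drops self/outside/unresolved", {
  links <- data.frame(
    from = c(toy_genes$QA01[1], toy_genes$QB01[1], toy_genes$QA01[1],
             toy_genes$QA01[2], toy_genes$QA01[3], "nosuch"),
    to = c(toy_genes$QB01[1], toy_genes$QA01[1], toy_genes$QA01[1],
           toy_genes$out[1], toy_genes$QA02[1], toy_genes$QB01[2]))
  expect_message(g <- build_connection_graph(links, toy$catalog, toy$qtls),
                 "unresolvable")
  # A<->B dedup to one cross-cross edge; self-link gone; link to the
  # outside gene gone; same-cross edge kept but labelled
  expect_equal(nrow(g$edges), 2)
  expect_equal(sum(g$edges$cross_cross), 1)
  expect_equal(g$qtl_info$n_genes[order(g$qtl_info$qtl_symbol)],
               c(3L, 2L, 4L, 1L))
})

test_that("count_pairs: empty graph, complete bipartite, symmetry, errors", {
  empty <- build_connection_graph(data.frame(from = character(),
                                             to = character()),
                                  toy$catalog, toy$qtls)
  expect_equal(count_pairs(empty, "QA01", "QB02"), 0L)

  # complete bipartite 3 x 2 between QA01 (3 genes) and {QB01[1], QB02[1]}
  targets <- c(toy_genes$QB01[1], toy_genes$QB02[1])
  links <- expand.grid(from = toy_genes$QA01, to = targets,
                       stringsAsFactors = FALSE)
  g <- build_connection_graph(links, toy$catalog, toy$qtls)
  expect_equal(count_pairs(g, "QA01", "QB01") + count_pairs(g, "QA01", "QB02"),
               6L)
  # argument order does not matter
  expect_equal(count_pairs(g, "QB01", "QA01"), count_pairs(g, "QA01", "QB01"))
  expect_error(count_pairs(g, "QA01", "QA02"), "opposite crosses")
})

test_that("count_pairs equals brute-force enumeration on random instances", {
  set.seed(77)
  for (i in 1:60) {
    gg <- make_disjoint_genome(sample(1:4, 2), sample(1:4, 2),
                               n_outside = 2)
    syms <- gg$catalog$symbol
    nl <- sample(0:15, 1)
    links <- data.frame(from = sample(syms, nl, replace = TRUE),
                        to = sample(syms, nl, replace = TRUE))
    g <- build_connection_graph(links, gg$catalog, gg$qtls)
    m <- gene_qtl_membership(gg$catalog, gg$qtls)
    for (q1 in unique(gg$qtls$qtl_symbol[gg$qtls$cross_id == "crossA"])) {
      for (q2 in unique(gg$qtls$qtl_symbol[gg$qtls$cross_id == "crossB"])) {
        want <- oracle_count_pairs(g$edges,
                                   m$symbol[m$qtl_symbol == q1],
                                   m$symbol[m$qtl_symbol == q2])
        expect_equal(count_pairs(g, q1, q2), want)
      }
    }
  }
})

test_that("expected_pairs matches hand arithmetic and conserves T", {
  # gene counts (2,3) x (4,1): weights {8,2,12,3}, T=10 -> 10*8/25 = 3.2
  gg <- make_disjoint_genome(c(2, 3), c(4, 1))
  m <- gene_qtl_membership(gg$catalog, gg$qtls)
  gA <- m$symbol[m$qtl_symbol == "QA01"]
  gB <- m$symbol[m$qtl_symbol == "QB01"]
  set.seed(8)
  u <- expand.grid(from = m$symbol[m$cross_id == "crossA"],
                   to = m$symbol[m$cross_id == "crossB"],
                   stringsAsFactors = FALSE)
  links <- u[sample(nrow(u), 10), ]
  g <- build_connection_graph(links, gg$catalog, gg$qtls)
  expect_equal(sum(g$edges$cross_cross), 10)
  expect_equal(expected_pairs(g, "QA01", "QB01"), 10 * 8 / 25)

  # symmetry: all QTLs equal-sized -> expected = T/(k1*k2)
  ge <- make_disjoint_genome(c(3, 3), c(3, 3))
  me <- gene_qtl_membership(ge$catalog, ge$qtls)
  ue <- expand.grid(from = me$symbol[me$cross_id == "crossA"],
                    to = me$symbol[me$cross_id == "crossB"],
                    stringsAsFactors = FALSE)
  gl <- build_connection_graph(ue[sample(nrow(ue), 12), ],
                               ge$catalog, ge$qtls)
  for (q1 in c("QA01", "QA02")) {
    for (q2 in c("QB01", "QB02")) {
      expect_equal(expected_pairs(gl, q1, q2), 12 / 4)
    }
  }

  # conservation: sum of expected over all pairs equals T
  pr <- qtl_pair_results(gl)
  expect_equal(sum(pr$expected), sum(gl$edges$cross_cross))

  # T = 0 -> untestable
  g0 <- build_connection_graph(data.frame(from = character(),
                                          to = character()),
                               gg$catalog, gg$qtls)
  expect_true(is.na(expected_pairs(g0, "QA01", "QB01")))
})

test_that("yates_chisq: worked value, clamp, invariances, margins", {
  r <- yates_chisq(20, 10, 15, 30)
  expect_equal(r$chi2, 6.752232, tolerance = 1e-6)

  # proportional table: |ad-bc| = 0 -> statistic clamped at 0, p = 1
  r0 <- yates_chisq(10, 20, 30, 60)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # small deviation within N/2 also clamps to zero
  expect_equal(yates_chisq(5, 5, 5, 6)$chi2, 0)

  # zero margin -> untestable
  z <- yates_chisq(0, 0, 10, 20)
  expect_false(z$testable)
  expect_true(is.na(z$chi2))

  set.seed(99)
  for (i in 1:200) {
    t <- sample(0:40, 4, replace = TRUE)
    if (any(c(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4]) == 0)) next
    r <- yates_chisq(t[1], t[2], t[3], t[4])
    o <- oracle_yates(t[1], t[2], t[3], t[4])
    expect_equal(r$chi2, o$chi2)
    expect_equal(r$p, o$p)
    # transposition and row/column swaps leave the statistic unchanged
    expect_equal(yates_chisq(t[1], t[3], t[2], t[4])$chi2, r$chi2)
    expect_equal(yates_chisq(t[3], t[4], t[1], t[2])$chi2, r$chi2)
    expect_equal(yates_chisq(t[2], t[1], t[4], t[3])$chi2, r$chi2)
  }
})

test_that("qtl_pair_results flags planted excess and handles degenerate cases", {
  # single QTL per cross: the only pair carries all edges, p = 1
  g1 <- make_disjoint_genome(3, 4)
  m <- gene_qtl_membership(g1$catalog, g1$qtls)
  u <- expand.grid(from = m$symbol[m$cross_id == "crossA"],
                   to = m$symbol[m$cross_id == "crossB"],
                   stringsAsFactors = FALSE)
  g <- build_connection_graph(u, g1$catalog, g1$qtls)
  pr <- qtl_pair_results(g)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$observed, 12L)
  expect_equal(pr$expected, 12)
  expect_equal(pr$p, 1)
  expect_equal(pr$flag, "")

  # strong excess on one pair of a 2x2 QTL layout gets flagged
  set.seed(12)
  gg <- make_disjoint_genome(c(10, 10), c(10, 10))
  mm <- gene_qtl_membership(gg$catalog, gg$qtls)
  inA <- function(q) mm$symbol[mm$qtl_symbol == q]
  dense <- expand.grid(from = inA("QA01"), to = inA("QB01"),
                       stringsAsFactors = FALSE)   # 100 pairs
  sparse <- data.frame(from = sample(inA("QA02"), 6, replace = TRUE),
                       to = sample(inA("QB02"), 6, replace = TRUE))
  g2 <- build_connection_graph(rbind(dense, sparse), gg$catalog, gg$qtls)
  pr2 <- qtl_pair_results(g2)
  expect_equal(pr2$qtl1[1], "QA01")
  expect_equal(pr2$qtl2[1], "QB01")
  expect_equal(pr2$flag[1], "significant")
  expect_true(all(pr2$p_holm >= pr2$p, na.rm = TRUE))

  # near-miss window: rerun with alpha below this pair's p
  p0 <- pr2$p[1]
  pr3 <- qtl_pair_results(g2, alpha = p0 * 0.5, near_miss = p0 * 1.5)
  expect_equal(pr3$flag[1], "near-miss")
})

test_that("filter_high_score_pairs applies the inclusive threshold", {
  pairs <- data.frame(gene1 = c("a", "b", "c"), gene2 = c("x", "y", "z"))
  scores <- c(a = 49.9, x = 12, b = 50, y = 0, c = 120, z = 80)
  out <- filter_high_score_pairs(pairs, scores)
  expect_equal(out$gene1, c("b", "c"))
  expect_error(filter_high_score_pairs(pairs, scores[-1]), "unscored.*a")
})

test_that("connection graphs honour multi-QTL membership", {
  # one gene lies in two overlapping cross-A QTLs; its edges count for both
  qtls <- make_qtls(c("QA01", "QA02", "QB01"),
                    c("crossA", "crossA", "crossB"),
                    c("chr1", "chr1", "chr2"),
                    c(1, 50, 1), c(100, 200, 100))
  cat <- make_catalog(c("g1", "g2"), c("chr1", "chr2"), c(60, 10),
                      c(70, 20))
  g <- build_connection_graph(data.frame(from = "g1", to = "g2"), cat, qtls)
  expect_equal(count_pairs(g, "QA01", "QB01"), 1L)
  expect_equal(count_pairs(g, "QA02", "QB01"), 1L)
  pr <- qtl_pair_results(g)
  expect_equal(nrow(pr), 2)
})
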