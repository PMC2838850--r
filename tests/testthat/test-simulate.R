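# a small, fast world shared by most generator tests
small_cfg <- function(...) {
  defaults <- list(n_chromosomes = 6, chrom_length = 2e6, n_genes = 150,
                   n_qtls_per_cross = c(3, 4), keyword_set_size = 12,
                   filler_range = c(5, 12), edge_count = 40, seed = 123)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$qtls, s2$qtls)
  expect_identical(s1$keywords, s2$keywords)
  expect_identical(s1$corpus$records, s2$corpus$records)
  expect_identical(s1$links, s2$links)
  s3 <- simulate_study(small_cfg(seed = 124))
  expect_false(identical(s1$corpus$records$text, s3$corpus$records$text))

  # byte-identical files too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), dir = d1)
  simulate_study(small_cfg(), dir = d2)
  for (f in c("catalog.tsv", "qtls.tsv", "keywords.tsv", "corpus.jsonl",
              "links.tsv", "cooccurrence.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generated files round-trip through the package readers", {
  d <- withr::local_tempdir()
  st <- simulate_study(small_cfg(), dir = d)
  expect_identical(read_gene_catalog(st$paths[["catalog"]]), st$catalog)
  expect_identical(read_qtl_table(st$paths[["qtls"]]), st$qtls)
  kw <- read_keywords(st$paths[["keywords"]])
  expect_equal(kw$term, st$keywords$term)
  expect_equal(kw$weight, st$keywords$weight)
  back <- read_corpus(st$paths[["corpus"]])
  expect_identical(back$records, st$corpus$records)
  expect_setequal(paste(back$links$from, back$links$to),
                  paste(st$corpus$links$from, st$corpus$links$to))
  lk <- read_links(st$paths[["links"]])
  expect_identical(lk, st$links)
  cooc <- read_cooccurrence(st$paths[["cooccurrence"]])
  expect_equal(keywords_from_cooccurrence(cooc)$weight, st$keywords$weight)
})

test_that("QTL coverage hits its target and degenerate settings work", {
  # realized inside-gene fraction near the 0.5 target across seeds
  fr <- vapply(1:6, function(s) {
    g <- generate_genome(small_cfg(seed = 200 + s, n_genes = 400))
    mean(classify_genes(g$catalog, g$qtls))
  }, numeric(1))
  expect_gt(mean(fr), 0.40)
  expect_lt(mean(fr), 0.60)

  # full coverage: every gene inside
  g1 <- generate_genome(small_cfg(qtl_coverage_fraction = 1,
                                  n_qtls_per_cross = c(3, 4)))
  expect_true(all(classify_genes(g1$catalog, g1$qtls)))

  # no QTLs: every gene outside
  g0 <- generate_genome(small_cfg(n_qtls_per_cross = c(0, 0)))
  expect_equal(nrow(g0$qtls), 0)
  expect_false(any(classify_genes(g0$catalog, g0$qtls)))

  # infeasible: one tiny QTL cannot cover half the genome
  expect_error(generate_genome(small_cfg(n_qtls_per_cross = c(1, 0),
                                         n_chromosomes = 10)),
               "infeasible")
})

test_that("corpus generation responds to keyword rate and enrichment", {
  g <- generate_genome(small_cfg())
  co0 <- generate_corpus(small_cfg(baseline_keyword_rate = 0), g)
  expect_true(all(score_corpus(co0$corpus, co0$keywords)$cgc_score == 0))

  # enrichment raises mean scores inside QTLs (averaged over replicates)
  diffs <- vapply(1:5, function(s) {
    cfg <- small_cfg(seed = 300 + s, inside_enrichment = 3,
                     baseline_keyword_rate = 0.05)
    gg <- generate_genome(cfg)
    co <- generate_corpus(cfg, gg)
    sc <- score_corpus(co$corpus, co$keywords)
    inside <- classify_genes(gg$catalog, gg$qtls)
    mean(sc$cgc_score[inside]) - mean(sc$cgc_score[!inside])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.6)

  # weights are valid percentages and terms are unique
  co <- generate_corpus(small_cfg(), g)
  expect_true(all(co$keywords$weight >= 0 & co$keywords$weight <= 100))
  expect_equal(anyDuplicated(co$keywords$term), 0)
})

test_that("link generation respects counts, excess and feasibility", {
  g <- generate_genome(small_cfg())
  expect_equal(nrow(generate_links(small_cfg(edge_count = 0), g)), 0)

  links <- generate_links(small_cfg(), g)
  expect_equal(nrow(links), 40)
  expect_equal(anyDuplicated(paste(pmin(links$from, links$to),
                                   pmax(links$from, links$to))), 0)
  expect_true(all(links$from != links$to))

  # infinite excess confines all edges to the designated pair
  dp <- designate_clean_pair(g$catalog, g$qtls)
  cfg_inf <- small_cfg(edge_count = 5)
  cfg_inf$pair_excess <- stats::setNames(list(Inf), dp$key)
  li <- generate_links(cfg_inf, g)
  gr <- build_connection_graph(li, g$catalog, g$qtls)
  expect_equal(count_pairs(gr, dp$qtl1, dp$qtl2), 5L)

  expect_error(generate_links(small_cfg(edge_count = 10^7), g), "exceeds")
})

test_that("null links land on QTL pairs in proportion to gene-count products", {
  # hand-built disjoint genome so the multinomial expectation is exact
  gg <- make_disjoint_genome(c(6, 10), c(8, 5, 12))
  base <- small_cfg(edge_count = 60)
  counts <- NULL
  for (r in 1:60) {
    cfg <- base
    cfg$seed <- 4000 + r
    links <- generate_links(cfg, gg)
    g <- build_connection_graph(links, gg$catalog, gg$qtls)
    pr <- qtl_pair_results(g)
    key <- paste(pr$qtl1, pr$qtl2)
    if (is.null(counts)) counts <- setNames(numeric(length(key)), key)
    counts[key] <- counts[key] + pr$observed
    if (r == 1) expected_prop <- pr$expected / sum(pr$expected)
  }
  gof <- suppressWarnings(chisq.test(counts, p = expected_prop))
  expect_gt(gof$p.value, 0.001)
})

test_that("designate_clean_pair prefers exclusive QTLs and largest size", {
  gg <- make_disjoint_genome(c(4, 9), c(3, 7))
  dp <- designate_clean_pair(gg$catalog, gg$qtls)
  expect_equal(dp$qtl1, "QA02")  # 9 genes
  expect_equal(dp$qtl2, "QB02")  # 7 genes
  expect_equal(dp$key, "QA02|QB02")
})
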