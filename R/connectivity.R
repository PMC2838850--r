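#' Build the gene connection graph over QTL regions
#'
#' Record hyperlinks are turned into undirected, deduplicated gene-gene
#' edges (a link A->B and B->A is one edge; self-links are dropped).  Link
#' endpoints that cannot be resolved in the catalog are logged and dropped.
#' Only edges whose endpoints both lie inside at least one QTL are
#' retained; each retained edge is labelled cross-cross if its endpoints
#' can be placed in QTLs from two different crosses, same-cross otherwise.
#' A gene overlapping several QTLs is a member of each of them, and a QTL
#' symbol mapped in both crosses appears once per cross.
#'
#' @param links Either a `cgc_corpus` (its embedded links are used) or a
#'   data frame with columns `from`, `to`.
#' @param catalog Gene catalog (see [read_gene_catalog()]).
#' @param qtls QTL table (see [read_qtl_table()]); must span exactly two
#'   cross identifiers for pair analysis.
#' @param overlap Overlap mode for gene-QTL membership (see
#'   [classify_genes()]).
#' @return A list of class `cgc_graph`: `edges` (data frame `g1`, `g2`,
#'   `cross_cross`), `membership` (data frame `symbol`, `qtl_symbol`,
#'   `cross_id`), `qtl_info` (per cross/QTL gene counts), `crosses`.
#' @export
build_connection_graph <- function(links, catalog, qtls,
                                   overlap = c("any", "full")) {
  overlap <- match.arg(overlap)
  if (inherits(links, "cgc_corpus")) links <- links$links
  links <- data.frame(from = as.character(links$from),
                      to = as.character(links$to),
                      stringsAsFactors = FALSE)
  unresolved <- setdiff(unique(c(links$from, links$to)), catalog$symbol)
  if (length(unresolved)) {
    cgc_log("dropping links with ", length(unresolved),
            " unresolvable symbol(s): ",
            paste(utils::head(unresolved, 5), collapse = ", "),
            if (length(unresolved) > 5) ", ...")
    links <- links[links$from %in% catalog$symbol &
                     links$to %in% catalog$symbol, , drop = FALSE]
  }
  g1 <- pmin(links$from, links$to)
  g2 <- pmax(links$from, links$to)
  keep <- g1 != g2
  edges <- unique(data.frame(g1 = g1[keep], g2 = g2[keep],
                             stringsAsFactors = FALSE))

  membership <- gene_qtl_membership(catalog, qtls, overlap)
  in_qtl <- unique(membership$symbol)
  edges <- edges[edges$g1 %in% in_qtl & edges$g2 %in% in_qtl, , drop = FALSE]

  crosses <- sort(unique(qtls$cross_id))
  cross_of <- split(membership$cross_id, membership$symbol)
  has_cross <- function(sym, cr) {
    vapply(cross_of[sym], function(cs) cr %in% cs, logical(1))
  }
  if (length(crosses) == 2L && nrow(edges) > 0L) {
    cc <- (has_cross(edges$g1, crosses[1]) & has_cross(edges$g2, crosses[2])) |
      (has_cross(edges$g2, crosses[1]) & has_cross(edges$g1, crosses[2]))
  } else {
    cc <- logical(nrow(edges))
  }
  edges$cross_cross <- cc

  qtl_info <- unique(qtls[, c("qtl_symbol", "cross_id")])
  cnt <- table(paste(membership$qtl_symbol, membership$cross_id, sep = "\r"))
  key <- paste(qtl_info$qtl_symbol, qtl_info$cross_id, sep = "\r")
  qtl_info$n_genes <- as.integer(ifelse(key %in% names(cnt), cnt[key], 0L))
  rownames(edges) <- rownames(qtl_info) <- NULL

  structure(list(edges = edges, membership = membership,
                 qtl_info = qtl_info, crosses = crosses),
            class = "cgc_graph")
}

#' @export
print.cgc_graph <- function(x, ...) {
  cat("cgc_graph:", nrow(x$edges), "edges (",
      sum(x$edges$cross_cross), "cross-cross ),",
      nrow(x$qtl_info), "QTL/cross entries,",
      length(unique(x$membership$symbol)), "genes in QTLs\n")
  invisible(x)
}

#' Gene-to-QTL membership table
#'
#' One row per (gene, QTL-in-a-cross) overlap; intervals are compared
#' individually (not flattened), so a gene in two overlapping QTLs gets two
#' rows.
#'
#' @inheritParams build_connection_graph
#' @return Data frame `symbol`, `qtl_symbol`, `cross_id`.
#' @export
gene_qtl_membership <- function(catalog, qtls, overlap = c("any", "full")) {
  overlap <- match.arg(overlap)
  if (nrow(qtls) == 0L) {
    return(data.frame(symbol = character(), qtl_symbol = character(),
                      cross_id = character(), stringsAsFactors = FALSE))
  }
  lev <- chrom_universe(catalog, qtls)
  genes <- granges_on(catalog$chrom, catalog$start, catalog$stop, lev)
  qr <- granges_on(qtls$chrom, qtls$start, qtls$stop, lev)
  type <- if (overlap == "any") "any" else "within"
  hits <- GenomicRanges::findOverlaps(genes, qr, type = type)
  data.frame(symbol = catalog$symbol[S4Vectors::queryHits(hits)],
             qtl_symbol = qtls$qtl_symbol[S4Vectors::subjectHits(hits)],
             cross_id = qtls$cross_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

## Per-edge QTL pair incidence: for each cross-cross edge, every distinct
## (QTL in cross 1, QTL in cross 2) pair it connects, excluding pairs of
## the same QTL symbol (a locus mapped in both crosses never pairs with
## itself).
edge_pair_incidence <- function(graph) {
  stopifnot(length(graph$crosses) == 2L)
  ed <- graph$edges[graph$edges$cross_cross, , drop = FALSE]
  empty <- data.frame(edge = integer(), q1 = character(), q2 = character(),
                      g_in_q1 = character(), g_in_q2 = character(),
                      stringsAsFactors = FALSE)
  if (nrow(ed) == 0L) return(empty)
  ed$edge <- seq_len(nrow(ed))
  m <- graph$membership
  m1 <- m[m$cross_id == graph$crosses[1], c("symbol", "qtl_symbol")]
  m2 <- m[m$cross_id == graph$crosses[2], c("symbol", "qtl_symbol")]
  names(m1) <- c("sym", "q1")
  names(m2) <- c("sym", "q2")
  orient <- function(a, b) {
    x <- merge(data.frame(edge = ed$edge, sym = ed[[a]], other = ed[[b]],
                          stringsAsFactors = FALSE), m1, by = "sym")
    names(x)[names(x) == "sym"] <- "g_in_q1"
    names(x)[names(x) == "other"] <- "sym"
    x <- merge(x, m2, by = "sym")
    names(x)[names(x) == "sym"] <- "g_in_q2"
    x[, c("edge", "q1", "q2", "g_in_q1", "g_in_q2")]
  }
  inc <- rbind(orient("g1", "g2"), orient("g2", "g1"))
  inc <- inc[inc$q1 != inc$q2, , drop = FALSE]
  inc <- unique(inc)
  if (nrow(inc) == 0L) empty else inc
}

qtl_levels <- function(graph, cross) {
  info <- graph$qtl_info
  sort(info$qtl_symbol[info$cross_id == cross])
}

## Observed count matrix O[q1, q2]: distinct connecting edges per QTL pair.
pair_count_matrix <- function(graph) {
  l1 <- qtl_levels(graph, graph$crosses[1])
  l2 <- qtl_levels(graph, graph$crosses[2])
  inc <- edge_pair_incidence(graph)
  inc <- unique(inc[, c("edge", "q1", "q2")])
  O <- table(factor(inc$q1, levels = l1), factor(inc$q2, levels = l2))
  matrix(as.integer(O), nrow = length(l1), dimnames = list(l1, l2))
}

#' Observed number of gene pairs connecting two QTLs
#'
#' Counts distinct unordered gene pairs (one gene in each QTL) joined by an
#' edge.  The two QTLs must come from opposite crosses.
#'
#' @param graph A `cgc_graph`.
#' @param qtl1,qtl2 QTL symbols, one per cross (either order).
#' @return Integer count.
#' @export
count_pairs <- function(graph, qtl1, qtl2) {
  O <- pair_count_matrix(graph)
  ord <- orient_pair(graph, qtl1, qtl2)
  O[ord[1], ord[2]]
}

orient_pair <- function(graph, qtl1, qtl2) {
  l1 <- qtl_levels(graph, graph$crosses[1])
  l2 <- qtl_levels(graph, graph$crosses[2])
  if (qtl1 %in% l1 && qtl2 %in% l2) return(c(qtl1, qtl2))
  if (qtl2 %in% l1 && qtl1 %in% l2) return(c(qtl2, qtl1))
  stop("QTLs ", qtl1, " and ", qtl2,
       " are not a pair from opposite crosses", call. = FALSE)
}

#' Expected number of gene pairs connecting two QTLs
#'
#' Under the null that connections fall on QTL pairs in proportion to the
#' product of their gene counts: `expected = T * n1 * n2 / sum(n_i * n_j)`,
#' where `T` is the total number of cross-cross edges and the sum runs over
#' every admissible QTL pair (one per cross, unequal symbols).  Genes in
#' multiple QTLs contribute to each containing QTL's count.
#'
#' @inheritParams count_pairs
#' @return Expected count (numeric); `NA` with a message if `T` is 0
#'   (untestable).
#' @export
expected_pairs <- function(graph, qtl1, qtl2) {
  ord <- orient_pair(graph, qtl1, qtl2)
  tab <- pair_null_weights(graph)
  T_edges <- sum(graph$edges$cross_cross)
  if (T_edges == 0L) {
    return(NA_real_)
  }
  w <- tab$weight[tab$q1 == ord[1] & tab$q2 == ord[2]]
  T_edges * w / sum(tab$weight)
}

## Admissible pairs and their n1*n2 weights.
pair_null_weights <- function(graph) {
  info <- graph$qtl_info
  i1 <- info[info$cross_id == graph$crosses[1], ]
  i2 <- info[info$cross_id == graph$crosses[2], ]
  g <- expand.grid(a = seq_len(nrow(i1)), b = seq_len(nrow(i2)))
  out <- data.frame(q1 = i1$qtl_symbol[g$a], q2 = i2$qtl_symbol[g$b],
                    n1 = i1$n_genes[g$a], n2 = i2$n_genes[g$b],
                    stringsAsFactors = FALSE)
  out <- out[out$q1 != out$q2, , drop = FALSE]
  out$weight <- as.numeric(out$n1) * out$n2
  out
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' `chi2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' statistic set to 0 when `|ad - bc| <= N/2` (the correction would
#' otherwise overshoot).  P-value from the chi-square distribution with
#' 1 df.  Vectorized over the four cell arguments.
#'
#' @param a,b,c,d Non-negative cell counts (row-wise: `a b / c d`).
#' @return List with vectors `chi2`, `p`, `testable` (`FALSE` where a row
#'   or column margin is zero; there `chi2` and `p` are `NA`).
#' @export
yates_chisq <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  N <- a + b + c + d
  if (any(N == 0)) stop("empty table", call. = FALSE)
  m1 <- (a + b) * (c + d) * (a + c) * (b + d)
  testable <- m1 > 0
  dev <- pmax(abs(a * d - b * c) - N / 2, 0)
  chi2 <- ifelse(testable, N * dev^2 / m1, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, testable = testable)
}

#' Test every cross-cross QTL pair for excess shared gene pairs
#'
#' For each admissible QTL pair (q1 from cross 1, q2 from cross 2) the 2x2
#' table is: a = connections between q1 and q2; b = q1's other cross-cross
#' connections; c = q2's other cross-cross connections; d = all remaining
#' cross-cross connections.  A Yates-corrected chi-square is computed, and
#' pairs with more observed than expected connections and `p < alpha` are
#' flagged `"significant"`; pairs with `alpha <= p < near_miss` (and excess
#' observed) are flagged `"near-miss"`.  Holm-adjusted p-values are
#' reported alongside; flagging uses the raw p-values.
#'
#' @param graph A `cgc_graph` built over exactly two crosses.
#' @param alpha Significance level (default 0.05).
#' @param near_miss Upper p bound for near-miss reporting (default 0.06).
#' @return Data frame with columns `qtl1`, `n1`, `qtl2`, `n2`, `observed`,
#'   `expected`, `chi2`, `p`, `p_holm`, `flag` (one row per pair, sorted by
#'   p).
#' @export
qtl_pair_results <- function(graph, alpha = 0.05, near_miss = 0.06) {
  stopifnot(length(graph$crosses) == 2L)
  tab <- pair_null_weights(graph)
  O <- pair_count_matrix(graph)
  obs <- mapply(function(q1, q2) O[q1, q2], tab$q1, tab$q2)
  total <- sum(O)
  rs <- rowSums(O)[tab$q1]
  cs <- colSums(O)[tab$q2]
  a <- obs
  b <- rs - a
  cc <- cs - a
  d <- total - rs - cs + a
  T_edges <- sum(graph$edges$cross_cross)
  expected <- if (T_edges > 0 && sum(tab$weight) > 0) {
    T_edges * tab$weight / sum(tab$weight)
  } else {
    rep(NA_real_, nrow(tab))
  }
  yt <- if (total > 0) {
    yates_chisq(a, b, cc, d)
  } else {
    list(chi2 = rep(NA_real_, nrow(tab)), p = rep(NA_real_, nrow(tab)),
         testable = rep(FALSE, nrow(tab)))
  }
  # degenerate tables (zero off-target margins, e.g. a single admissible
  # pair) where the null predicts the observation exactly: report p = 1
  # rather than untestable
  certain <- !yt$testable & !is.na(expected) & obs == expected
  yt$chi2[certain] <- 0
  yt$p[certain] <- 1
  yt$testable[certain] <- TRUE
  p_holm <- rep(NA_real_, nrow(tab))
  p_holm[yt$testable] <- stats::p.adjust(yt$p[yt$testable], method = "holm")
  excess <- !is.na(expected) & obs > expected
  flag <- rep("", nrow(tab))
  flag[yt$testable & excess & yt$p < alpha] <- "significant"
  flag[yt$testable & excess & yt$p >= alpha & yt$p < near_miss] <- "near-miss"
  out <- data.frame(qtl1 = tab$q1, n1 = tab$n1, qtl2 = tab$q2, n2 = tab$n2,
                    observed = as.integer(obs), expected = expected,
                    chi2 = yt$chi2, p = yt$p, p_holm = p_holm, flag = flag,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$qtl1, out$qtl2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene pairs connecting two QTLs
#'
#' @inheritParams count_pairs
#' @return Data frame `gene1` (in the cross-1 QTL), `gene2` (in the cross-2
#'   QTL), one row per connecting edge.
#' @export
connecting_gene_pairs <- function(graph, qtl1, qtl2) {
  ord <- orient_pair(graph, qtl1, qtl2)
  inc <- edge_pair_incidence(graph)
  inc <- inc[inc$q1 == ord[1] & inc$q2 == ord[2], , drop = FALSE]
  out <- unique(data.frame(gene1 = inc$g_in_q1, gene2 = inc$g_in_q2,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Keep gene pairs where at least one gene scores above a threshold
#'
#' Retains pairs whose higher-scoring member has a CGC score at or above
#' `threshold` (inclusive; the study used 50 as the mark of a strong
#' arthritis candidate).
#'
#' @param pairs Data frame with columns `gene1`, `gene2`.
#' @param scores Named numeric vector of CGC scores, or a scored-genes data
#'   frame with `symbol` and `cgc_score`.
#' @param threshold Inclusive score threshold (default 50).
#' @return The filtered pairs, with `score1`, `score2` columns added.
#' @export
filter_high_score_pairs <- function(pairs, scores, threshold = 50) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$cgc_score, scores$symbol)
  }
  missing <- setdiff(unique(c(pairs$gene1, pairs$gene2)), names(scores))
  if (length(missing)) {
    stop("unscored gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs$score1 <- unname(scores[pairs$gene1])
  pairs$score2 <- unname(scores[pairs$gene2])
  keep <- pmax(pairs$score1, pairs$score2) >= threshold
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
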