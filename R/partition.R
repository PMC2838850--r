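#' Read a gene catalog
#'
#' TSV with header `symbol<TAB>chrom<TAB>start<TAB>stop`, 1-based inclusive
#' coordinates.  A path ending in `.bed` is read as headerless 6-column BED
#' (0-based half-open) and converted to 1-based inclusive.
#'
#' @param path Path to the catalog file.
#' @return Data frame `symbol`, `chrom`, `start`, `stop`.
#' @export
read_gene_catalog <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    d <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    out <- data.frame(symbol = as.character(d[[4]]),
                      chrom = as.character(d[[1]]),
                      start = as.integer(d[[2]]) + 1L,
                      stop = as.integer(d[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    d <- read_tsv(path)
    out <- data.frame(symbol = as.character(d$symbol),
                      chrom = as.character(d$chrom),
                      start = as.integer(d$start),
                      stop = as.integer(d$stop),
                      stringsAsFactors = FALSE)
  }
  validate_intervals(out, "gene catalog")
  if (anyDuplicated(out$symbol)) {
    stop("duplicate gene symbols in catalog", call. = FALSE)
  }
  out
}

#' Read a QTL interval table
#'
#' TSV mirroring the study's QTL list: columns `qtl_symbol`, `cross_id`,
#' `chrom`, `start`, `stop` and optionally `lod`, `p`.
#'
#' @param path Path to the QTL file.
#' @return Data frame with those columns (`lod`, `p` as `NA` if absent).
#' @export
read_qtl_table <- function(path) {
  d <- read_tsv(path)
  out <- data.frame(qtl_symbol = as.character(d$qtl_symbol),
                    cross_id = as.character(d$cross_id),
                    chrom = as.character(d$chrom),
                    start = as.integer(d$start),
                    stop = as.integer(d$stop),
                    lod = if ("lod" %in% names(d)) as.numeric(d$lod) else NA_real_,
                    p = if ("p" %in% names(d)) as.numeric(d$p) else NA_real_,
                    stringsAsFactors = FALSE)
  names(out)[1] <- "qtl_symbol"
  validate_intervals(stats::setNames(out[c("qtl_symbol", "chrom", "start",
                                           "stop")],
                                     c("symbol", "chrom", "start", "stop")),
                     "QTL table")
  if (anyDuplicated(paste(out$qtl_symbol, out$cross_id))) {
    stop("duplicate QTL symbols within a cross", call. = FALSE)
  }
  out
}

validate_intervals <- function(d, what) {
  if (any(d$start < 1L) || any(d$stop < d$start)) {
    stop(what, ": need 1 <= start <= stop", call. = FALSE)
  }
  invisible(d)
}

#' Write a QTL table to TSV
#' @param qtls Data frame as from [read_qtl_table()].
#' @param path Output path.
#' @export
write_qtl_table <- function(qtls, path) {
  write_tsv(qtls, path)
}

## GRanges on an explicit shared seqlevel set, so comparing gene and QTL
## ranges never warns about disjoint chromosome universes.
granges_on <- function(chrom, start, stop, levels) {
  GenomicRanges::GRanges(factor(chrom, levels = levels),
                         IRanges::IRanges(start, stop))
}

chrom_universe <- function(catalog, qtls) {
  sort(unique(c(catalog$chrom, qtls$chrom)))
}

#' Classify genes as inside or outside QTL regions
#'
#' A gene is "inside" if its interval shares at least one base with at
#' least one QTL interval on the same chromosome (`overlap = "any"`, the
#' default), or lies entirely within the flattened QTL union
#' (`overlap = "full"`).  Overlapping QTLs are flattened to their union so a
#' gene covered by several QTLs is counted once.
#'
#' @param catalog Gene catalog data frame (see [read_gene_catalog()]).
#' @param qtls QTL table (see [read_qtl_table()]); may have zero rows.
#' @param overlap `"any"` or `"full"`.
#' @return Logical vector, `TRUE` = inside, named by gene symbol.
#' @export
classify_genes <- function(catalog, qtls, overlap = c("any", "full")) {
  overlap <- match.arg(overlap)
  if (nrow(qtls) == 0L) {
    return(stats::setNames(rep(FALSE, nrow(catalog)), catalog$symbol))
  }
  lev <- chrom_universe(catalog, qtls)
  genes <- granges_on(catalog$chrom, catalog$start, catalog$stop, lev)
  union <- GenomicRanges::reduce(granges_on(qtls$chrom, qtls$start,
                                            qtls$stop, lev))
  type <- if (overlap == "any") "any" else "within"
  inside <- GenomicRanges::countOverlaps(genes, union, type = type) > 0L
  stats::setNames(inside, catalog$symbol)
}

#' Default CGC-score bin edges
#'
#' Lower edges of the seven half-open score strata used in the genome-wide
#' partition: `[0.1,10) [10,20) [20,30) [30,50) [50,100) [100,200) [200,Inf)`.
#' @return Numeric vector of bin edges including `Inf`.
#' @export
default_score_edges <- function() c(0.1, 10, 20, 30, 50, 100, 200, Inf)

#' Assign filtered CGC scores to score bins
#'
#' Bins are half-open `[lower, upper)`; a score of exactly 100 falls in the
#' 100-200 bin.  All scores must be at least the lowest edge (run
#' [filter_min_score()] first).
#'
#' @param scores Numeric vector of CGC scores.
#' @param edges Increasing numeric vector of bin edges ending in `Inf`.
#' @return Integer vector of bin indices (1 = lowest bin), with attribute
#'   `labels` giving display labels ordered from highest bin to lowest as in
#'   the report.
#' @export
bin_by_score <- function(scores, edges = default_score_edges()) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  if (any(scores < edges[1])) {
    stop("scores below the lowest bin edge (", edges[1],
         "); apply filter_min_score() first", call. = FALSE)
  }
  idx <- findInterval(scores, edges, rightmost.closed = FALSE)
  structure(idx, labels = bin_labels(edges))
}

bin_labels <- function(edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  ifelse(is.finite(hi), paste(lo, "-", hi), paste(lo, "-"))
}

#' Test one score bin's inside/outside split against the genome-wide split
#'
#' The default `"gof"` variant is a 1-df Pearson goodness-of-fit test of
#' the bin's (inside, outside) counts against the expected proportions from
#' the genome-wide totals, with no continuity correction.  `"2x2"` tests
#' the bin against all remaining genes in a 2x2 contingency table (also
#' uncorrected); both give nearly identical values here.
#'
#' @param n_inside,n_outside Counts in the bin.
#' @param total_inside,total_outside Genome-wide totals (all bins).
#' @param variant `"gof"` (default) or `"2x2"`.
#' @return List with `chi2`, `p`, and `testable` (`FALSE` for an empty bin,
#'   in which case `chi2` and `p` are `NA`).
#' @export
bin_proportion_test <- function(n_inside, n_outside, total_inside,
                                total_outside, variant = c("gof", "2x2")) {
  variant <- match.arg(variant)
  stopifnot(total_inside > 0, total_outside > 0)
  n <- n_inside + n_outside
  if (n == 0L) {
    return(list(chi2 = NA_real_, p = NA_real_, testable = FALSE))
  }
  p_in <- total_inside / (total_inside + total_outside)
  if (variant == "gof") {
    e_in <- n * p_in
    e_out <- n * (1 - p_in)
    chi2 <- (n_inside - e_in)^2 / e_in + (n_outside - e_out)^2 / e_out
  } else {
    tab <- rbind(c(n_inside, n_outside),
                 c(total_inside - n_inside, total_outside - n_outside))
    N <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / N
    chi2 <- sum((tab - e)^2 / e)
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       testable = TRUE)
}

#' Partition report: scored genes inside vs outside QTLs by score stratum
#'
#' Joins scored genes to the catalog, classifies each gene inside/outside
#' the QTL union, stratifies by CGC-score bin, and tests each bin's split
#' against the genome-wide proportion.  Scored symbols absent from the
#' catalog are listed in a warning and excluded.
#'
#' @param catalog Gene catalog.
#' @param qtls QTL table.
#' @param scored Scored genes (`symbol`, `cgc_score`), already filtered or
#'   filtered here via `min_score`.
#' @param min_score Inclusive score cut applied before binning (default 0.1).
#' @param edges Bin edges (see [bin_by_score()]).
#' @param overlap Overlap mode for [classify_genes()].
#' @param variant Test variant for [bin_proportion_test()].
#' @return Data frame with one row per bin, highest stratum first: columns
#'   `bin`, `lower`, `upper`, `n_inside`, `n_outside`, `chi2`, `p`,
#'   `testable`; attributes `totals` (list with `n_inside`, `n_outside`,
#'   `inside_pct`, `outside_pct`, integer-rounded percentages) and `edges`.
#' @export
partition_report <- function(catalog, qtls, scored, min_score = 0.1,
                             edges = default_score_edges(),
                             overlap = c("any", "full"),
                             variant = c("gof", "2x2")) {
  overlap <- match.arg(overlap)
  variant <- match.arg(variant)
  scored <- filter_min_score(scored, min_score)
  unknown <- setdiff(scored$symbol, catalog$symbol)
  if (length(unknown)) {
    warning("scored symbols absent from catalog, excluded: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    scored <- scored[!scored$symbol %in% unknown, , drop = FALSE]
  }
  inside_all <- classify_genes(catalog, qtls, overlap)
  inside <- inside_all[scored$symbol]
  idx <- bin_by_score(scored$cgc_score, edges)
  nb <- length(edges) - 1L
  n_in <- tabulate(idx[inside], nbins = nb)
  n_out <- tabulate(idx[!inside], nbins = nb)
  tot_in <- sum(n_in)
  tot_out <- sum(n_out)
  tests <- lapply(seq_len(nb), function(b) {
    if (tot_in > 0 && tot_out > 0) {
      bin_proportion_test(n_in[b], n_out[b], tot_in, tot_out, variant)
    } else {
      list(chi2 = NA_real_, p = NA_real_, testable = FALSE)
    }
  })
  out <- data.frame(bin = bin_labels(edges),
                    lower = edges[-length(edges)],
                    upper = edges[-1],
                    n_inside = n_in,
                    n_outside = n_out,
                    chi2 = vapply(tests, `[[`, numeric(1), "chi2"),
                    p = vapply(tests, `[[`, numeric(1), "p"),
                    testable = vapply(tests, `[[`, logical(1), "testable"),
                    stringsAsFactors = FALSE)
  out <- out[rev(seq_len(nb)), , drop = FALSE]  # highest stratum first
  rownames(out) <- NULL
  total <- tot_in + tot_out
  attr(out, "totals") <- list(
    n_inside = tot_in, n_outside = tot_out,
    inside_pct = if (total > 0) round(100 * tot_in / total) else NA_real_,
    outside_pct = if (total > 0) round(100 * tot_out / total) else NA_real_)
  attr(out, "edges") <- edges
  class(out) <- c("cgc_partition_report", "data.frame")
  out
}

#' @export
print.cgc_partition_report <- function(x, ...) {
  tot <- attr(x, "totals")
  cat("CGC score stratification, genes inside vs outside QTL regions\n\n")
  d <- data.frame(`CGC score` = x$bin, `within QTLs` = x$n_inside,
                  `outside QTLs` = x$n_outside,
                  `P (chi2)` = ifelse(x$testable,
                                      formatC(x$p, digits = 2,
                                              format = "f"), "-"),
                  check.names = FALSE)
  print(d, row.names = FALSE)
  cat(sprintf("\nTotal: %d within (%s%%), %d outside (%s%%)\n",
              tot$n_inside, tot$inside_pct, tot$n_outside, tot$outside_pct))
  invisible(x)
}

#' Write a partition report to TSV
#' @param report Output of [partition_report()].
#' @param path Output path.
#' @export
write_partition_report <- function(report, path) {
  tot <- attr(report, "totals")
  d <- as.data.frame(report)
  d <- rbind(d, data.frame(bin = "Total", lower = NA, upper = NA,
                           n_inside = tot$n_inside,
                           n_outside = tot$n_outside,
                           chi2 = NA, p = NA, testable = NA))
  write_tsv(d, path)
}
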