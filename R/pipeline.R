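#' Assemble a pipeline run configuration
#'
#' @param keywords,catalog,qtls,corpus,links Input file paths (corpus is a
#'   JSON-lines record file; `links` may be `NULL` when the corpus embeds
#'   its hyperlinks).
#' @param outdir Output directory.
#' @param min_score Inclusive CGC-score cut (default 0.1).
#' @param edges Score-bin edges (default [default_score_edges()]).
#' @param match Keyword matching mode, `"token"` or `"substring"`.
#' @param overlap Gene-QTL overlap mode, `"any"` or `"full"`.
#' @param variant Per-bin test variant, `"gof"` or `"2x2"`.
#' @param alpha Significance level for QTL-pair flagging.
#' @param near_miss Near-miss p bound.
#' @param score_threshold CGC threshold for the high-score pair filter.
#' @param seed Integer seed recorded in the run summary.
#' @return List of class `cgc_run_config`.
#' @export
run_config <- function(keywords, catalog, qtls, corpus, links = NULL,
                       outdir = ".", min_score = 0.1,
                       edges = default_score_edges(),
                       match = "token", overlap = "any", variant = "gof",
                       alpha = 0.05, near_miss = 0.06, score_threshold = 50,
                       seed = 1L) {
  cfg <- list(keywords = keywords, catalog = catalog, qtls = qtls,
              corpus = corpus, links = links, outdir = outdir,
              min_score = as.numeric(min_score), edges = as.numeric(edges),
              match = match, overlap = overlap, variant = variant,
              alpha = as.numeric(alpha), near_miss = as.numeric(near_miss),
              score_threshold = as.numeric(score_threshold),
              seed = as.integer(seed))
  stopifnot(cfg$min_score >= 0, cfg$alpha > 0, cfg$score_threshold >= 0)
  structure(cfg, class = "cgc_run_config")
}

check_inputs <- function(config, need) {
  for (field in need) {
    path <- config[[field]]
    if (is.null(path)) {
      stop("missing required input path: ", field, call. = FALSE)
    }
    if (!file.exists(path)) {
      stop("input file for '", field, "' not found: ", path, call. = FALSE)
    }
  }
}

#' Run the genome partition analysis end to end
#'
#' Reads keywords, catalog, QTLs and the record corpus, scores every gene,
#' and writes three artifacts to the output directory: `scores.tsv`,
#' `partition_report.tsv` and `partition_summary.json` (totals, the
#' integer inside/outside percentages, and per-bin chi-square results).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `scored`, `report` and `paths`.
#' @export
run_partition_analysis <- function(config) {
  check_inputs(config, c("keywords", "catalog", "qtls", "corpus"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  keywords <- read_keywords(config$keywords)
  catalog <- read_gene_catalog(config$catalog)
  qtls <- read_qtl_table(config$qtls)
  corpus <- read_corpus(config$corpus)
  cgc_log("scoring ", nrow(corpus$records), " records against ",
          nrow(keywords), " keywords")
  scored <- score_corpus(corpus, keywords, match = config$match)
  report <- partition_report(catalog, qtls, scored,
                             min_score = config$min_score,
                             edges = config$edges,
                             overlap = config$overlap,
                             variant = config$variant)
  tot <- attr(report, "totals")
  paths <- c(scores = file.path(config$outdir, "scores.tsv"),
             report = file.path(config$outdir, "partition_report.tsv"),
             summary = file.path(config$outdir, "partition_summary.json"))
  write_scores(scored, paths["scores"])
  write_partition_report(report, paths["report"])
  jsonlite::write_json(
    list(seed = config$seed, n_scored = nrow(scored),
         n_filtered = tot$n_inside + tot$n_outside,
         totals = tot,
         bins = as.data.frame(report)[, c("bin", "n_inside", "n_outside",
                                          "chi2", "p", "testable")]),
    paths["summary"], auto_unbox = TRUE, digits = NA, na = "null")
  cgc_log("partition: ", tot$n_inside, " genes inside (", tot$inside_pct,
          "%), ", tot$n_outside, " outside (", tot$outside_pct, "%)")
  invisible(list(scored = scored, report = report, paths = paths))
}

#' Run the QTL connectivity analysis end to end
#'
#' Builds the connection graph from record hyperlinks, tests every
#' cross-cross QTL pair, and writes `qtl_pairs.tsv` (all pairs),
#' `qtl_pairs_flagged.tsv` (significant and near-miss pairs), and
#' `gene_pairs_high_score.tsv` (connecting gene pairs of flagged QTL pairs
#' where at least one gene reaches the CGC threshold, with per-gene
#' scores).
#'
#' @param config A [run_config()].  `links` may be `NULL` if the corpus
#'   embeds hyperlinks.
#' @return Invisibly, a list with `graph`, `pairs`, `flagged`,
#'   `high_score_pairs` and `paths`.
#' @export
run_connectivity_analysis <- function(config) {
  check_inputs(config, c("keywords", "catalog", "qtls", "corpus"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  keywords <- read_keywords(config$keywords)
  catalog <- read_gene_catalog(config$catalog)
  qtls <- read_qtl_table(config$qtls)
  corpus <- read_corpus(config$corpus)
  links <- if (!is.null(config$links)) {
    check_inputs(config, "links")
    read_links(config$links)
  } else {
    corpus$links
  }
  graph <- build_connection_graph(links, catalog, qtls,
                                  overlap = config$overlap)
  pairs <- qtl_pair_results(graph, alpha = config$alpha,
                            near_miss = config$near_miss)
  flagged <- pairs[pairs$flag != "", , drop = FALSE]
  scored <- score_corpus(corpus, keywords, match = config$match)
  gp <- do.call(rbind, c(list(
    data.frame(qtl1 = character(), qtl2 = character(), gene1 = character(),
               gene2 = character(), score1 = numeric(), score2 = numeric(),
               stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(flagged)), function(i) {
      g <- connecting_gene_pairs(graph, flagged$qtl1[i], flagged$qtl2[i])
      if (nrow(g) == 0L) return(NULL)
      g <- filter_high_score_pairs(g, scored,
                                   threshold = config$score_threshold)
      if (nrow(g) == 0L) return(NULL)
      cbind(data.frame(qtl1 = flagged$qtl1[i], qtl2 = flagged$qtl2[i],
                       stringsAsFactors = FALSE), g)
    })))
  paths <- c(pairs = file.path(config$outdir, "qtl_pairs.tsv"),
             flagged = file.path(config$outdir, "qtl_pairs_flagged.tsv"),
             high = file.path(config$outdir, "gene_pairs_high_score.tsv"))
  write_tsv(pairs, paths["pairs"])
  write_tsv(flagged, paths["flagged"])
  write_tsv(gp, paths["high"])
  cgc_log("connectivity: ", sum(pairs$flag == "significant"),
          " significant QTL pair(s), ",
          sum(pairs$flag == "near-miss"), " near-miss")
  invisible(list(graph = graph, pairs = pairs, flagged = flagged,
                 high_score_pairs = gp, paths = paths))
}
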