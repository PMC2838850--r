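#' Configuration for the synthetic study generator
#'
#' Defaults emulate the real study's scale: a ~2.5 Gb genome in 20
#' chromosomes, 2403 positioned genes, QTL intervals from two crosses whose
#' union covers about half the genome, and 49 weighted keywords.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bases (equal for all).
#' @param n_genes Number of genes placed uniformly.
#' @param n_qtls_per_cross Integer vector of length 2: QTL counts for the
#'   two crosses (default `c(5, 9)`, the two collagen-induced-arthritis
#'   crosses).
#' @param qtl_coverage_fraction Target fraction of the genome covered by
#'   the QTL union, in `(0, 1]` (default 0.5); realized coverage is brought
#'   within 5 percentage points of this.
#' @param keyword_set_size Number of keywords (default 49).
#' @param keyword_weight_distribution List with `shape1`, `shape2`: keyword
#'   weights are `100 * Beta(shape1, shape2)` draws (default skews low, as
#'   literature relevance indices do).
#' @param baseline_keyword_rate Per-keyword probability of inclusion in a
#'   gene's record text (default 0.03, giving mostly low CGC scores with a
#'   thin high tail).
#' @param inside_enrichment Multiplier on the keyword rate for genes inside
#'   QTLs (1 = null, no positional signal).
#' @param edge_count Total number of undirected cross-cross record links.
#' @param pair_excess Named numeric vector/list mapping `"QTL1|QTL2"` (one
#'   QTL per cross) to a multiplicative edge-rate excess (1 = null; `Inf`
#'   puts all edges there).
#' @param filler_range Integer range of filler tokens per record text.
#' @param seed Integer master seed; per-stage substreams are derived from
#'   it, so each stage is reproducible in isolation.
#' @return A validated list of class `cgc_synth_config`.
#' @export
synth_config <- function(n_chromosomes = 20L,
                         chrom_length = 125e6,
                         n_genes = 2403L,
                         n_qtls_per_cross = c(5L, 9L),
                         qtl_coverage_fraction = 0.5,
                         keyword_set_size = 49L,
                         keyword_weight_distribution = list(shape1 = 0.8,
                                                            shape2 = 3),
                         baseline_keyword_rate = 0.03,
                         inside_enrichment = 1.0,
                         edge_count = 300L,
                         pair_excess = NULL,
                         filler_range = c(30L, 70L),
                         seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              n_qtls_per_cross = as.integer(n_qtls_per_cross),
              qtl_coverage_fraction = qtl_coverage_fraction,
              keyword_set_size = as.integer(keyword_set_size),
              keyword_weight_distribution = keyword_weight_distribution,
              baseline_keyword_rate = baseline_keyword_rate,
              inside_enrichment = inside_enrichment,
              edge_count = as.integer(edge_count),
              pair_excess = pair_excess,
              filler_range = as.integer(filler_range),
              seed = as.integer(seed))
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length >= 1e4,
            cfg$n_genes >= 0L, length(cfg$n_qtls_per_cross) == 2L,
            all(cfg$n_qtls_per_cross >= 0L),
            cfg$qtl_coverage_fraction > 0, cfg$qtl_coverage_fraction <= 1,
            cfg$keyword_set_size >= 1L,
            cfg$baseline_keyword_rate >= 0, cfg$inside_enrichment >= 0,
            cfg$edge_count >= 0L, length(cfg$filler_range) == 2L)
  structure(cfg, class = "cgc_synth_config")
}

cross_names <- c("crossA", "crossB")

## Total bases covered by the union of 1-based inclusive intervals,
## grouped by chromosome.  Plain-vector version used inside the coverage
## calibration loop, where GRanges construction overhead would dominate.
union_length <- function(chrom, start, stop) {
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; stop <- stop[o]
  total <- 0
  for (idx in split(seq_along(chrom), chrom)) {
    s <- start[idx]; e <- stop[idx]
    ce <- cummax(e)
    new_grp <- c(TRUE, s[-1] > ce[-length(ce)] + 1)
    grp <- cumsum(new_grp)
    total <- total +
      sum(tapply(ce, grp, max) - s[new_grp] + 1)
  }
  total
}

#' Generate a synthetic gene catalog and two-cross QTL set
#'
#' Genes are placed uniformly over the genome.  QTL intervals are placed on
#' chromosomes round-robin and their lengths rescaled iteratively until the
#' realized union coverage is within 5 percentage points of the target; one
#' cross-B QTL is deliberately placed overlapping a cross-A QTL, mirroring
#' the partially overlapping loci of real QTL maps.
#'
#' @param config A [synth_config()].
#' @return List with `catalog` (see [read_gene_catalog()]) and `qtls` (see
#'   [read_qtl_table()]).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "cgc_synth_config"))
  set.seed(sub_seed(config$seed, 1L))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  glen <- pmax(1000, round(stats::rlnorm(config$n_genes, log(3e4), 1)))
  glen <- pmin(glen, config$chrom_length - 1)
  gchrom <- sample(config$n_chromosomes, config$n_genes, replace = TRUE)
  gstart <- floor(runif(config$n_genes, 1, config$chrom_length - glen + 1))
  catalog <- data.frame(symbol = sprintf("G%05d", seq_len(config$n_genes)),
                        chrom = chroms[gchrom],
                        start = as.integer(gstart),
                        stop = as.integer(gstart + glen - 1),
                        stringsAsFactors = FALSE)

  k <- config$n_qtls_per_cross
  ktot <- sum(k)
  if (ktot == 0L) {
    qtls <- data.frame(qtl_symbol = character(), cross_id = character(),
                       chrom = character(), start = integer(),
                       stop = integer(), lod = numeric(), p = numeric(),
                       stringsAsFactors = FALSE)
    return(list(catalog = catalog, qtls = qtls))
  }
  genome <- config$n_chromosomes * config$chrom_length
  target <- config$qtl_coverage_fraction * genome
  if (ktot * config$chrom_length < target * 0.95) {
    stop("infeasible QTL coverage: ", ktot, " QTLs of at most ",
         config$chrom_length, " bases cannot cover ",
         round(100 * config$qtl_coverage_fraction), "% of the genome",
         call. = FALSE)
  }
  qchrom <- rep_len(sample(config$n_chromosomes), ktot)
  frac_start <- runif(ktot)
  raw <- stats::rgamma(ktot, shape = 2, rate = 1)
  # deliberate overlap: first cross-B QTL shares the first cross-A QTL's
  # chromosome and starts inside it; skipped near full coverage, where
  # every chromosome needs its QTL and overlap happens anyway
  if (all(k >= 1L) && config$qtl_coverage_fraction <= 0.9) {
    qchrom[k[1] + 1L] <- qchrom[1L]
    frac_start[k[1] + 1L] <- frac_start[1L] + 1e-4
  }
  # exact full coverage: tile whole chromosomes (needs one QTL per
  # chromosome, guaranteed by the round-robin assignment when feasible)
  if (config$qtl_coverage_fraction == 1) {
    if (!all(seq_len(config$n_chromosomes) %in% qchrom)) {
      stop("infeasible QTL coverage: fewer QTLs than chromosomes at ",
           "full coverage", call. = FALSE)
    }
    frac_start[] <- 0
    raw[] <- 1
  }
  len <- raw / sum(raw) * target
  realized <- 0
  place <- function(len) {
    start <- pmax(1, pmin(floor(frac_start * (config$chrom_length - len) + 1),
                          config$chrom_length))
    stop_ <- pmin(config$chrom_length, pmax(floor(start + len - 1), start))
    list(start = start, stop = stop_)
  }
  for (iter in 1:40) {
    pl <- place(len)
    start <- pl$start
    stop_ <- pl$stop
    realized <- union_length(qchrom, start, stop_)
    if (abs(realized - target) / genome <= 0.04) break
    len <- pmin(len * target / realized, config$chrom_length)
  }
  if (abs(realized - target) / genome > 0.05) {
    stop("could not reach target QTL coverage (realized ",
         round(100 * realized / genome), "%, target ",
         round(100 * config$qtl_coverage_fraction), "%)", call. = FALSE)
  }
  pl <- place(len)
  start <- pl$start
  stop_ <- pl$stop
  cross <- rep(cross_names, times = k)
  qsym <- c(sprintf("QA%02d", seq_len(k[1])), sprintf("QB%02d", seq_len(k[2])))
  qtls <- data.frame(qtl_symbol = qsym, cross_id = cross,
                     chrom = chroms[qchrom],
                     start = as.integer(start), stop = as.integer(stop_),
                     lod = round(runif(ktot, 2.5, 12), 1),
                     p = signif(10^runif(ktot, -6, -2), 2),
                     stringsAsFactors = FALSE)
  list(catalog = catalog, qtls = qtls)
}

synth_wordlist <- function() {
  path <- system.file("extdata", "wordlist.txt", package = "cgcqtl")
  w <- readLines(path, warn = FALSE)
  w <- w[nzchar(w) & !startsWith(w, "#")]
  unique(tolower(w))
}

#' Generate a synthetic keyword set and record corpus
#'
#' Keywords are sampled from the shipped word list (about one in five as
#' two-word phrases), with weights derived from fabricated literature
#' co-occurrence counts so that the keyword file and the raw-count file are
#' exactly consistent.  Each gene's record text is a shuffled bag of filler
#' tokens plus each keyword independently included with probability
#' `baseline_keyword_rate`, multiplied by `inside_enrichment` (capped at 1)
#' for genes inside the QTL union.
#'
#' @param config A [synth_config()].
#' @param genome Output of [generate_genome()].
#' @return List with `keywords` (keyword set), `cooccurrence` (raw counts),
#'   and `corpus` (a `cgc_corpus`, linkless).
#' @export
generate_corpus <- function(config, genome) {
  stopifnot(inherits(config, "cgc_synth_config"))
  set.seed(sub_seed(config$seed, 2L))
  words <- synth_wordlist()
  nk <- config$keyword_set_size
  if (nk > floor(length(words) / 3)) {
    stop("keyword_set_size too large for the shipped word list",
         call. = FALSE)
  }
  n_bigram <- floor(nk / 5)
  kw_words <- sample(words, nk + n_bigram)
  terms <- c(if (n_bigram > 0)
               paste(kw_words[seq_len(n_bigram)],
                     kw_words[nk + seq_len(n_bigram)]),
             kw_words[seq.int(n_bigram + 1L, nk)])
  fillers <- setdiff(words, kw_words)

  wd <- config$keyword_weight_distribution
  w_target <- pmin(pmax(100 * stats::rbeta(nk, wd$shape1, wd$shape2), 0.1),
                   100)
  n_keyword <- sample(200:5000, nk, replace = TRUE)
  n_joint <- pmin(round(w_target / 100 * n_keyword), n_keyword)
  cooc <- data.frame(term = terms, n_keyword = n_keyword, n_joint = n_joint,
                     stringsAsFactors = FALSE)
  keywords <- keywords_from_cooccurrence(cooc)

  n <- nrow(genome$catalog)
  inside <- classify_genes(genome$catalog, genome$qtls)
  rate <- pmin(config$baseline_keyword_rate *
                 ifelse(inside, config$inside_enrichment, 1), 1)
  inc <- matrix(runif(n * nk) < rate, nrow = n)  # recycles rate by gene
  nfill <- sample(seq(config$filler_range[1], config$filler_range[2]),
                  n, replace = TRUE)
  kw_hit <- which(inc, arr.ind = TRUE)
  toks <- c(sample(fillers, sum(nfill), replace = TRUE),
            keywords$term[kw_hit[, 2]])
  gidx <- c(rep(seq_len(n), nfill), kw_hit[, 1])
  perm <- sample(length(toks))  # shuffles token order within each record
  texts <- vapply(split(toks[perm], factor(gidx[perm], levels = seq_len(n))),
                  paste, character(1), collapse = " ")
  list(keywords = keywords, cooccurrence = cooc,
       corpus = gene_corpus(genome$catalog$symbol, texts))
}

#' Generate a synthetic cross-cross link table
#'
#' Samples `edge_count` distinct undirected links between genes inside
#' cross-A QTLs and genes inside cross-B QTLs, with sampling weight 1
#' multiplied by any `pair_excess` entry covering the gene pair's QTL pair
#' (a gene in several QTLs takes the largest applicable multiplier).
#'
#' @param config A [synth_config()].
#' @param genome Output of [generate_genome()].
#' @return Data frame `from`, `to` of undirected links.
#' @export
generate_links <- function(config, genome) {
  stopifnot(inherits(config, "cgc_synth_config"))
  set.seed(sub_seed(config$seed, 3L))
  if (config$edge_count == 0L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gene_qtl_membership(genome$catalog, genome$qtls)
  gA <- unique(m$symbol[m$cross_id == cross_names[1]])
  gB <- unique(m$symbol[m$cross_id == cross_names[2]])
  if (length(gA) == 0L || length(gB) == 0L) {
    stop("no genes inside one of the crosses' QTLs; cannot place links",
         call. = FALSE)
  }
  u <- expand.grid(a = gA, b = gB, stringsAsFactors = FALSE)
  u <- u[u$a != u$b, , drop = FALSE]
  key <- paste(pmin(u$a, u$b), pmax(u$a, u$b))
  u <- u[!duplicated(key), , drop = FALSE]
  if (config$edge_count > nrow(u)) {
    stop("edge_count (", config$edge_count, ") exceeds the ", nrow(u),
         " possible cross-cross gene pairs", call. = FALSE)
  }
  w <- rep(1, nrow(u))
  pe <- config$pair_excess
  if (length(pe)) {
    mA <- m[m$cross_id == cross_names[1], ]
    mB <- m[m$cross_id == cross_names[2], ]
    for (nm in names(pe)) {
      qq <- strsplit(nm, "|", fixed = TRUE)[[1]]
      hit <- (u$a %in% mA$symbol[mA$qtl_symbol == qq[1]]) &
        (u$b %in% mB$symbol[mB$qtl_symbol == qq[2]])
      w[hit] <- pmax(w[hit], as.numeric(pe[[nm]]))
    }
  }
  if (any(is.infinite(w))) {
    pool <- which(is.infinite(w))
    if (config$edge_count > length(pool)) {
      stop("edge_count exceeds the pairs eligible under an infinite excess",
           call. = FALSE)
    }
    pick <- sample(pool, config$edge_count)
  } else {
    pick <- sample.int(nrow(u), config$edge_count, prob = w)
  }
  data.frame(from = u$a[pick], to = u$b[pick], stringsAsFactors = FALSE)
}

#' Choose a designated QTL pair for planted-excess experiments
#'
#' Planted-excess power experiments need an identifiable target: when QTLs
#' overlap, genes belong to several QTLs and a planted excess between one
#' pair is genuinely shared by every overlapping pair, so no single pair
#' need carry the smallest p.  This helper picks, deterministically, the
#' cross-A/cross-B QTL pair whose member genes belong to no other QTL
#' (preferring the largest such pair by gene-count product, for power);
#' if no fully exclusive pair exists, the pair with the fewest shared
#' genes wins.
#'
#' @param catalog Gene catalog.
#' @param qtls Two-cross QTL table.
#' @return Named list with `qtl1`, `qtl2`, and `key` (`"qtl1|qtl2"`, the
#'   format [synth_config()]'s `pair_excess` expects).
#' @export
designate_clean_pair <- function(catalog, qtls) {
  m <- gene_qtl_membership(catalog, qtls)
  crosses <- sort(unique(qtls$cross_id))
  stopifnot(length(crosses) == 2L)
  n_memb <- table(m$symbol)
  shared <- names(n_memb)[n_memb > 1L]
  per_qtl <- split(m$symbol, m$qtl_symbol)
  stats_for <- function(cr) {
    syms <- unique(qtls$qtl_symbol[qtls$cross_id == cr])
    data.frame(qtl = syms,
               n = lengths(per_qtl[syms]),
               n_shared = vapply(per_qtl[syms],
                                 function(g) sum(g %in% shared), 0L),
               stringsAsFactors = FALSE)
  }
  sA <- stats_for(crosses[1])
  sB <- stats_for(crosses[2])
  gr <- expand.grid(a = seq_len(nrow(sA)), b = seq_len(nrow(sB)))
  gr <- gr[sA$qtl[gr$a] != sB$qtl[gr$b], , drop = FALSE]
  shared_tot <- sA$n_shared[gr$a] + sB$n_shared[gr$b]
  size <- as.numeric(sA$n[gr$a]) * sB$n[gr$b]
  best <- gr[order(shared_tot, -size, sA$qtl[gr$a], sB$qtl[gr$b])[1], ]
  list(qtl1 = sA$qtl[best$a], qtl2 = sB$qtl[best$b],
       key = paste(sA$qtl[best$a], sB$qtl[best$b], sep = "|"))
}

#' Generate a full synthetic study, optionally writing it to disk
#'
#' Runs [generate_genome()], [generate_corpus()] and [generate_links()]
#' under the config's seed and, if `dir` is given, writes every file in the
#' exact formats the pipeline readers consume, plus a `manifest.json`
#' recording the configuration.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed), or `NULL` for an
#'   in-memory study only.
#' @return Invisibly, a list with `catalog`, `qtls`, `keywords`,
#'   `cooccurrence`, `corpus` (with links embedded), `links`, and `paths`
#'   (named file paths when `dir` was given).
#' @export
simulate_study <- function(config, dir = NULL) {
  genome <- generate_genome(config)
  corp <- generate_corpus(config, genome)
  links <- generate_links(config, genome)
  corpus <- gene_corpus(corp$corpus$records$symbol,
                        corp$corpus$records$text, links)
  out <- list(catalog = genome$catalog, qtls = genome$qtls,
              keywords = corp$keywords, cooccurrence = corp$cooccurrence,
              corpus = corpus, links = links, paths = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(catalog = file.path(dir, "catalog.tsv"),
               qtls = file.path(dir, "qtls.tsv"),
               keywords = file.path(dir, "keywords.tsv"),
               cooccurrence = file.path(dir, "cooccurrence.tsv"),
               corpus = file.path(dir, "corpus.jsonl"),
               links = file.path(dir, "links.tsv"),
               manifest = file.path(dir, "manifest.json"))
    write_tsv(genome$catalog, paths["catalog"])
    write_qtl_table(genome$qtls, paths["qtls"])
    write_keywords(corp$keywords, paths["keywords"])
    write_tsv(corp$cooccurrence, paths["cooccurrence"])
    write_corpus(corpus, paths["corpus"])
    write_tsv(links, paths["links"])
    manifest <- unclass(config)
    manifest$pair_excess <- as.list(manifest$pair_excess)
    jsonlite::write_json(list(tool = "cgcqtl",
                              version = as.character(
                                utils::packageVersion("cgcqtl")),
                              config = manifest),
                         paths["manifest"], auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  invisible(out)
}
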