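# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive: per-keyword sliding-window token scans and per-pair
# interval checks, never sharing code with the implementation they check.

oracle_tokens <- function(x) {
  t <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  t[nzchar(t)]
}

# naive score: for each keyword, slide its token sequence over the record's
# tokens; count the keyword's weight once if any position matches
oracle_score <- function(text, keywords) {
  toks <- oracle_tokens(text)
  total <- 0
  matched <- character()
  for (i in seq_len(nrow(keywords))) {
    kt <- oracle_tokens(keywords$term[i])
    hit <- FALSE
    if (length(kt) >= 1 && length(toks) >= length(kt)) {
      for (s in seq_len(length(toks) - length(kt) + 1)) {
        if (all(toks[s:(s + length(kt) - 1)] == kt)) {
          hit <- TRUE
          break
        }
      }
    }
    if (hit) {
      total <- total + keywords$weight[i]
      matched <- c(matched, keywords$term[i])
    }
  }
  list(score = total, matched_terms = matched)
}

# naive inside/outside: check every (gene, QTL) pair
oracle_inside <- function(catalog, qtls) {
  vapply(seq_len(nrow(catalog)), function(i) {
    any(qtls$chrom == catalog$chrom[i] &
          qtls$start <= catalog$stop[i] &
          catalog$start[i] <= qtls$stop)
  }, logical(1))
}

# step-by-step re-evaluation of the Yates-corrected statistic
oracle_yates <- function(a, b, c, d) {
  N <- a + b + c + d
  dev <- abs(a * d - b * c)
  corr <- dev - N / 2
  if (corr < 0) corr <- 0
  chi2 <- N * corr * corr / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# naive count of distinct connecting gene pairs for one QTL pair
oracle_count_pairs <- function(edges, members1, members2) {
  n <- 0
  seen <- character()
  for (i in seq_len(nrow(edges))) {
    g1 <- edges$g1[i]; g2 <- edges$g2[i]
    ok <- (g1 %in% members1 && g2 %in% members2) ||
      (g2 %in% members1 && g1 %in% members2)
    key <- paste(min(g1, g2), max(g1, g2))
    if (ok && !key %in% seen) {
      n <- n + 1
      seen <- c(seen, key)
    }
  }
  n
}

# published reference stratification (bundled fixture)
reference_bin_counts <- function() {
  path <- system.file("extdata", "reference_bin_counts.tsv", package = "cgcqtl")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# fixture builders -----------------------------------------------------

make_catalog <- function(symbol, chrom, start, stop) {
  data.frame(symbol = symbol, chrom = chrom, start = as.integer(start),
             stop = as.integer(stop), stringsAsFactors = FALSE)
}

make_qtls <- function(qtl_symbol, cross_id, chrom, start, stop) {
  data.frame(qtl_symbol = qtl_symbol, cross_id = cross_id, chrom = chrom,
             start = as.integer(start), stop = as.integer(stop),
             lod = rep(NA_real_, length(qtl_symbol)),
             p = rep(NA_real_, length(qtl_symbol)),
             stringsAsFactors = FALSE)
}

# a two-cross toy genome with disjoint QTLs and genes placed inside them:
# nA, nB give genes per QTL for each cross
make_disjoint_genome <- function(nA, nB, n_outside = 0) {
  kA <- length(nA); kB <- length(nB)
  qtls <- make_qtls(
    c(sprintf("QA%02d", seq_len(kA)), sprintf("QB%02d", seq_len(kB))),
    rep(c("crossA", "crossB"), c(kA, kB)),
    sprintf("chr%d", seq_len(kA + kB)),
    rep(1L, kA + kB), rep(1000L, kA + kB))
  counts <- c(nA, nB)
  sym <- sprintf("G%03d", seq_len(sum(counts) + n_outside))
  chrom <- c(rep(qtls$chrom, counts), rep("chrZ", n_outside))
  start <- unlist(lapply(counts, function(n) seq(10, by = 20,
                                                 length.out = n)))
  if (n_outside > 0) start <- c(start, seq(10, by = 20,
                                           length.out = n_outside))
  catalog <- make_catalog(sym, chrom, start, start + 5L)
  list(catalog = catalog, qtls = qtls)
}

random_keywords <- function(n, allow_bigrams = TRUE) {
  pool <- c("alpha", "beta", "gamma", "delta", "joint", "bone", "swelling",
            "immune", "antigen", "synovial", "erosion", "cytokine",
            "autoimmune", "cartilage", "inflammation", "arthritis")
  stopifnot(n <= length(pool))
  terms <- sample(pool, n)
  if (allow_bigrams && n >= 2) {
    terms[1] <- paste(terms[1], "response")
  }
  keyword_set(terms, round(runif(n, 0, 100), 1))
}

random_text <- function(keywords, n_tokens = 20, p_kw = 0.3) {
  fillers <- c("the", "cell", "was", "shown", "protein", "binding",
               "mouse", "pathway", "level", "clinical")
  toks <- sample(fillers, n_tokens, replace = TRUE)
  for (t in keywords$term) {
    if (runif(1) < p_kw) toks <- append(toks, t, after = sample(length(toks), 1))
  }
  paste(toks, collapse = " ")
}
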