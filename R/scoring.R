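#' CGC score of a single record text
#'
#' The Candidate Gene Capture (CGC) score of a gene is the sum of the
#' weights of all distinct keywords found in its descriptive record text.
#' Each keyword contributes its weight at most once no matter how often it
#' occurs.  Matching is case-insensitive; in the default `"token"` mode a
#' keyword matches only as a whole token (multi-word keywords as a
#' contiguous token sequence), so keyword "arthritis" does not match the
#' token "osteoarthritis".  `"substring"` mode matches anywhere in the
#' lower-cased text.
#'
#' @param text A single record text (possibly empty).
#' @param keywords Keyword set from [keyword_set()] or [read_keywords()].
#' @param match `"token"` (default) or `"substring"`.
#' @return List with `score` (numeric) and `matched_terms` (character).
#' @export
cgc_score <- function(text, keywords, match = c("token", "substring")) {
  stopifnot(length(text) == 1L)
  m <- score_corpus_text(text, keywords, match)
  list(score = m$cgc_score[1], matched_terms = m$matched_terms[[1]])
}

## Vectorized scorer over texts; shared by cgc_score and score_corpus.
score_corpus_text <- function(texts, keywords, match = c("token", "substring")) {
  match <- match.arg(match)
  n <- length(texts)
  if (nrow(keywords) == 0L) {
    return(data.frame(cgc_score = numeric(n),
                      matched_terms = I(replicate(n, character(), FALSE)),
                      stringsAsFactors = FALSE))
  }
  if (match == "token") {
    hay <- token_key(texts)
    pats <- token_key(keywords$term)
  } else {
    hay <- tolower(texts)
    pats <- tolower(keywords$term)
  }
  hit <- matrix(FALSE, nrow = n, ncol = nrow(keywords))
  for (j in seq_len(nrow(keywords))) {
    hit[, j] <- grepl(pats[j], hay, fixed = TRUE)
  }
  score <- as.numeric(hit %*% keywords$weight)
  matched <- lapply(seq_len(n), function(i) keywords$term[hit[i, ]])
  data.frame(cgc_score = score, matched_terms = I(matched),
             stringsAsFactors = FALSE)
}

#' Score every gene record in a corpus
#'
#' @param corpus A `cgc_corpus` (see [gene_corpus()]).
#' @param keywords Keyword set.
#' @param match Matching mode, see [cgc_score()].
#' @return Data frame with columns `symbol`, `cgc_score` and list-column
#'   `matched_terms`, one row per record in corpus order.
#' @export
score_corpus <- function(corpus, keywords, match = c("token", "substring")) {
  sc <- score_corpus_text(corpus$records$text, keywords, match)
  cbind(data.frame(symbol = corpus$records$symbol,
                   stringsAsFactors = FALSE), sc)
}

#' Rank scored genes
#'
#' Orders genes by decreasing CGC score; ties are broken by ascending gene
#' symbol so output is deterministic.
#'
#' @param scored Data frame with columns `symbol`, `cgc_score`.
#' @return The same data frame, reordered.
#' @export
rank_genes <- function(scored) {
  stopifnot(nrow(scored) > 0L)
  scored[order(-scored$cgc_score, scored$symbol), , drop = FALSE]
}

#' Filter scored genes at a minimum CGC score
#'
#' @param scored Data frame with column `cgc_score`.
#' @param min_score Inclusive lower bound (default 0.1, the cut used for
#'   genome-wide ranking).
#' @return Rows with `cgc_score >= min_score`.
#' @export
filter_min_score <- function(scored, min_score = 0.1) {
  stopifnot(min_score >= 0)
  scored[scored$cgc_score >= min_score, , drop = FALSE]
}

#' Write scored genes to TSV
#'
#' Columns `symbol`, `cgc_score`, `matched_terms` (semicolon-joined).
#'
#' @param scored Output of [score_corpus()].
#' @param path Output path.
#' @export
write_scores <- function(scored, path) {
  out <- data.frame(symbol = scored$symbol,
                    cgc_score = scored$cgc_score,
                    matched_terms = vapply(scored$matched_terms,
                                           paste, character(1),
                                           collapse = ";"),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read scored genes from TSV
#' @param path Path written by [write_scores()].
#' @return Data frame with `symbol`, `cgc_score`, list-column `matched_terms`.
#' @export
read_scores <- function(path) {
  d <- read_tsv(path)
  terms <- strsplit(as.character(d$matched_terms %||% ""), ";", fixed = TRUE)
  terms <- lapply(terms, function(t) t[nzchar(t)])
  data.frame(symbol = as.character(d$symbol),
             cgc_score = as.numeric(d$cgc_score),
             matched_terms = I(terms), stringsAsFactors = FALSE)
}
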