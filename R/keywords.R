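#' Relevance index of a keyword from literature co-occurrence counts
#'
#' A keyword's weight is defined as the percentage of abstracts mentioning
#' the keyword that also mention a fixed reference term (by default
#' "arthritis"): `100 * n_joint / n_keyword`.
#'
#' @param n_joint Number of abstracts containing both the keyword and the
#'   reference term (non-negative integer, vectorized).
#' @param n_keyword Number of abstracts containing the keyword alone
#'   (positive integer, vectorized).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' relevance_index(37, 500)  # 7.4
#' @export
relevance_index <- function(n_joint, n_keyword) {
  if (any(n_keyword == 0)) {
    stop("relevance index undefined: n_keyword is 0", call. = FALSE)
  }
  if (any(n_joint < 0) || any(n_keyword < 0)) {
    stop("co-occurrence counts must be non-negative", call. = FALSE)
  }
  if (any(n_joint > n_keyword)) {
    stop("n_joint exceeds n_keyword: joint abstracts are a subset of ",
         "keyword-containing abstracts", call. = FALSE)
  }
  100 * n_joint / n_keyword
}

#' Construct and validate a keyword set
#'
#' A keyword set is a data frame with columns `term` (lower-cased,
#' case-insensitively unique) and `weight` (a percentage in `[0, 100]`).
#'
#' @param term Character vector of keyword terms (may be multi-word).
#' @param weight Numeric vector of percentage weights.
#' @return Validated data frame with columns `term`, `weight`.
#' @export
keyword_set <- function(term, weight) {
  term <- tolower(trimws(as.character(term)))
  weight <- as.numeric(weight)
  if (length(term) != length(weight)) {
    stop("term and weight lengths differ", call. = FALSE)
  }
  if (any(!nzchar(term))) {
    stop("empty keyword term", call. = FALSE)
  }
  dup <- unique(term[duplicated(term)])
  if (length(dup)) {
    stop("duplicate keyword terms (case-insensitive): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(weight) | weight < 0 | weight > 100
  if (any(bad)) {
    stop("keyword weights outside [0, 100]: ",
         paste(term[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(term = term, weight = weight, stringsAsFactors = FALSE)
}

#' Read a keyword-weight table
#'
#' Expects a two-column TSV `term<TAB>weight` with a header row; `#` lines
#' are comments.  Terms are lower-cased and must be unique.
#'
#' @param path Path to the TSV file.
#' @return Keyword set as produced by [keyword_set()].
#' @export
read_keywords <- function(path) {
  d <- read_tsv(path)
  if (nrow(d) == 0L) {
    warning("empty keyword file: ", path, call. = FALSE)
    return(data.frame(term = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(d) < 2L) {
    stop("keyword file needs two columns (term, weight): ", path,
         call. = FALSE)
  }
  keyword_set(d[[1]], d[[2]])
}

#' Write a keyword set to TSV
#' @param keywords Keyword set data frame.
#' @param path Output path.
#' @export
write_keywords <- function(keywords, path) {
  write_tsv(keywords[, c("term", "weight")], path)
}

#' Read raw co-occurrence counts
#'
#' Three-column TSV `term<TAB>n_keyword<TAB>n_joint` giving, per keyword,
#' the number of abstracts containing the keyword alone and together with
#' the reference term.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `term`, `n_keyword`, `n_joint`.
#' @export
read_cooccurrence <- function(path) {
  d <- read_tsv(path)
  if (ncol(d) < 3L) {
    stop("co-occurrence file needs three columns ",
         "(term, n_keyword, n_joint): ", path, call. = FALSE)
  }
  out <- data.frame(term = tolower(as.character(d[[1]])),
                    n_keyword = as.integer(d[[2]]),
                    n_joint = as.integer(d[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$n_joint > out$n_keyword) || any(out$n_joint < 0)) {
    stop("invalid co-occurrence counts: need 0 <= n_joint <= n_keyword",
         call. = FALSE)
  }
  out
}

#' Derive keyword weights from co-occurrence counts
#'
#' @param counts Data frame as returned by [read_cooccurrence()].
#' @return Keyword set with weights equal to the relevance index.
#' @export
keywords_from_cooccurrence <- function(counts) {
  keyword_set(counts$term, relevance_index(counts$n_joint, counts$n_keyword))
}
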