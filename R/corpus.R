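#' Construct a gene record corpus
#'
#' A corpus holds, per gene, a free-text descriptive record (emulating an
#' OMIM entry) and the outgoing hyperlinks to other gene symbols.
#'
#' @param symbol Character vector of unique gene symbols.
#' @param text Character vector of record texts (may be empty strings).
#' @param links Data frame with columns `from`, `to` (gene symbols), or
#'   `NULL` for a linkless corpus.
#' @return A list of class `cgc_corpus` with elements `records` (data frame
#'   `symbol`, `text`) and `links` (data frame `from`, `to`, directed as
#'   stored; deduplicated, no self-links).
#' @export
gene_corpus <- function(symbol, text = "", links = NULL) {
  symbol <- as.character(symbol)
  if (anyDuplicated(symbol)) {
    stop("duplicate gene symbols in corpus: ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "),
         call. = FALSE)
  }
  text <- rep_len(as.character(text), length(symbol))
  if (is.null(links)) {
    links <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  links <- data.frame(from = as.character(links$from),
                      to = as.character(links$to),
                      stringsAsFactors = FALSE)
  links <- links[links$from != links$to, , drop = FALSE]
  links <- unique(links)
  structure(list(records = data.frame(symbol = symbol, text = text,
                                      stringsAsFactors = FALSE),
                 links = links),
            class = "cgc_corpus")
}

#' @export
print.cgc_corpus <- function(x, ...) {
  cat("cgc_corpus:", nrow(x$records), "gene records,",
      nrow(x$links), "links\n")
  invisible(x)
}

#' Read a record corpus from JSON-lines
#'
#' One JSON object per line: `{"symbol": ..., "text": ..., "links": [...]}`.
#' The per-record `links` arrays are flattened into the corpus link table.
#'
#' @param path Path to a `.jsonl` file.
#' @return A `cgc_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  symbol <- vapply(recs, function(r) as.character(r$symbol), character(1))
  text <- vapply(recs, function(r) as.character(r$text %||% ""), character(1))
  link_list <- lapply(recs, function(r) {
    to <- r$links
    if (is.null(to) || length(to) == 0L) character() else as.character(to)
  })
  from <- rep(symbol, lengths(link_list))
  links <- data.frame(from = from, to = unlist(link_list, use.names = FALSE),
                      stringsAsFactors = FALSE)
  gene_corpus(symbol, text, links)
}

#' Write a record corpus to JSON-lines
#' @param corpus A `cgc_corpus`.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  by_gene <- split(corpus$links$to, factor(corpus$links$from,
                                           levels = corpus$records$symbol))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$records))) {
    obj <- list(symbol = corpus$records$symbol[i],
                text = corpus$records$text[i],
                links = as.character(by_gene[[i]]))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a record corpus from a directory of per-gene text files
#'
#' Each `<symbol>.txt` file in `dir` becomes one gene record whose text is
#' the file's contents; hyperlinks, if any, come from a separate two-column
#' TSV (`from<TAB>to`, see [read_links()]).
#'
#' @param dir Directory containing `<symbol>.txt` files.
#' @param links_path Optional path to a links TSV.
#' @return A `cgc_corpus`.
#' @export
read_corpus_dir <- function(dir, links_path = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) {
    warning("no .txt record files in ", dir, call. = FALSE)
  }
  symbol <- sub("\\.txt$", "", basename(files))
  text <- vapply(files, function(f)
    paste(readLines(f, warn = FALSE), collapse = "\n"), character(1))
  links <- if (!is.null(links_path)) read_links(links_path) else NULL
  gene_corpus(symbol, text, links)
}

#' Read a link table
#'
#' Two-column TSV `from<TAB>to` of directed record hyperlinks.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `from`, `to`.
#' @export
read_links <- function(path) {
  d <- read_tsv(path)
  if (ncol(d) < 2L) {
    stop("link file needs two columns (from, to): ", path, call. = FALSE)
  }
  data.frame(from = as.character(d[[1]]), to = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}
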