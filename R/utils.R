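#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq rbinom runif rbeta setNames p.adjust ks.test
#' @importFrom utils read.delim write.table packageVersion
NULL

## Tokenization used for whole-token keyword matching: lower-case, split on
## any non-alphanumeric run.  Gene-record text and keywords go through the
## same normalization so matching is case- and punctuation-insensitive.
tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

## " a b c " representation of a token sequence; contiguous sub-sequence
## search then reduces to a fixed substring match on " kw tokens ".
token_key <- function(x) {
  toks <- tokenize(x)
  vapply(toks, function(t) {
    if (length(t) == 0L) "" else paste0(" ", paste(t, collapse = " "), " ")
  }, character(1))
}

cgc_log <- function(...) {
  message("[cgcqtl] ", ...)
}

## Plain TSV helpers.  All pipeline files are small tab-separated text with
## a header row and optional '#' comment lines.
read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Bounded sub-seeds derived from one user seed so the simulation stages can
## be regenerated independently.  Kept well below 2^31.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 20000000L) * 97L + as.integer(k)
}
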