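# Word embedding table and lookup.
#
# Lookup is lowercase-first with original-case fallback; tokens absent from
# the vocabulary map to a single learned <unk> row.

UNK_TOKEN <- "<unk>"

#' Create a randomly initialized embedding table
#'
#' @param tokens character vector of vocabulary tokens (an `<unk>` row is
#'   always added).
#' @param d_w embedding dimension (default 300).
#' @return list with `vocab` (token -> row map) and `E` (|vocab| x d_w).
#' @export
embedding_table <- function(tokens, d_w = 300L) {
  tokens <- unique(c(UNK_TOKEN, tokens))
  E <- init_matrix(length(tokens), d_w, fan_in = d_w)
  list(vocab = stats::setNames(seq_along(tokens), tokens), E = E)
}

#' Load pretrained word vectors (word2vec text dialect)
#'
#' Whitespace-separated `token v1 ... v_d` lines; an optional `count dim`
#' header line is skipped; `.gz` files are accepted.
#'
#' @param path path to the vector file.
#' @param d_w expected dimension; checked against the file.
#' @return list with `vocab` and `E` as in [embedding_table()].
#' @export
load_word_embeddings <- function(path, d_w = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  parts <- parts[lengths(parts) > 0L]
  if (length(parts) > 0L && length(parts[[1]]) == 2L &&
      !is.na(suppressWarnings(as.numeric(parts[[1]][2])))) {
    parts <- parts[-1]  # "count dim" header
  }
  if (length(parts) == 0L) stop("empty embedding file: ", path)
  dim_file <- length(parts[[1]]) - 1L
  if (!is.null(d_w) && dim_file != d_w) {
    stop(sprintf("embedding file has dimension %d, expected %d", dim_file, d_w))
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  E <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim_file)))
  if (!UNK_TOKEN %in% tokens) {
    tokens <- c(UNK_TOKEN, tokens)
    E <- rbind(colMeans(E), E)
  }
  list(vocab = stats::setNames(seq_along(tokens), tokens), E = E)
}

#' Map tokens to embedding rows
#'
#' @param tokens character vector.
#' @param vocab named integer vector (token -> row).
#' @return integer vector of rows; unknown tokens map to the `<unk>` row.
#' @export
token_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tolower(tokens)])
  miss <- is.na(ids)
  if (any(miss)) ids[miss] <- unname(vocab[tokens[miss]])
  ids[is.na(ids)] <- unname(vocab[[UNK_TOKEN]])
  as.integer(ids)
}
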