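# Sentence segmentation, tokenization and mention-token alignment.
#
# Offsets follow the PubTator convention: 0-based, half-open, counted over
# title + separator + abstract (separator configurable, default "\n").
# Internally, token and sentence spans are stored 1-based inclusive, the
# natural indexing for substr().

# Tokenizer: maximal runs of word characters (letters, digits, ', _, -) or a
# single non-space punctuation character.  Periods are therefore standalone
# tokens, which keeps sentence-final punctuation out of word embeddings.
.token_regex <- "[A-Za-z0-9'_-]+|[^A-Za-z0-9'_[:space:]-]"

tokenize_with_offsets <- function(text, base = 0L) {
  m <- gregexpr(.token_regex, text)[[1]]
  if (m[1] == -1L) {
    return(list(tokens = character(0),
                spans = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("start", "end")))))
  }
  starts <- as.integer(m) + base
  ends <- starts + attr(m, "match.length") - 1L
  list(tokens = regmatches(text, gregexpr(.token_regex, text))[[1]],
       spans = cbind(start = starts, end = ends))
}

# Candidate sentence boundaries in `text` (returned as 1-based index of the
# first character of the following sentence): after a run of .!? plus
# whitespace.  Boundaries that would split a mention are suppressed so that
# every mention lives in exactly one sentence.
propose_boundaries <- function(text, base = 0L) {
  m <- gregexpr("[.!?]+[[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) + attr(m, "match.length") + base
}

repair_boundaries <- function(boundaries, mentions) {
  if (nrow(mentions) == 0L || length(boundaries) == 0L) return(boundaries)
  keep <- vapply(boundaries, function(b) {
    # mention occupies 1-based chars [char_start+1, char_end]; boundary b
    # starts a new sentence at b, splitting between b-1 and b
    !any(mentions$char_start + 1L < b & b <= mentions$char_end)
  }, logical(1))
  boundaries[keep]
}

#' Segment a raw annotated document and align mentions to tokens
#'
#' Splits the abstract into sentences (the title is always sentence 1),
#' tokenizes every sentence, and assigns each mention its sentence index and
#' token span.  A proposed sentence boundary that falls inside a mention span
#' (e.g. after an abbreviation period) is suppressed, keeping the mention
#' intact in a single sentence.
#'
#' @param doc_id document identifier (PMID-like string).
#' @param title,abstract document text fields.
#' @param mentions data frame with columns `char_start`, `char_end` (0-based
#'   half-open offsets over title + separator + abstract), `surface`, `etype`
#'   (`"Chemical"` or `"Disease"`) and `concept_id`.
#' @param relations data frame with columns `chemical_id`, `disease_id`.
#' @param offset_sep separator assumed between title and abstract when
#'   interpreting offsets (default `"\n"`).
#' @return a `cid_document`: sentences as token vectors, aligned mentions,
#'   the concept table and gold relations.
#' @export
segment_and_align <- function(doc_id, title, abstract,
                              mentions = empty_mentions(),
                              relations = empty_relations(),
                              offset_sep = "\n") {
  text <- paste0(title, offset_sep, abstract)
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)

  # validate surfaces against claimed offsets
  if (nrow(mentions) > 0L) {
    got <- substr(rep(text, nrow(mentions)), mentions$char_start + 1L,
                  mentions$char_end)
    bad <- which(got != mentions$surface)
    if (length(bad) > 0L) {
      stop(sprintf(
        "document %s: mention offset/surface mismatch at %d..%d: expected %s, text has %s",
        doc_id, mentions$char_start[bad[1]], mentions$char_end[bad[1]],
        dQuote(mentions$surface[bad[1]]), dQuote(got[bad[1]])))
    }
    badtype <- setdiff(unique(mentions$etype), c("Chemical", "Disease"))
    if (length(badtype) > 0L) {
      stop(sprintf("document %s: unknown entity type %s", doc_id, badtype[1]))
    }
  }

  abs_base <- nchar(title) + nchar(offset_sep)
  bnd <- propose_boundaries(abstract, base = abs_base)
  bnd <- repair_boundaries(bnd, mentions)

  # sentence spans: title, then abstract pieces between repaired boundaries
  sent_starts <- c(1L, abs_base + 1L, bnd)
  sent_ends <- c(nchar(title), bnd - 1L, nchar(text))
  if (nchar(abstract) == 0L) {
    sent_starts <- 1L
    sent_ends <- nchar(title)
  }
  keep <- sent_ends >= sent_starts
  sent_starts <- sent_starts[keep]; sent_ends <- sent_ends[keep]

  sentences <- vector("list", length(sent_starts))
  token_spans <- vector("list", length(sent_starts))
  for (s in seq_along(sent_starts)) {
    piece <- substr(text, sent_starts[s], sent_ends[s])
    tk <- tokenize_with_offsets(piece, base = sent_starts[s] - 1L)
    sentences[[s]] <- tk$tokens
    token_spans[[s]] <- tk$spans
  }
  nonempty <- lengths(sentences) > 0L
  sentences <- sentences[nonempty]
  token_spans <- token_spans[nonempty]
  sent_starts <- sent_starts[nonempty]; sent_ends <- sent_ends[nonempty]
  if (length(sentences) == 0L) {
    stop(sprintf("document %s: no tokens found", doc_id))
  }

  # mention -> sentence and token span
  n_m <- nrow(mentions)
  mentions$sentence_index <- integer(n_m)
  mentions$tok_start <- integer(n_m)
  mentions$tok_end <- integer(n_m)
  for (i in seq_len(n_m)) {
    a <- mentions$char_start[i] + 1L
    b <- mentions$char_end[i]
    s <- which(sent_starts <= a & b <= sent_ends)
    if (length(s) != 1L) {
      stop(sprintf(
        "document %s: mention at %d..%d (%s) does not fall inside one sentence",
        doc_id, mentions$char_start[i], mentions$char_end[i],
        dQuote(mentions$surface[i])))
    }
    sp <- token_spans[[s]]
    hit <- which(sp[, "start"] <= b & a <= sp[, "end"])
    if (length(hit) == 0L) {
      stop(sprintf("document %s: mention at %d..%d not alignable to tokens",
                   doc_id, mentions$char_start[i], mentions$char_end[i]))
    }
    mentions$sentence_index[i] <- s
    mentions$tok_start[i] <- min(hit)
    mentions$tok_end[i] <- max(hit)
  }

  concepts <- build_concepts(mentions)
  relations <- validate_relations(doc_id, relations, concepts)

  structure(list(
    doc_id = doc_id, title = title, abstract = abstract, text = text,
    offset_sep = offset_sep,
    sentences = sentences, token_spans = token_spans,
    sent_spans = cbind(start = sent_starts, end = sent_ends),
    mentions = mentions, concepts = concepts, relations = relations
  ), class = "cid_document")
}

empty_mentions <- function() {
  data.frame(char_start = integer(0), char_end = integer(0),
             surface = character(0), etype = character(0),
             concept_id = character(0), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(chemical_id = character(0), disease_id = character(0),
             stringsAsFactors = FALSE)
}

build_concepts <- function(mentions) {
  if (nrow(mentions) == 0L) {
    cp <- data.frame(concept_id = character(0), etype = character(0),
                     stringsAsFactors = FALSE)
    cp$mention_idx <- list()
    return(cp)
  }
  ids <- unique(mentions$concept_id)
  etype <- vapply(ids, function(id) {
    et <- unique(mentions$etype[mentions$concept_id == id])
    if (length(et) != 1L) {
      stop(sprintf("concept %s annotated with multiple entity types", id))
    }
    et
  }, character(1))
  cp <- data.frame(concept_id = ids, etype = unname(etype),
                   stringsAsFactors = FALSE)
  cp$mention_idx <- lapply(ids, function(id) which(mentions$concept_id == id))
  cp
}

validate_relations <- function(doc_id, relations, concepts) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(relations) == 0L) return(empty_relations())
  chem <- concepts$concept_id[concepts$etype == "Chemical"]
  dis <- concepts$concept_id[concepts$etype == "Disease"]
  ok <- relations$chemical_id %in% chem & relations$disease_id %in% dis
  if (any(!ok)) {
    warning(sprintf(
      "document %s: dropping %d relation(s) referencing absent concepts",
      doc_id, sum(!ok)))
    relations <- relations[ok, , drop = FALSE]
  }
  relations <- unique(relations[, c("chemical_id", "disease_id")])
  rownames(relations) <- NULL
  relations
}
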