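# PubTator corpus reader/writer.
#
# Dialect:
#   PMID|t|title
#   PMID|a|abstract
#   PMID<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>MeSH      (annotation)
#   PMID<TAB>CID<TAB>chemicalID<TAB>diseaseID                 (relation)
#   blank line between documents
#
# Composite MeSH fields ("D00X|D00Y") expand to one mention per identifier
# sharing the span; annotations normalized to "-1" are dropped with a
# warning, since the concept identifier is the unit of classification.

#' Read a PubTator-format corpus
#'
#' @param path_or_text path to a PubTator file, a connection, or a character
#'   vector of lines.
#' @param offset_sep separator assumed between title and abstract when
#'   interpreting annotation offsets (`"\n"`, the default, or `" "`);
#'   validated against every mention surface.
#' @param split_tag tag attached to the returned corpus
#'   (`train`/`dev`/`test`/`synthetic`).
#' @return a `cid_corpus`: a list of `cid_document`s.
#' @export
read_pubtator <- function(path_or_text, offset_sep = "\n",
                          split_tag = "train") {
  lines <- if (inherits(path_or_text, "connection")) {
    readLines(path_or_text, warn = FALSE)
  } else if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
             file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE)
  } else if (length(path_or_text) == 1L) {
    strsplit(path_or_text, "\n", fixed = TRUE)[[1]]
  } else {
    path_or_text  # already a vector of lines
  }
  lines <- sub("\r$", "", lines)

  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[lengths(blocks) > 0L]

  docs <- lapply(blocks, parse_pubtator_block, offset_sep = offset_sep)
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate document ids in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  new_corpus(docs, split_tag = split_tag)
}

parse_pubtator_block <- function(block, offset_sep = "\n") {
  tl <- grep("^[^\t|]+\\|t\\|", block, value = TRUE)
  al <- grep("^[^\t|]+\\|a\\|", block, value = TRUE)
  if (length(tl) != 1L) stop("PubTator block without a unique title line")
  doc_id <- sub("\\|.*$", "", tl)
  title <- sub("^[^|]+\\|t\\|", "", tl)
  abstract <- if (length(al) >= 1L) sub("^[^|]+\\|a\\|", "", al[1]) else ""

  tab_lines <- grep("\t", block, value = TRUE)
  fields <- strsplit(tab_lines, "\t", fixed = TRUE)

  mention_rows <- list()
  relations <- empty_relations()
  for (f in fields) {
    if (length(f) >= 4L && f[2] == "CID") {
      relations <- rbind(relations,
                         data.frame(chemical_id = f[3], disease_id = f[4],
                                    stringsAsFactors = FALSE))
    } else if (length(f) >= 6L) {
      if (f[1] != doc_id) {
        stop(sprintf("annotation line PMID %s inside document %s", f[1], doc_id))
      }
      ids <- strsplit(f[6], "|", fixed = TRUE)[[1]]
      ids <- ids[ids != ""]
      dropped <- ids == "-1"
      if (any(dropped)) {
        warning(sprintf(
          "document %s: dropping unnormalized annotation %s at %s..%s",
          doc_id, dQuote(f[4]), f[2], f[3]))
        ids <- ids[!dropped]
      }
      for (id in ids) {
        mention_rows[[length(mention_rows) + 1L]] <- data.frame(
          char_start = as.integer(f[2]), char_end = as.integer(f[3]),
          surface = f[4], etype = f[5], concept_id = id,
          stringsAsFactors = FALSE)
      }
    } else {
      stop(sprintf("document %s: malformed tab-separated line: %s",
                   doc_id, paste(f, collapse = "\t")))
    }
  }
  mentions <- if (length(mention_rows) > 0L) do.call(rbind, mention_rows)
              else empty_mentions()

  segment_and_align(doc_id, title, abstract, mentions, relations,
                    offset_sep = offset_sep)
}

#' @export
new_corpus <- function(documents, split_tag = "train") {
  structure(list(documents = unname(documents), split_tag = split_tag),
            class = "cid_corpus")
}

#' @export
print.cid_corpus <- function(x, ...) {
  cat(sprintf("<cid_corpus> %d documents (%s)\n",
              length(x$documents), x$split_tag))
  invisible(x)
}

#' @export
print.cid_document <- function(x, ...) {
  cat(sprintf("<cid_document %s> T=%d sentences, N=%d mentions, R=%d concepts, %d gold relations\n",
              x$doc_id, length(x$sentences), nrow(x$mentions),
              nrow(x$concepts), nrow(x$relations)))
  invisible(x)
}

#' Write a corpus in PubTator format
#'
#' The output re-parses (with [read_pubtator()]) to an identical corpus.
#'
#' @param corpus a `cid_corpus`.
#' @param path output file path or connection; omit to return the lines.
#' @export
write_pubtator <- function(corpus, path = NULL) {
  out <- as.character(unlist(lapply(corpus$documents, function(d) {
    header <- c(paste0(d$doc_id, "|t|", d$title),
                paste0(d$doc_id, "|a|", d$abstract))
    ann <- character(0)
    if (nrow(d$mentions) > 0L) {
      m <- d$mentions
      ann <- paste(d$doc_id, m$char_start, m$char_end, m$surface, m$etype,
                   m$concept_id, sep = "\t")
    }
    rel <- character(0)
    if (nrow(d$relations) > 0L) {
      rel <- paste(d$doc_id, "CID", d$relations$chemical_id,
                   d$relations$disease_id, sep = "\t")
    }
    c(header, ann, rel, "")
  }), use.names = FALSE))
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(NULL)
}

#' Enumerate candidate chemical-disease concept pairs of a document
#'
#' The full cross-product of chemical and disease concepts, labelled 1 when
#' the pair is a gold relation, in deterministic lexicographic order
#' (chemical id, then disease id).
#'
#' @param document a `cid_document`.
#' @return data frame with columns `chemical_id`, `disease_id`, `label`.
#' @export
enumerate_candidate_pairs <- function(document) {
  chem <- sort(document$concepts$concept_id[document$concepts$etype == "Chemical"])
  dis <- sort(document$concepts$concept_id[document$concepts$etype == "Disease"])
  if (length(chem) == 0L || length(dis) == 0L) {
    return(data.frame(chemical_id = character(0), disease_id = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  pairs <- expand.grid(disease_id = dis, chemical_id = chem,
                       stringsAsFactors = FALSE)[, c("chemical_id", "disease_id")]
  pairs <- pairs[order(pairs$chemical_id, pairs$disease_id), , drop = FALSE]
  key <- paste(pairs$chemical_id, pairs$disease_id)
  gold <- paste(document$relations$chemical_id, document$relations$disease_id)
  pairs$label <- as.integer(key %in% gold)
  rownames(pairs) <- NULL
  pairs
}
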