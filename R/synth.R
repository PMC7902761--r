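# Synthetic PubTator corpus generator.
#
# Emulates the structural statistics of document-level chemical-disease
# corpora: multi-sentence abstracts, multi-mention entities normalized to
# MeSH-like identifiers, document-level chemical->disease relations, and a
# configurable fraction of positives realized only across sentences.
#
# The positive label is a deterministic function of lexical witnesses:
#   intra : one sentence  "<chem> <cue> <dis> ."
#   inter : "<chem> was administered ."  +  "<dis> was observed ."  in
#           different sentences, plus a mention-free witness sentence
#           "the drug <cue> the illness ."
# Distractor "administered"/"observed" sentences appear only in documents
# without a witness sentence, so resolving inter-sentence pairs requires
# aggregating evidence from a sentence containing neither mention.
# Negative pairs may co-occur in a sentence, always without the cue.

#' Synthetic-corpus configuration
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc integer range (min, max) of sentences per
#'   document, title included.
#' @param chemicals_per_doc,diseases_per_doc integer ranges of distinct
#'   concepts per document.
#' @param mentions_per_concept integer range of mentions per concept
#'   (witness templates may force more than the drawn value).
#' @param inter_fraction fraction of positive pairs realized only across
#'   sentences (corpus-wide, matched exactly after rounding).
#' @param positive_rate fraction of candidate chemical x disease pairs per
#'   document made positive (rounded).
#' @param distractor_rate probability that a witness-free document receives
#'   an "administered" (resp. "observed") distractor sentence.
#' @param cooccur_rate probability that a negative pair co-occurs in one
#'   cue-free sentence.
#' @param vocab_size number of pseudo-words in the filler vocabulary.
#' @param concept_pool_size number of distinct chemical (and disease)
#'   concepts shared across the corpus.
#' @param cue_token the lexical cue marking a causal witness.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_docs = 100,
                         sentences_per_doc = c(6L, 10L),
                         chemicals_per_doc = c(1L, 3L),
                         diseases_per_doc = c(1L, 3L),
                         mentions_per_concept = c(1L, 3L),
                         inter_fraction = 0.30,
                         positive_rate = 0.30,
                         distractor_rate = 0.5,
                         cooccur_rate = 0.3,
                         vocab_size = 150L,
                         concept_pool_size = 40L,
                         cue_token = "induced",
                         seed = 1L) {
  cfg <- list(n_docs = as.integer(n_docs),
              sentences_per_doc = as.integer(sentences_per_doc),
              chemicals_per_doc = as.integer(chemicals_per_doc),
              diseases_per_doc = as.integer(diseases_per_doc),
              mentions_per_concept = as.integer(mentions_per_concept),
              inter_fraction = inter_fraction,
              positive_rate = positive_rate,
              distractor_rate = distractor_rate,
              cooccur_rate = cooccur_rate,
              vocab_size = as.integer(vocab_size),
              concept_pool_size = as.integer(concept_pool_size),
              cue_token = cue_token,
              seed = as.integer(seed))
  stopifnot(cfg$n_docs >= 0L,
            length(cfg$sentences_per_doc) == 2L,
            cfg$sentences_per_doc[1] <= cfg$sentences_per_doc[2],
            cfg$mentions_per_concept[1] >= 1L,
            cfg$inter_fraction >= 0, cfg$inter_fraction <= 1,
            cfg$positive_rate >= 0, cfg$positive_rate <= 1)
  class(cfg) <- "synth_config"
  cfg
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1]
  else sample(seq(range[1], range[2]), 1L)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given `config$seed`.  Corpus-wide, exactly
#' `round(inter_fraction * n_positives)` positive pairs are inter-sentence
#' (no sentence contains mentions of both concepts); each document hosts at
#' most one "administered" chemical so that inter-sentence labels remain
#' decidable from the document graph, which carries no sentence order.
#'
#' @param config a [synth_config()].
#' @return a `cid_corpus` with `split_tag = "synthetic"`.
#' @export
generate_corpus <- function(config = synth_config()) {
  cfg <- config
  struct <- new_rng_stream(cfg$seed)
  lex <- new_rng_stream(cfg$seed + 1000003L)

  chem_pool <- data.frame(
    concept_id = sprintf("D%06d", 100000L + seq_len(cfg$concept_pool_size)),
    surface = paste0("chemical", seq_len(cfg$concept_pool_size)),
    stringsAsFactors = FALSE)
  dis_pool <- data.frame(
    concept_id = sprintf("D%06d", 200000L + seq_len(cfg$concept_pool_size)),
    surface = paste0("disease", seq_len(cfg$concept_pool_size)),
    stringsAsFactors = FALSE)
  filler <- paste0("w", sprintf("%03d", seq_len(cfg$vocab_size)))

  # ---- structural plan per document ------------------------------------
  plans <- rng_with(struct, lapply(seq_len(cfg$n_docs), function(i) {
    nc <- sample_range(cfg$chemicals_per_doc)
    nd <- sample_range(cfg$diseases_per_doc)
    chems <- chem_pool[sample(nrow(chem_pool), nc), , drop = FALSE]
    diss <- dis_pool[sample(nrow(dis_pool), nd), , drop = FALSE]
    pairs <- expand.grid(ci = seq_len(nc), di = seq_len(nd))
    npos <- round(cfg$positive_rate * nrow(pairs))
    pos <- if (npos > 0L) pairs[sample(nrow(pairs), npos), , drop = FALSE]
           else pairs[0, , drop = FALSE]
    m_target_c <- replicate(nc, sample_range(cfg$mentions_per_concept))
    m_target_d <- replicate(nd, sample_range(cfg$mentions_per_concept))
    list(doc_id = as.character(9000000L + i), chems = chems, diss = diss,
         pos = pos, m_target_c = m_target_c, m_target_d = m_target_d,
         T_drawn = sample_range(cfg$sentences_per_doc))
  }))

  # ---- corpus-wide inter/intra allocation ------------------------------
  # Each document can host inter positives for a single chemical only.
  total_pos <- sum(vapply(plans, function(p) nrow(p$pos), integer(1)))
  n_inter <- round(cfg$inter_fraction * total_pos)
  plans <- rng_with(struct, {
    order_docs <- if (length(plans) > 0L) sample(length(plans)) else integer(0)
    remaining <- n_inter
    for (k in order_docs) {
      p <- plans[[k]]
      p$inter <- rep(FALSE, nrow(p$pos))
      if (remaining > 0L && nrow(p$pos) > 0L) {
        counts <- table(p$pos$ci)
        best_ci <- as.integer(names(counts)[which.max(counts)])
        cand <- which(p$pos$ci == best_ci)
        take <- min(remaining, length(cand))
        p$inter[sample_vec(cand, take)] <- TRUE
        remaining <- remaining - take
      }
      plans[[k]] <- p
    }
    if (remaining > 0L) {
      stop(sprintf(
        "infeasible config: cannot realize %d inter-sentence positives", n_inter))
    }
    plans
  })

  docs <- lapply(plans, function(p) realize_document(p, cfg, filler,
                                                     struct, lex))
  new_corpus(docs, split_tag = "synthetic")
}

# sample() with the degenerate-length-1 pitfall removed
sample_vec <- function(x, k) if (length(x) == 1L) x[seq_len(k)] else sample(x, k)

realize_document <- function(plan, cfg, filler, struct, lex) {
  cue <- cfg$cue_token
  chems <- plan$chems; diss <- plan$diss
  nc <- nrow(chems); nd <- nrow(diss)
  pos <- plan$pos; inter <- plan$inter

  # sentence = list(tokens, mention = data.frame(tok, concept_id, surface, etype))
  sent <- list()
  add_sentence <- function(tokens, m_tok = integer(0), m_ci = character(0),
                           m_et = character(0)) {
    sent[[length(sent) + 1L]] <<- list(
      tokens = tokens,
      mentions = data.frame(tok = m_tok, concept_id = m_ci, etype = m_et,
                            stringsAsFactors = FALSE))
  }

  mention_count <- stats::setNames(
    rep(0L, nc + nd), c(chems$concept_id, diss$concept_id))
  bump <- function(ids) {
    mention_count[ids] <<- mention_count[ids] + 1L
  }

  # intra positives: "<chem> <cue> <dis> ."
  for (r in which(!inter)) {
    cs <- chems$surface[pos$ci[r]]; ds <- diss$surface[pos$di[r]]
    add_sentence(c(cs, cue, ds, "."),
                 m_tok = c(1L, 3L),
                 m_ci = c(chems$concept_id[pos$ci[r]],
                          diss$concept_id[pos$di[r]]),
                 m_et = c("Chemical", "Disease"))
    bump(c(chems$concept_id[pos$ci[r]], diss$concept_id[pos$di[r]]))
  }

  # inter positives: administered chem + observed diseases + witness
  has_witness <- any(inter)
  if (has_witness) {
    ci <- unique(pos$ci[inter])
    stopifnot(length(ci) == 1L)
    add_sentence(c(chems$surface[ci], "was", "administered", "."),
                 m_tok = 1L, m_ci = chems$concept_id[ci], m_et = "Chemical")
    bump(chems$concept_id[ci])
    for (r in which(inter)) {
      add_sentence(c(diss$surface[pos$di[r]], "was", "observed", "."),
                   m_tok = 1L, m_ci = diss$concept_id[pos$di[r]],
                   m_et = "Disease")
      bump(diss$concept_id[pos$di[r]])
    }
    add_sentence(c("the", "drug", cue, "the", "illness", "."))
  }

  # mandatory: every concept needs at least one mention
  all_concepts <- rbind(
    data.frame(concept_id = chems$concept_id, surface = chems$surface,
               etype = "Chemical", target = plan$m_target_c,
               stringsAsFactors = FALSE),
    data.frame(concept_id = diss$concept_id, surface = diss$surface,
               etype = "Disease", target = plan$m_target_d,
               stringsAsFactors = FALSE))
  for (k in which(mention_count[all_concepts$concept_id] == 0L)) {
    add_sentence(c(all_concepts$surface[k], "appeared", "."),
                 m_tok = 1L, m_ci = all_concepts$concept_id[k],
                 m_et = all_concepts$etype[k])
    bump(all_concepts$concept_id[k])
  }

  core <- 1L + length(sent)  # + title
  s_max <- cfg$sentences_per_doc[2]
  if (core > s_max) {
    stop(sprintf(
      "infeasible config: document %s needs %d sentences, range allows %d",
      plan$doc_id, core, s_max))
  }
  room <- function() s_max - 1L - length(sent)

  # optional, budget-capped: negative co-occurrence (cue-free), distractors
  rng_with(struct, {
    pos_key <- paste(pos$ci, pos$di)
    for (ci in seq_len(nc)) for (di in seq_len(nd)) {
      if (paste(ci, di) %in% pos_key || room() <= 0L) next
      if (stats::runif(1) < cfg$cooccur_rate) {
        add_sentence(c(chems$surface[ci], "and", diss$surface[di], "."),
                     m_tok = c(1L, 3L),
                     m_ci = c(chems$concept_id[ci], diss$concept_id[di]),
                     m_et = c("Chemical", "Disease"))
        bump(c(chems$concept_id[ci], diss$concept_id[di]))
      }
    }
    if (!has_witness) {
      if (room() > 0L && stats::runif(1) < cfg$distractor_rate) {
        ci <- sample(nc, 1L)
        add_sentence(c(chems$surface[ci], "was", "administered", "."),
                     m_tok = 1L, m_ci = chems$concept_id[ci], m_et = "Chemical")
        bump(chems$concept_id[ci])
      }
      if (room() > 0L && stats::runif(1) < cfg$distractor_rate) {
        di <- sample(nd, 1L)
        add_sentence(c(diss$surface[di], "was", "observed", "."),
                     m_tok = 1L, m_ci = diss$concept_id[di], m_et = "Disease")
        bump(diss$concept_id[di])
      }
    }
  })

  T_total <- min(max(plan$T_drawn, 1L + length(sent)), s_max)

  # extra mentions ("<surface> appeared .") while the budget allows;
  # concepts still at a single mention get priority so that multi-mention
  # concepts span multiple sentences
  rng_with(struct, {
    need <- pmax(all_concepts$target - mention_count[all_concepts$concept_id], 0L)
    ord <- order(mention_count[all_concepts$concept_id],
                 -need, sample(nrow(all_concepts)))
    queue <- rep(ord, times = need[ord])
    budget <- max(0L, T_total - 1L - length(sent))
    for (k in queue[seq_len(min(length(queue), budget))]) {
      add_sentence(c(all_concepts$surface[k], "appeared", "."),
                   m_tok = 1L, m_ci = all_concepts$concept_id[k],
                   m_et = all_concepts$etype[k])
      bump(all_concepts$concept_id[k])
    }
  })

  # filler sentences up to T_total, then shuffle abstract sentence order
  n_fill <- T_total - 1L - length(sent)
  rng_with(lex, {
    for (k in seq_len(max(0L, n_fill))) {
      add_sentence(c(sample(filler, sample(4:7, 1L), replace = TRUE), "."))
    }
  })
  sent <- rng_with(struct, sent[sample(length(sent))])
  title_tokens <- rng_with(lex, sample(filler, sample(3:5, 1L), replace = TRUE))

  # ---- assemble text + annotation offsets ------------------------------
  title <- paste(title_tokens, collapse = " ")
  sep <- "\n"
  offset <- nchar(title) + nchar(sep)
  ann <- list()
  abstract_parts <- character(length(sent))
  for (s in seq_along(sent)) {
    toks <- sent[[s]]$tokens
    starts <- offset + cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
    stxt <- paste(toks, collapse = " ")
    m <- sent[[s]]$mentions
    for (j in seq_len(nrow(m))) {
      tk <- m$tok[j]
      ann[[length(ann) + 1L]] <- data.frame(
        char_start = starts[tk], char_end = starts[tk] + nchar(toks[tk]),
        surface = toks[tk], etype = m$etype[j], concept_id = m$concept_id[j],
        stringsAsFactors = FALSE)
    }
    abstract_parts[s] <- stxt
    offset <- offset + nchar(stxt) + 1L  # sentences joined by " "
  }
  abstract <- paste(abstract_parts, collapse = " ")
  mentions <- if (length(ann) > 0L) do.call(rbind, ann) else empty_mentions()
  mentions <- mentions[order(mentions$char_start), , drop = FALSE]
  rownames(mentions) <- NULL

  relations <- data.frame(
    chemical_id = chems$concept_id[pos$ci],
    disease_id = diss$concept_id[pos$di],
    stringsAsFactors = FALSE)
  relations <- relations[order(relations$chemical_id, relations$disease_id),
                         , drop = FALSE]
  rownames(relations) <- NULL

  segment_and_align(plan$doc_id, title, abstract, mentions, relations,
                    offset_sep = sep)
}

#' Summary statistics of a corpus
#'
#' @param corpus a `cid_corpus`.
#' @return list with document/sentence/mention/concept counts, candidate and
#'   positive pair counts, the intra/inter split of the positives, and the
#'   fraction of multi-mention concepts whose mentions span >= 2 sentences.
#' @export
corpus_stats <- function(corpus) {
  docs <- corpus$documents
  n_multi <- 0L; n_multi_spread <- 0L
  intra <- 0L; inter <- 0L
  for (d in docs) {
    for (k in seq_len(nrow(d$concepts))) {
      idx <- d$concepts$mention_idx[[k]]
      if (length(idx) >= 2L) {
        n_multi <- n_multi + 1L
        if (length(unique(d$mentions$sentence_index[idx])) >= 2L) {
          n_multi_spread <- n_multi_spread + 1L
        }
      }
    }
    for (r in seq_len(nrow(d$relations))) {
      kind <- split_intra_inter(d, d$relations$chemical_id[r],
                                d$relations$disease_id[r])
      if (kind == "intra") intra <- intra + 1L else inter <- inter + 1L
    }
  }
  list(
    documents = length(docs),
    sentences = sum(vapply(docs, function(d) length(d$sentences), integer(1))),
    mentions = sum(vapply(docs, function(d) nrow(d$mentions), integer(1))),
    concepts = sum(vapply(docs, function(d) nrow(d$concepts), integer(1))),
    candidate_pairs = sum(vapply(docs, function(d)
      nrow(enumerate_candidate_pairs(d)), integer(1))),
    positives = intra + inter,
    intra_positives = intra,
    inter_positives = inter,
    multi_mention_concepts = n_multi,
    multi_mention_multi_sentence_fraction =
      if (n_multi == 0L) NA_real_ else n_multi_spread / n_multi
  )
}
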