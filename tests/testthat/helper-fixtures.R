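# Fixtures are built in code: a tiny hand-written abstract, a document with
# the canonical 8-sentence / 12-mention / 6-concept structure, and small
# helpers for assembling PubTator blocks with correct offsets.

# Assemble a PubTator block from tokenized sentences.  Sentences are joined
# by a single space; the title is the first "sentence"; mentions are given
# as list(sentence, token, etype, concept_id) with 1-based indices.
pubtator_block <- function(doc_id, title_tokens, sentence_tokens, mentions,
                           relations = NULL) {
  title <- paste(title_tokens, collapse = " ")
  offset <- nchar(title) + 1L  # "\n" separator
  ann <- character(0)
  parts <- character(length(sentence_tokens))
  for (s in seq_along(sentence_tokens)) {
    toks <- sentence_tokens[[s]]
    starts <- offset + cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
    for (m in mentions) {
      if (m$sentence == s) {
        st <- starts[m$token]
        ann <- c(ann, paste(doc_id, st, st + nchar(toks[m$token]),
                            toks[m$token], m$etype, m$concept_id, sep = "\t"))
      }
    }
    parts[s] <- paste(toks, collapse = " ")
    offset <- offset + nchar(parts[s]) + 1L
  }
  rel <- vapply(relations, function(r) {
    paste(doc_id, "CID", r[1], r[2], sep = "\t")
  }, character(1))
  c(paste0(doc_id, "|t|", title),
    paste0(doc_id, "|a|", paste(parts, collapse = " ")),
    ann, rel, "")
}

# Two sentences (title + one abstract sentence), 3 mentions, 2 concepts,
# 1 CID fact.
tiny_pubtator_lines <- function() {
  pubtator_block(
    "100001",
    title_tokens = c("naloxone", "and", "hypertension"),
    sentence_tokens = list(c("naloxone", "attenuates", "hypertension", ".")),
    mentions = list(
      list(sentence = 1L, token = 1L, etype = "Chemical",
           concept_id = "D009270"),
      list(sentence = 1L, token = 3L, etype = "Disease",
           concept_id = "D006973")),
    relations = list(c("D009270", "D006973"))) -> block
  # add the two title mentions by hand (title tokens: 0- and 13-offset)
  c(block[1:2],
    paste("100001", 0, 8, "naloxone", "Chemical", "D009270", sep = "\t"),
    block[3:length(block)])
}

tiny_corpus <- function() read_pubtator(tiny_pubtator_lines())

# 8 sentences (title + 7), 12 mentions, 6 concepts (3 chemicals, 3
# diseases): the canonical document-scale example.
example_structure_lines <- function() {
  chem <- function(i) list(etype = "Chemical", concept_id = sprintf("D10000%d", i))
  dis <- function(i) list(etype = "Disease", concept_id = sprintf("D20000%d", i))
  m <- function(s, t, who) c(list(sentence = s, token = t), who)
  pubtator_block(
    "200001",
    title_tokens = c("drugA", "in", "advanced", "sarcoma"),
    sentence_tokens = list(
      c("drugA", "was", "given", "."),
      c("patients", "received", "drugB", "and", "drugC", "."),
      c("drugA", "induced", "anemia", "."),
      c("nausea", "was", "frequent", "."),
      c("three", "subjects", "had", "neutropenia", "."),
      c("drugB", "and", "nausea", "were", "unrelated", "."),
      c("neutropenia", "resolved", "after", "drugC", ".")),
    mentions = list(
      # title: drugA (sentence 0 = title handled below)
      m(1, 1, chem(1)), m(2, 3, chem(2)), m(2, 5, chem(3)),
      m(3, 1, chem(1)), m(3, 3, dis(1)), m(4, 1, dis(2)),
      m(5, 4, dis(3)), m(6, 1, chem(2)), m(6, 3, dis(2)),
      m(7, 1, dis(3)), m(7, 4, chem(3))),
    relations = list(c("D100001", "D200001"), c("D100003", "D200003"))
  ) -> block
  # title mention of drugA: offset 0..5
  c(block[1:2],
    paste("200001", 0, 5, "drugA", "Chemical", "D100001", sep = "\t"),
    block[3:length(block)])
}

example_structure_doc <- function() {
  read_pubtator(example_structure_lines())$documents[[1]]
}

# Vocabulary of a corpus (lowercased tokens)
corpus_vocab <- function(corpus) {
  sort(unique(unlist(lapply(corpus$documents,
                            function(d) tolower(unlist(d$sentences))))))
}

# Small model for plumbing tests
tiny_model <- function(corpus, d_w = 6L, d_h = 5L, d_t = 3L, n_layers = 2L,
                       mode = "gated", seed = 1L, ...) {
  cid_model(corpus_vocab(corpus), d_w = d_w, d_h = d_h, d_t = d_t,
            n_layers = n_layers, mode = mode, seed = seed, ...)
}
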