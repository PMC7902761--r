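# PubTator reading, writing and candidate-pair enumeration.

test_that("empty input yields an empty corpus", {
  corp <- read_pubtator(character(0))
  expect_s3_class(corp, "cid_corpus")
  expect_length(corp$documents, 0)
  expect_equal(write_pubtator(corp), character(0))
})

test_that("the tiny fixture parses to the expected document", {
  corp <- tiny_corpus()
  expect_length(corp$documents, 1)
  d <- corp$documents[[1]]
  expect_equal(length(d$sentences), 2)        # title + 1 abstract sentence
  expect_equal(nrow(d$mentions), 3)
  expect_equal(nrow(d$concepts), 2)
  expect_equal(nrow(d$relations), 1)
  expect_equal(d$relations$chemical_id, "D009270")
  # every surface equals the character slice it claims
  for (i in seq_len(nrow(d$mentions))) {
    expect_identical(
      substr(d$text, d$mentions$char_start[i] + 1L, d$mentions$char_end[i]),
      d$mentions$surface[i])
  }
  # the title mention is sentence 1; abstract mentions sentence 2
  expect_equal(sort(unique(d$mentions$sentence_index)), c(1, 2))
})

test_that("the 8-sentence example structure parses to T=8, N=12, R=6", {
  d <- example_structure_doc()
  expect_equal(length(d$sentences), 8)
  expect_equal(nrow(d$mentions), 12)
  expect_equal(nrow(d$concepts), 6)
  expect_equal(sum(d$concepts$etype == "Chemical"), 3)
  expect_equal(sum(d$concepts$etype == "Disease"), 3)
})

test_that("read-write-read is the identity on fixtures and synthetic corpora", {
  for (corp in list(tiny_corpus(),
                    generate_corpus(synth_config(n_docs = 3, seed = 5)))) {
    txt <- write_pubtator(corp)
    corp2 <- read_pubtator(txt, split_tag = corp$split_tag)
    expect_identical(write_pubtator(corp2), txt)
    # field-by-field: mentions, concepts and relations survive
    for (k in seq_along(corp$documents)) {
      expect_equal(corp2$documents[[k]]$mentions, corp$documents[[k]]$mentions)
      expect_equal(corp2$documents[[k]]$relations,
                   corp$documents[[k]]$relations)
      expect_equal(corp2$documents[[k]]$sentences,
                   corp$documents[[k]]$sentences)
    }
  }
})

test_that("composite MeSH ids expand and unnormalized ids are dropped", {
  lines <- c("300001|t|combo toxicity",
             "300001|a|comboX causes rash .",
             paste("300001", 15, 21, "comboX", "Chemical", "D000111|D000222",
                   sep = "\t"),
             paste("300001", 29, 33, "rash", "Disease", "D000333", sep = "\t"),
             "")
  corp <- read_pubtator(lines)
  d <- corp$documents[[1]]
  expect_equal(nrow(d$mentions), 3)  # composite expanded to two mentions
  expect_setequal(d$mentions$concept_id[d$mentions$etype == "Chemical"],
                  c("D000111", "D000222"))
  # both expanded mentions share the span
  sp <- d$mentions[d$mentions$etype == "Chemical", c("char_start", "char_end")]
  expect_equal(nrow(unique(sp)), 1)

  lines_unnorm <- c("300002|t|tt",
                    "300002|a|badword here .",
                    paste("300002", 3, 10, "badword", "Chemical", "-1",
                          sep = "\t"),
                    "")
  expect_warning(corp2 <- read_pubtator(lines_unnorm), "unnormalized")
  expect_equal(nrow(corp2$documents[[1]]$mentions), 0)
})

test_that("malformed input is rejected with informative errors", {
  bad_offset <- c("400001|t|abc def",
                  "400001|a|ghi jkl .",
                  paste("400001", 0, 3, "zzz", "Chemical", "D1", sep = "\t"),
                  "")
  expect_error(read_pubtator(bad_offset), "mismatch")

  bad_type <- c("400002|t|abc def",
                "400002|a|ghi jkl .",
                paste("400002", 0, 3, "abc", "Gene", "D1", sep = "\t"),
                "")
  expect_error(read_pubtator(bad_type), "entity type")

  dangling_rel <- c("400003|t|abc def",
                    "400003|a|ghi jkl .",
                    paste("400003", 0, 3, "abc", "Chemical", "D1", sep = "\t"),
                    paste("400003", "CID", "D1", "D999", sep = "\t"),
                    "")
  expect_warning(corp <- read_pubtator(dangling_rel), "absent")
  expect_equal(nrow(corp$documents[[1]]$relations), 0)
})

test_that("candidate pairs are the labelled chemical x disease cross-product", {
  d <- example_structure_doc()  # 3 chemicals x 3 diseases
  pairs <- enumerate_candidate_pairs(d)
  expect_equal(nrow(pairs), 9)
  expect_equal(sum(pairs$label), 2)
  # deterministic lexicographic order
  expect_identical(pairs, pairs[order(pairs$chemical_id, pairs$disease_id), ])

  # no chemicals -> empty list
  lines <- c("500001|t|tt",
             "500001|a|rash happened .",
             paste("500001", 3, 7, "rash", "Disease", "D3", sep = "\t"),
             "")
  expect_equal(nrow(enumerate_candidate_pairs(
    read_pubtator(lines)$documents[[1]])), 0)
})

test_that("pair enumeration depends only on concept ids, not mention order", {
  corp <- generate_corpus(synth_config(n_docs = 2, seed = 9))
  d <- corp$documents[[1]]
  d2 <- d
  perm <- rev(seq_len(nrow(d$mentions)))
  d2$mentions <- d$mentions[perm, ]
  rownames(d2$mentions) <- NULL
  d2$concepts <- build_concepts(d2$mentions)
  expect_identical(enumerate_candidate_pairs(d2),
                   enumerate_candidate_pairs(d))
})
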