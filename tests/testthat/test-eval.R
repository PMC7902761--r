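# Intra/inter classification and micro-averaged evaluation.

make_pred <- function(doc_id, chem, dis, label = 1L, score = 1) {
  data.frame(doc_id = doc_id, chemical_id = chem, disease_id = dis,
             score = score, label = label, stringsAsFactors = FALSE)
}

test_that("sentence co-occurrence decides intra versus inter", {
  d <- tiny_corpus()$documents[[1]]
  # both concepts have a mention in the abstract sentence
  expect_equal(split_intra_inter(d, "D009270", "D006973"), "intra")
  expect_error(split_intra_inter(d, "D009270", "D999999"), "absent")

  # chemical in many sentences, disease only in a final sentence that does
  # not contain the chemical -> inter
  lines <- pubtator_block(
    "700001",
    title_tokens = c("long", "term", "drugX", "therapy"),
    sentence_tokens = list(
      c("drugX", "was", "assessed", "."),
      c("drugX", "was", "continued", "."),
      c("growth", "retardation", "appears", "significant", ".")),
    mentions = list(
      list(sentence = 1L, token = 1L, etype = "Chemical", concept_id = "D011433"),
      list(sentence = 2L, token = 1L, etype = "Chemical", concept_id = "D011433"),
      list(sentence = 3L, token = 1L, etype = "Disease", concept_id = "D005317")),
    relations = list(c("D011433", "D005317")))
  lines <- c(lines[1:2],
             paste("700001", 10, 15, "drugX", "Chemical", "D011433", sep = "\t"),
             lines[3:length(lines)])
  d2 <- read_pubtator(lines)$documents[[1]]
  expect_equal(split_intra_inter(d2, "D011433", "D005317"), "inter")

  # shared sentence anywhere makes the pair intra
  d3 <- example_structure_doc()
  expect_equal(split_intra_inter(d3, "D100001", "D200001"), "intra")
  expect_equal(split_intra_inter(d3, "D100001", "D200003"), "inter")
})

test_that("evaluation has its closed-form corner cases", {
  corp <- tiny_corpus()
  gold <- make_pred("100001", "D009270", "D006973")
  r <- evaluate_predictions(corp, gold)
  expect_equal(r$overall$f1, 1)
  expect_equal(r$intra$f1, 1)
  expect_equal(r$inter$tp + r$inter$fp + r$inter$fn, 0)

  # no predictions: recall 0, precision reported as 0
  r0 <- evaluate_predictions(corp, gold[0, ])
  expect_equal(r0$overall$precision, 0)
  expect_equal(r0$overall$recall, 0)
  expect_equal(r0$overall$f1, 0)

  expect_error(evaluate_predictions(corp, make_pred("zzz", "a", "b")),
               "unknown")
})

test_that("gold {a,b,c} against predicted {a,b,d} scores 2/3 everywhere", {
  lines <- c(
    pubtator_block("800001",
      title_tokens = c("tt"),
      sentence_tokens = list(c("c1", "induced", "d1", "."),
                             c("c2", "induced", "d2", "."),
                             c("c3", "induced", "d3", "."),
                             c("c4", "and", "d4", ".")),
      mentions = list(
        list(sentence = 1L, token = 1L, etype = "Chemical", concept_id = "C1"),
        list(sentence = 1L, token = 3L, etype = "Disease", concept_id = "D1"),
        list(sentence = 2L, token = 1L, etype = "Chemical", concept_id = "C2"),
        list(sentence = 2L, token = 3L, etype = "Disease", concept_id = "D2"),
        list(sentence = 3L, token = 1L, etype = "Chemical", concept_id = "C3"),
        list(sentence = 3L, token = 3L, etype = "Disease", concept_id = "D3"),
        list(sentence = 4L, token = 1L, etype = "Chemical", concept_id = "C4"),
        list(sentence = 4L, token = 3L, etype = "Disease", concept_id = "D4")),
      relations = list(c("C1", "D1"), c("C2", "D2"), c("C3", "D3"))))
  corp <- read_pubtator(lines)
  pred <- rbind(make_pred("800001", "C1", "D1"),
                make_pred("800001", "C2", "D2"),
                make_pred("800001", "C4", "D4"))
  r <- evaluate_predictions(corp, pred)
  expect_equal(r$overall$precision, 2 / 3)
  expect_equal(r$overall$recall, 2 / 3)
  expect_equal(r$overall$f1, 2 / 3)
})

test_that("intra and inter partitions conserve the overall counts", {
  corp <- generate_corpus(synth_config(n_docs = 20, seed = 67,
                                       inter_fraction = 0.4))
  # predict a scrambled subset: half the gold plus some negatives
  preds <- list()
  for (d in corp$documents) {
    pairs <- enumerate_candidate_pairs(d)
    set.seed(as.integer(d$doc_id) %% 1000)
    take <- pairs[sample(nrow(pairs), ceiling(nrow(pairs) / 2)), ]
    if (nrow(take) > 0) {
      preds[[length(preds) + 1L]] <-
        make_pred(d$doc_id, take$chemical_id, take$disease_id)
    }
  }
  pred <- do.call(rbind, preds)
  r <- evaluate_predictions(corp, pred)
  for (f in c("tp", "fp", "fn")) {
    expect_equal(r$intra[[f]] + r$inter[[f]], r$overall[[f]])
  }
  # report-internal F1 consistency
  for (b in c("overall", "intra", "inter")) {
    v <- r[[b]]
    p <- if (v$tp + v$fp == 0) 0 else v$tp / (v$tp + v$fp)
    rr <- if (v$tp + v$fn == 0) 0 else v$tp / (v$tp + v$fn)
    f1 <- if (p + rr == 0) 0 else 2 * p * rr / (p + rr)
    expect_equal(v$f1, f1, tolerance = 1e-9)
  }
  # invariant to prediction order and duplication
  r2 <- evaluate_predictions(corp, pred[rev(seq_len(nrow(pred))), ])
  expect_equal(r2, r)
  r3 <- evaluate_predictions(corp, rbind(pred, pred[1, ]))
  expect_equal(r3, r)
})
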