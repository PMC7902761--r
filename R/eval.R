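# Concept-pair evaluation with the intra-/inter-sentence breakdown, and the
# ablation harness.

#' Classify a concept pair as intra- or inter-sentence
#'
#' A pair is intra-sentence iff some single sentence contains at least one
#' mention of the chemical concept and one of the disease concept;
#' otherwise it is inter-sentence.
#'
#' @param document an aligned `cid_document`.
#' @param chemical_id,disease_id concept identifiers present in the
#'   document.
#' @return `"intra"` or `"inter"`.
#' @export
split_intra_inter <- function(document, chemical_id, disease_id) {
  m <- document$mentions
  s_chem <- m$sentence_index[m$concept_id == chemical_id]
  s_dis <- m$sentence_index[m$concept_id == disease_id]
  if (length(s_chem) == 0L || length(s_dis) == 0L) {
    stop(sprintf("document %s: pair (%s, %s) references absent concepts",
                 document$doc_id, chemical_id, disease_id))
  }
  if (length(intersect(s_chem, s_dis)) > 0L) "intra" else "inter"
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Micro-averaged precision/recall/F1 with intra/inter breakdown
#'
#' Pair identity is at the concept level, keyed by
#' (doc_id, chemical_id, disease_id).  Every gold and predicted pair is
#' assigned to exactly one of the intra/inter partitions by
#' [split_intra_inter()], so the partition counts sum to the overall
#' counts.
#'
#' @param gold_corpus a `cid_corpus` carrying the gold relations.
#' @param predictions data frame with columns `doc_id`, `chemical_id`,
#'   `disease_id` and `label` (1 = predicted CID), as returned by
#'   [predict_relations()].
#' @return an `EvalReport` list with blocks `overall`, `intra`, `inter`,
#'   each holding precision/recall/f1/tp/fp/fn.
#' @export
evaluate_predictions <- function(gold_corpus, predictions) {
  docs <- gold_corpus$documents
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  predictions <- predictions[predictions$label == 1L, , drop = FALSE]
  unknown <- setdiff(unique(predictions$doc_id), names(docs))
  if (length(unknown) > 0L) {
    stop("predictions for unknown document(s): ",
         paste(unknown, collapse = ", "))
  }

  key <- function(doc, chem, dis) paste(doc, chem, dis, sep = "\r")
  gold_keys <- character(0); gold_kind <- character(0)
  for (d in docs) {
    if (nrow(d$relations) == 0L) next
    kk <- key(d$doc_id, d$relations$chemical_id, d$relations$disease_id)
    kindd <- vapply(seq_len(nrow(d$relations)), function(r) {
      split_intra_inter(d, d$relations$chemical_id[r], d$relations$disease_id[r])
    }, character(1))
    gold_keys <- c(gold_keys, kk); gold_kind <- c(gold_kind, kindd)
  }
  pred_keys <- character(0); pred_kind <- character(0)
  if (nrow(predictions) > 0L) {
    pred_keys <- key(predictions$doc_id, predictions$chemical_id,
                     predictions$disease_id)
    dup <- duplicated(pred_keys)
    predictions <- predictions[!dup, , drop = FALSE]
    pred_keys <- pred_keys[!dup]
    pred_kind <- vapply(seq_len(nrow(predictions)), function(r) {
      split_intra_inter(docs[[predictions$doc_id[r]]],
                        predictions$chemical_id[r], predictions$disease_id[r])
    }, character(1))
  }

  block <- function(kind) {
    g <- if (is.null(kind)) gold_keys else gold_keys[gold_kind == kind]
    p <- if (is.null(kind)) pred_keys else pred_keys[pred_kind == kind]
    prf(tp = length(intersect(p, g)),
        fp = length(setdiff(p, g)),
        fn = length(setdiff(g, p)))
  }
  structure(list(overall = block(NULL), intra = block("intra"),
                 inter = block("inter")),
            class = "cid_eval_report")
}

#' @export
print.cid_eval_report <- function(x, ...) {
  for (b in c("overall", "intra", "inter")) {
    v <- x[[b]]
    cat(sprintf("%-8s P %.4f  R %.4f  F1 %.4f  (tp %d fp %d fn %d)\n",
                b, v$precision, v$recall, v$f1, v$tp, v$fp, v$fn))
  }
  invisible(x)
}

#' Ablation harness over graph/aggregation variants
#'
#' Trains and evaluates the configured variants, each with every seed, and
#' tabulates overall/intra/inter F1.  Variants: `full` (gated GCN on the
#' document graph), `fully_connected` (all-ones adjacency),
#' `no_gating` (plain convolution stack) and `no_aggregation` (classifier
#' applied directly to the encoder entity nodes, bypassing all GCN layers).
#'
#' @param train_corpus,test_corpus `cid_corpus` objects.
#' @param vocab_tokens vocabulary for the embedding table.
#' @param variants subset of the four variant names.
#' @param seeds integer vector; one run per (variant, seed).
#' @param model_args extra arguments to [cid_model()] (dimensions, layers).
#' @param train_args extra arguments to [train_config()].
#' @param dev_corpus optional development corpus; when given, each run
#'   early-stops on dev F1 and evaluates its best checkpoint.
#' @return data frame with one row per run: variant, seed, precision,
#'   recall, f1, intra_f1, inter_f1.
#' @export
ablation_suite <- function(train_corpus, test_corpus, vocab_tokens,
                           variants = c("full", "fully_connected",
                                        "no_gating", "no_aggregation"),
                           seeds = 1L, model_args = list(),
                           train_args = list(), dev_corpus = NULL) {
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  for (variant in variants) {
    va <- switch(variant,
      full = list(),
      fully_connected = list(fully_connected = TRUE),
      no_gating = list(mode = "plain"),
      no_aggregation = list(n_layers = 0L))
    for (seed in seeds) {
      args <- utils::modifyList(model_args, va)
      args$vocab_tokens <- vocab_tokens
      args$seed <- seed
      model <- do.call(cid_model, args)
      tc <- do.call(train_config, utils::modifyList(train_args,
                                                    list(seed = seed)))
      model <- train_model(model, train_corpus, dev_corpus, config = tc)
      rep <- evaluate_predictions(test_corpus,
                                  predict_relations(model, test_corpus))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, seed = seed,
        precision = rep$overall$precision, recall = rep$overall$recall,
        f1 = rep$overall$f1, intra_f1 = rep$intra$f1,
        inter_f1 = rep$inter$f1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Depth-by-mode sweep of GCN connection mechanisms
#'
#' @param train_corpus,test_corpus `cid_corpus` objects.
#' @param vocab_tokens vocabulary for the embedding table.
#' @param modes connection mechanisms to sweep.
#' @param layers integer vector of GCN depths.
#' @param seeds integer vector; one run per (mode, depth, seed).
#' @param model_args,train_args,dev_corpus as in [ablation_suite()].
#' @return data frame: mode, n_layers, seed, f1, intra_f1, inter_f1.
#' @export
mode_depth_sweep <- function(train_corpus, test_corpus, vocab_tokens,
                             modes = c("plain", "residual", "dense", "gated"),
                             layers = c(2L, 4L, 8L), seeds = 1L,
                             model_args = list(), train_args = list(),
                             dev_corpus = NULL) {
  rows <- list()
  for (mode in modes) for (L in layers) for (seed in seeds) {
    args <- utils::modifyList(model_args,
                              list(mode = mode, n_layers = as.integer(L)))
    args$vocab_tokens <- vocab_tokens
    args$seed <- seed
    model <- do.call(cid_model, args)
    tc <- do.call(train_config, utils::modifyList(train_args,
                                                  list(seed = seed)))
    model <- train_model(model, train_corpus, dev_corpus, config = tc)
    rep <- evaluate_predictions(test_corpus,
                                predict_relations(model, test_corpus))
    rows[[length(rows) + 1L]] <- data.frame(
      mode = mode, n_layers = L, seed = seed,
      f1 = rep$overall$f1, intra_f1 = rep$intra$f1,
      inter_f1 = rep$inter$f1, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
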