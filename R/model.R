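# Full model: embeddings -> BiLSTM -> document graph -> GCN -> bilinear
# classifier, with hand-written reverse-mode gradients and an SGD loop.

#' Create a relation-extraction model
#'
#' @param vocab_tokens character vector of vocabulary tokens, or a
#'   pretrained table from [load_word_embeddings()] /
#'   [embedding_table()].
#' @param d_w word embedding dimension (default 300).
#' @param d_h one-side LSTM hidden dimension (default 300); the node hidden
#'   part, since the two directions are averaged.
#' @param d_t node-type embedding dimension (default 50).
#' @param n_layers number of GCN layers (default 4).
#' @param mode GCN connection mechanism (default `"gated"`).
#' @param leaky_slope LeakyReLU negative slope.
#' @param adjacency adjacency normalization used by the model
#'   (`"sym"` by default for training stability; `"none"` applies the
#'   convolution on the raw binary adjacency).
#' @param fully_connected replace the document graph by a fully connected
#'   one (ablation).
#' @param threshold decision threshold on p(r = 1).
#' @param train_embeddings fine-tune the embedding table during training.
#' @param seed seed for parameter initialization.
#' @return a `cid_model`.
#' @export
cid_model <- function(vocab_tokens, d_w = 300L, d_h = 300L, d_t = 50L,
                      n_layers = 4L, mode = "gated", leaky_slope = 0.01,
                      adjacency = "sym", fully_connected = FALSE,
                      threshold = 0.5, train_embeddings = TRUE, seed = 1L) {
  set.seed(seed)
  emb <- if (is.list(vocab_tokens)) vocab_tokens
         else embedding_table(vocab_tokens, d_w)
  d_w <- ncol(emb$E)
  d <- d_h + d_t
  gcfg <- gcn_config(n_layers = n_layers, mode = mode,
                     leaky_slope = leaky_slope, adjacency_mode = adjacency)
  params <- list(
    E = emb$E,
    lstm_f = init_lstm_params(d_w, d_h),
    lstm_b = init_lstm_params(d_w, d_h),
    types = init_type_embeddings(d_t),
    gcn = init_gcn_params(d, gcfg),
    W_cls = init_bilinear_params(d))
  structure(list(
    params = params,
    vocab = emb$vocab,
    config = list(d_w = d_w, d_h = d_h, d_t = d_t, d = d, gcn = gcfg,
                  fully_connected = fully_connected, threshold = threshold,
                  train_embeddings = train_embeddings, seed = seed)
  ), class = "cid_model")
}

#' @export
print.cid_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cid_model> d_w=%d d_h=%d d_t=%d | %d %s GCN layer(s), adjacency=%s | vocab %d\n",
    cfg$d_w, cfg$d_h, cfg$d_t, cfg$gcn$n_layers, cfg$gcn$mode,
    cfg$gcn$adjacency_mode, length(x$vocab)))
  invisible(x)
}

model_adjacency <- function(model, document) {
  g <- build_adjacency(document)
  if (isTRUE(model$config$fully_connected)) g <- make_fully_connected(g)
  list(graph = g,
       A = normalize_adjacency(g$A, model$config$gcn$adjacency_mode))
}

#' Precompute the parameter-independent structures of a document
#'
#' Token ids, candidate pairs, the document graph and its (normalized)
#' adjacency do not depend on model parameters; computing them once per
#' document saves substantial time across training epochs.
#'
#' @param model a `cid_model`.
#' @param document a `cid_document`.
#' @return an opaque list accepted by [forward_document()].
#' @export
prepare_document <- function(model, document) {
  adj <- model_adjacency(model, document)
  pairs <- enumerate_candidate_pairs(document)
  entity_row <- stats::setNames(
    nrow(document$mentions) + seq_len(nrow(document$concepts)),
    document$concepts$concept_id)
  list(document = document,
       ids_list = lapply(document$sentences, token_ids, vocab = model$vocab),
       pairs = pairs,
       rows_i = unname(entity_row[pairs$chemical_id]),
       rows_j = unname(entity_row[pairs$disease_id]),
       plan = node_plan(document),
       adj = adj)
}

#' Forward pass over one document
#'
#' @param model a `cid_model`.
#' @param document a `cid_document`.
#' @param prep optional precomputed structures from [prepare_document()].
#' @param keep_cache keep intermediates for backpropagation.
#' @return list with `pairs` (candidate pairs + `score` = p(r=1)), `loss`
#'   (NLL of the gold labels) and, if requested, `cache`.
#' @export
forward_document <- function(model, document, prep = NULL,
                             keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  if (is.null(prep)) prep <- prepare_document(model, document)
  pairs <- prep$pairs

  enc <- doc_bilstm_forward(p$E, prep$ids_list, p$lstm_f, p$lstm_b)
  H_list <- enc$H_list

  nodes <- build_nodes_from_plan(prep$plan, H_list, p$types)
  gout <- if (cfg$gcn$n_layers > 0L) {
    gcn_forward(nodes$V, prep$adj$A, p$gcn, cfg$gcn, keep_cache = TRUE)
  } else {
    list(V = nodes$V, cache = NULL)
  }
  V_final <- gout$V

  n_pairs <- nrow(pairs)
  probs <- vector("list", n_pairs)
  rows_i <- prep$rows_i; rows_j <- prep$rows_j
  W1 <- p$W_cls[, 1, ]; W2 <- p$W_cls[, 2, ]
  for (q in seq_len(n_pairs)) {
    e_i <- V_final[rows_i[q], ]; e_j <- V_final[rows_j[q], ]
    z <- c(drop(e_i %*% W1 %*% e_j), drop(e_i %*% W2 %*% e_j))
    probs[[q]] <- exp(z - log_sum_exp(z))
  }
  pairs$score <- vapply(probs, `[[`, numeric(1), 2L)
  loss <- if (n_pairs > 0L) document_loss(probs, pairs$label) else 0

  out <- list(pairs = pairs, loss = loss)
  if (keep_cache) {
    out$cache <- list(prep = prep, enc = enc, H_list = H_list, nodes = nodes,
                      gcn = gout$cache, V_final = V_final,
                      probs = probs, rows_i = rows_i, rows_j = rows_j)
  }
  out
}

#' Loss and analytic gradients for one document
#'
#' @param model a `cid_model`.
#' @param document a `cid_document`.
#' @param prep optional precomputed structures from [prepare_document()].
#' @return list with `loss` and `grads` (same nested shape as
#'   `model$params`).
#' @export
document_gradients <- function(model, document, prep = NULL) {
  p <- model$params
  cfg <- model$config
  fw <- forward_document(model, document, prep = prep, keep_cache = TRUE)
  ch <- fw$cache
  grads <- param_zero_like(p)

  if (nrow(fw$pairs) == 0L) return(list(loss = 0, grads = grads))
  if (!is.finite(fw$loss)) {
    stop(sprintf("non-finite loss on document %s", document$doc_id))
  }

  cls <- classifier_backward(ch$V_final, ch$rows_i, ch$rows_j, ch$probs,
                             fw$pairs$label, p$W_cls)
  grads$W_cls <- cls$dW_cls

  if (cfg$gcn$n_layers > 0L) {
    gb <- gcn_backward(cls$dV, ch$gcn, ch$prep$adj$A, p$gcn, cfg$gcn)
    grads$gcn <- gb$grads
    dV0 <- gb$dV0
  } else {
    dV0 <- cls$dV
  }

  nb <- nodes_backward_from_plan(dV0, ch$prep$plan, ch$H_list,
                                 cfg$d_h, cfg$d_t)
  grads$types$t_m <- nb$dt_m
  grads$types$t_e <- nb$dt_e
  grads$types$t_s <- nb$dt_s

  bk <- doc_bilstm_backward(nb$dH_list, ch$enc, p$lstm_f, p$lstm_b,
                            nrow(p$E))
  grads$lstm_f <- bk$grads_fwd
  grads$lstm_b <- bk$grads_bwd
  if (isTRUE(cfg$train_embeddings)) grads$E <- bk$dE
  list(loss = fw$loss, grads = grads)
}

#' Training configuration
#'
#' Values the optimizer needs: plain SGD with optional momentum, one
#' document per step, global gradient-norm clipping, and optional early
#' stopping on development F1.
#'
#' @param lr learning rate.
#' @param momentum classical momentum coefficient (0 disables).
#' @param epochs maximum number of passes over the training corpus.
#' @param clip_norm global L2 gradient clip (Inf disables).
#' @param patience early-stopping patience on dev F1 (ignored without a dev
#'   corpus).
#' @param stop_train_f1 stop early once training F1 reaches this value
#'   (1 by default; NA disables the check and the per-epoch training
#'   evaluation).
#' @param seed seed for document shuffling.
#' @param verbose print a per-epoch log line.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, epochs = 50L,
                         clip_norm = 5, patience = 10L, stop_train_f1 = 1,
                         seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1L)
  list(lr = lr, momentum = momentum, epochs = as.integer(epochs),
       clip_norm = clip_norm, patience = as.integer(patience),
       stop_train_f1 = stop_train_f1, seed = as.integer(seed),
       verbose = isTRUE(verbose))
}

#' Train a model with stochastic gradient descent
#'
#' Minimizes the summed negative log-likelihood of the gold labels over all
#' candidate pairs, one document per parameter update.  With a dev corpus
#' the checkpoint with the best dev F1 is returned (early stopping after
#' `patience` epochs without improvement); otherwise the final parameters.
#'
#' @param model a `cid_model`.
#' @param train_corpus,dev_corpus `cid_corpus` objects (`dev_corpus`
#'   optional).
#' @param config a [train_config()].
#' @return the trained model, with the training log in
#'   `attr(, "history")` (per-epoch loss and F1 columns).
#' @export
train_model <- function(model, train_corpus, dev_corpus = NULL,
                        config = train_config()) {
  docs <- train_corpus$documents
  if (length(docs) == 0L) stop("empty training corpus")
  set.seed(config$seed)
  preps <- lapply(docs, prepare_document, model = model)
  dev_preps <- if (!is.null(dev_corpus)) {
    lapply(dev_corpus$documents, prepare_document, model = model)
  }
  velocity <- param_zero_like(model$params)
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  since_best <- 0L
  history <- list()

  for (epoch in seq_len(config$epochs)) {
    total_loss <- 0
    for (di in sample(length(docs))) {
      gr <- document_gradients(model, docs[[di]], prep = preps[[di]])
      if (!is.finite(gr$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, doc %s",
                     epoch, docs[[di]]$doc_id))
      }
      total_loss <- total_loss + gr$loss
      gnorm <- sqrt(param_sq_norm(gr$grads))
      scale <- if (is.finite(config$clip_norm) && gnorm > config$clip_norm) {
        config$clip_norm / gnorm
      } else 1
      velocity <- param_map(function(v, g) config$momentum * v -
                              config$lr * scale * g,
                            velocity, gr$grads)
      model$params <- param_add(model$params, velocity)
    }

    train_f1 <- NA_real_
    if (!is.na(config$stop_train_f1)) {
      train_f1 <- quick_f1(model, train_corpus, preps)
    }
    dev_f1 <- NA_real_
    if (!is.null(dev_corpus)) {
      dev_f1 <- quick_f1(model, dev_corpus, dev_preps)
      if (dev_f1 > best$f1) {
        best <- list(f1 = dev_f1, params = model$params, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, loss = total_loss,
                                   train_f1 = train_f1, dev_f1 = dev_f1)
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %10.4f  train F1 %.3f  dev F1 %.3f",
                      epoch, total_loss, train_f1, dev_f1))
    }
    if (!is.na(train_f1) && !is.na(config$stop_train_f1) &&
        train_f1 >= config$stop_train_f1) break
    if (!is.null(dev_corpus) && since_best >= config$patience) break
  }
  if (!is.null(dev_corpus) && is.finite(best$f1)) {
    model$params <- best$params
  }
  attr(model, "history") <- do.call(rbind, history)
  model
}

quick_f1 <- function(model, corpus, preps = NULL) {
  pred <- predict_relations(model, corpus, preps = preps)
  evaluate_predictions(corpus, pred)$overall$f1
}

#' Predict scored relations for every candidate pair
#'
#' @param model a trained `cid_model`.
#' @param corpus a `cid_corpus`.
#' @param threshold decision threshold on p(r = 1); defaults to the model
#'   configuration.  A pair is predicted positive iff score > threshold
#'   (strict).
#' @param preps optional list of precomputed structures (one per document).
#' @return data frame `doc_id`, `chemical_id`, `disease_id`, `score`,
#'   `label` (predicted 0/1), ranked by descending score.
#' @export
predict_relations <- function(model, corpus, threshold = NULL, preps = NULL) {
  if (is.null(threshold)) threshold <- model$config$threshold
  out <- lapply(seq_along(corpus$documents), function(k) {
    d <- corpus$documents[[k]]
    fw <- forward_document(model, d,
                           prep = if (is.null(preps)) NULL else preps[[k]])
    if (nrow(fw$pairs) == 0L) return(NULL)
    data.frame(doc_id = d$doc_id,
               chemical_id = fw$pairs$chemical_id,
               disease_id = fw$pairs$disease_id,
               score = fw$pairs$score,
               label = as.integer(fw$pairs$score > threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(doc_id = character(0), chemical_id = character(0),
                      disease_id = character(0), score = numeric(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' The archive stores all parameters, the vocabulary and the configuration;
#' a reloaded model produces bitwise-identical predictions.
#'
#' @param model a `cid_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cid_model"))
  m
}
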