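# LSTM recurrence, bidirectional averaging, and node construction.

zero_lstm <- function(d_w, d_h) {
  p <- init_lstm_params(d_w, d_h)
  param_map(function(x) x * 0, p)
}

scalar_lstm <- function(w = 1) {
  p <- zero_lstm(1L, 1L)
  for (g in c("i", "f", "o", "c")) {
    p[[paste0("W_", g)]][] <- w
    p[[paste0("U_", g)]][] <- w
  }
  p
}

test_that("zero parameters give zero hidden and cell states", {
  p <- zero_lstm(3L, 4L)
  st <- lstm_step(c(1, -2, 3), rep(0, 4), rep(0, 4), p)
  expect_equal(st$h, rep(0, 4))
  expect_equal(st$C, rep(0, 4))
  # and over a sequence
  H <- bilstm_encode(matrix(rnorm(12), 4, 3), p, p)
  expect_equal(H, matrix(0, 4, 4))
})

test_that("the scalar step matches hand arithmetic", {
  p <- scalar_lstm(1)
  st <- lstm_step(1, 0, 0, p)
  s1 <- 1 / (1 + exp(-1))
  C_exp <- s1 * tanh(1)
  h_exp <- s1 * tanh(C_exp)
  expect_equal(st$C, C_exp, tolerance = 1e-10)
  expect_equal(st$h, h_exp, tolerance = 1e-10)
})

test_that("gate activations always lie strictly inside (0, 1)", {
  set.seed(5)
  p <- init_lstm_params(3L, 4L)
  for (rep in 1:20) {
    x <- rnorm(3, sd = 3); h <- rnorm(4); C <- rnorm(4)
    i <- sigmoid(drop(x %*% p$W_i + h %*% p$U_i) + p$b_i)
    f <- sigmoid(drop(x %*% p$W_f + h %*% p$U_f) + p$b_f)
    o <- sigmoid(drop(x %*% p$W_o + h %*% p$U_o) + p$b_o)
    expect_true(all(c(i, f, o) > 0 & c(i, f, o) < 1))
  }
})

test_that("scalar three-step sequence matches an unrolled oracle", {
  p <- scalar_lstm(0.7)
  x <- c(0.5, -1, 2)
  # independent unrolled recurrence
  step <- function(x, h, C) {
    i <- sigmoid(0.7 * x + 0.7 * h); f <- i; o <- i
    g <- tanh(0.7 * x + 0.7 * h)
    C2 <- i * g + f * C
    list(h = o * tanh(C2), C = C2)
  }
  run <- function(xs) {
    h <- 0; C <- 0; out <- numeric(length(xs))
    for (t in seq_along(xs)) {
      st <- step(xs[t], h, C); h <- st$h; C <- st$C; out[t] <- h
    }
    out
  }
  fwd <- run(x); bwd <- rev(run(rev(x)))
  H <- bilstm_encode(matrix(x, 3, 1), p, p)
  expect_equal(drop(H), (fwd + bwd) / 2, tolerance = 1e-10)
})

test_that("identical direction parameters on a palindrome give a symmetric encoding", {
  set.seed(8)
  p <- init_lstm_params(2L, 3L)
  X <- matrix(rnorm(6), 3, 2)
  X[3, ] <- X[1, ]  # palindromic sequence
  H <- bilstm_encode(X, p, p)
  expect_equal(H, H[3:1, ], tolerance = 1e-12)
})

test_that("the batched document encoder equals the per-sentence encoder", {
  corp <- generate_corpus(synth_config(n_docs = 4, seed = 19))
  m <- tiny_model(corp, seed = 3)
  for (d in corp$documents) {
    ids_list <- lapply(d$sentences, token_ids, vocab = m$vocab)
    enc <- doc_bilstm_forward(m$params$E, ids_list,
                              m$params$lstm_f, m$params$lstm_b)
    ref <- lapply(ids_list, function(ids) {
      bilstm_encode(m$params$E[ids, , drop = FALSE],
                    m$params$lstm_f, m$params$lstm_b)
    })
    expect_equal(enc$H_list, ref, tolerance = 1e-12)
  }
})

test_that("empty sentences are rejected", {
  p <- init_lstm_params(2L, 3L)
  expect_error(bilstm_encode(matrix(numeric(0), 0, 2), p, p), "empty")
})

test_that("node construction averages correctly on the tiny fixture", {
  d <- tiny_corpus()$documents[[1]]
  d_h <- 2L
  set.seed(4)
  H_list <- lapply(d$sentences, function(s) matrix(rnorm(length(s) * d_h),
                                                   length(s), d_h))
  types <- list(t_m = c(1, 0, 0), t_e = c(0, 1, 0), t_s = c(0, 0, 1))
  ns <- build_nodes(d, H_list, types)
  # 3 mentions + 2 entities + 2 sentences = 7 nodes of dim 2 + 3
  expect_equal(dim(ns$V), c(7, 5))
  # single-token mention rows equal the token's H row exactly
  for (j in 1:3) {
    s <- d$mentions$sentence_index[j]; t <- d$mentions$tok_start[j]
    expect_equal(ns$V[j, 1:2], H_list[[s]][t, ])
    expect_equal(ns$V[j, 3:5], types$t_m)
  }
  # entity rows: hand-computed mention averages
  for (k in 1:2) {
    idx <- d$concepts$mention_idx[[k]]
    expect_equal(ns$V[3 + k, 1:2], colMeans(ns$V[idx, 1:2, drop = FALSE]))
    expect_equal(ns$V[3 + k, 3:5], types$t_e)
  }
  # sentence rows: mean over all token vectors
  for (s in 1:2) {
    expect_equal(ns$V[5 + s, 1:2], colMeans(H_list[[s]]))
    expect_equal(ns$V[5 + s, 3:5], types$t_s)
  }
})

test_that("an entity with two identical mentions equals either mention", {
  d <- tiny_corpus()$documents[[1]]
  H_list <- list(matrix(1:6 / 10, 3, 2), matrix(rep(c(0.5, 0.25), each = 4),
                                                4, 2))
  # force both mentions of the chemical concept to identical H rows
  H_list[[2]][1, ] <- H_list[[1]][1, ]
  types <- init_type_embeddings(3L)
  ns <- build_nodes(d, H_list, types)
  chem <- which(d$concepts$etype == "Chemical")
  idx <- d$concepts$mention_idx[[chem]]
  expect_equal(ns$V[3 + chem, 1:2], ns$V[idx[1], 1:2])
})

test_that("embedding lookup is lowercase-first with UNK fallback", {
  tab <- embedding_table(c("aspirin", "Fever"), d_w = 4)
  ids <- token_ids(c("Aspirin", "aspirin", "Fever", "unknownword"), tab$vocab)
  expect_equal(ids[1], ids[2])
  expect_equal(ids[3], unname(tab$vocab[["Fever"]]))
  expect_equal(ids[4], unname(tab$vocab[["<unk>"]]))
})

test_that("pretrained embeddings load from word2vec text format", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("3 4",
               "aspirin 0.1 0.2 0.3 0.4",
               "fever -1 0 1 2",
               "dog 0 0 0 1"), tmp)
  tab <- load_word_embeddings(tmp, d_w = 4)
  expect_equal(unname(tab$E[tab$vocab[["fever"]], ]), c(-1, 0, 1, 2))
  expect_true("<unk>" %in% names(tab$vocab))
  expect_error(load_word_embeddings(tmp, d_w = 5), "dimension")
})
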