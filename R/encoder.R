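# Sentence encoder: LSTM recurrence, bidirectional averaging, and
# construction of mention/entity/sentence node representations.
#
# Conventions: token vectors are rows; a sentence is an n x d_w matrix X.
# Gate parameters follow the standard LSTM form
#   i = sigmoid(x W_i + h U_i + b_i), f, o alike; candidate
#   c~ = tanh(x W_c + h U_c + b_c);  C = i*c~ + f*C_prev;  h = o*tanh(C),
# with h_0 = C_0 = 0.  The bidirectional output is the average (not the
# concatenation) of the forward and re-reversed backward hidden states, so
# the contextual dimension stays d_h.

#' Initialize one direction of LSTM parameters
#'
#' @param d_w input (word embedding) dimension.
#' @param d_h hidden dimension (default 300).
#' @return list of weight matrices `W_*` (d_w x d_h), recurrent maps `U_*`
#'   (d_h x d_h) and biases `b_*` for gates i, f, o and candidate c.
#' @export
init_lstm_params <- function(d_w, d_h = 300L) {
  p <- list()
  for (g in c("i", "f", "o", "c")) {
    p[[paste0("W_", g)]] <- init_matrix(d_w, d_h, fan_in = d_w)
    p[[paste0("U_", g)]] <- init_matrix(d_h, d_h, fan_in = d_h)
    p[[paste0("b_", g)]] <- numeric(d_h)
  }
  p$b_f[] <- 1  # open forget gate at init, the usual LSTM trick
  p
}

#' One LSTM time step
#'
#' @param x_t input vector (length d_w).
#' @param h_prev,C_prev previous hidden and cell state (length d_h).
#' @param params parameters from [init_lstm_params()].
#' @return list with `h` and `C`.
#' @export
lstm_step <- function(x_t, h_prev, C_prev, params) {
  if (any(!is.finite(x_t))) stop("non-finite LSTM input")
  x_t <- matrix(x_t, 1); h_prev <- matrix(h_prev, 1)
  i <- sigmoid(x_t %*% params$W_i + h_prev %*% params$U_i + params$b_i)
  f <- sigmoid(x_t %*% params$W_f + h_prev %*% params$U_f + params$b_f)
  o <- sigmoid(x_t %*% params$W_o + h_prev %*% params$U_o + params$b_o)
  g <- tanh(x_t %*% params$W_c + h_prev %*% params$U_c + params$b_c)
  C <- drop(i * g + f * C_prev)
  list(h = drop(o * tanh(C)), C = C)
}

# Full unidirectional pass with cached intermediates for backpropagation.
lstm_forward <- function(X, params) {
  n <- nrow(X); d_h <- ncol(params$U_i)
  XWi <- X %*% params$W_i; XWf <- X %*% params$W_f
  XWo <- X %*% params$W_o; XWc <- X %*% params$W_c
  H <- matrix(0, n, d_h); Cs <- matrix(0, n, d_h)
  I <- matrix(0, n, d_h); F_ <- matrix(0, n, d_h)
  O <- matrix(0, n, d_h); G <- matrix(0, n, d_h)
  h <- matrix(0, 1, d_h); C <- rep(0, d_h)
  for (t in seq_len(n)) {
    i <- sigmoid(XWi[t, ] + h %*% params$U_i + params$b_i)
    f <- sigmoid(XWf[t, ] + h %*% params$U_f + params$b_f)
    o <- sigmoid(XWo[t, ] + h %*% params$U_o + params$b_o)
    g <- tanh(XWc[t, ] + h %*% params$U_c + params$b_c)
    C <- drop(i * g + f * C)
    h <- o * tanh(C)
    I[t, ] <- i; F_[t, ] <- f; O[t, ] <- o; G[t, ] <- g
    Cs[t, ] <- C; H[t, ] <- h
  }
  list(H = H, cache = list(X = X, I = I, F = F_, O = O, G = G, Cs = Cs))
}

# Reverse-mode pass; dH is the gradient on the hidden outputs.
lstm_backward <- function(dH, fwd, params) {
  cache <- fwd$cache
  X <- cache$X; n <- nrow(X); d_h <- ncol(dH)
  grads <- param_zero_like(params)
  dX <- matrix(0, nrow(X), ncol(X))
  dh_next <- rep(0, d_h); dC_next <- rep(0, d_h)
  for (t in rev(seq_len(n))) {
    i <- cache$I[t, ]; f <- cache$F[t, ]; o <- cache$O[t, ]; g <- cache$G[t, ]
    C <- cache$Cs[t, ]; tC <- tanh(C)
    C_prev <- if (t > 1L) cache$Cs[t - 1L, ] else rep(0, d_h)
    h_prev <- if (t > 1L) fwd$H[t - 1L, ] else rep(0, d_h)
    dh <- dH[t, ] + dh_next
    dC <- dC_next + dh * o * (1 - tC^2)
    do_a <- (dh * tC) * o * (1 - o)
    di_a <- (dC * g) * i * (1 - i)
    df_a <- (dC * C_prev) * f * (1 - f)
    dg_a <- (dC * i) * (1 - g^2)
    dC_next <- dC * f
    x <- X[t, ]
    grads$W_i <- grads$W_i + outer(x, di_a)
    grads$W_f <- grads$W_f + outer(x, df_a)
    grads$W_o <- grads$W_o + outer(x, do_a)
    grads$W_c <- grads$W_c + outer(x, dg_a)
    grads$U_i <- grads$U_i + outer(h_prev, di_a)
    grads$U_f <- grads$U_f + outer(h_prev, df_a)
    grads$U_o <- grads$U_o + outer(h_prev, do_a)
    grads$U_c <- grads$U_c + outer(h_prev, dg_a)
    grads$b_i <- grads$b_i + di_a
    grads$b_f <- grads$b_f + df_a
    grads$b_o <- grads$b_o + do_a
    grads$b_c <- grads$b_c + dg_a
    dX[t, ] <- di_a %*% t(params$W_i) + df_a %*% t(params$W_f) +
               do_a %*% t(params$W_o) + dg_a %*% t(params$W_c)
    dh_next <- drop(di_a %*% t(params$U_i) + df_a %*% t(params$U_f) +
                    do_a %*% t(params$U_o) + dg_a %*% t(params$U_c))
  }
  list(dX = dX, grads = grads)
}

#' Encode a sentence with a bidirectional LSTM
#'
#' The backward pass runs on the reversed sequence and is re-reversed; the
#' contextual representation of each token is the average of the two
#' directions, so the output dimension equals `d_h`.
#'
#' @param X n x d_w matrix of token embeddings (n >= 1).
#' @param params_fwd,params_bwd independent parameter sets from
#'   [init_lstm_params()].
#' @return n x d_h matrix `H`.
#' @export
bilstm_encode <- function(X, params_fwd, params_bwd) {
  bilstm_forward(X, params_fwd, params_bwd)$H
}

bilstm_forward <- function(X, params_fwd, params_bwd) {
  if (!is.matrix(X) || nrow(X) == 0L) stop("cannot encode an empty sentence")
  n <- nrow(X)
  fw <- lstm_forward(X, params_fwd)
  bw <- lstm_forward(X[rev(seq_len(n)), , drop = FALSE], params_bwd)
  H <- (fw$H + bw$H[rev(seq_len(n)), , drop = FALSE]) / 2
  list(H = H, fw = fw, bw = bw)
}

bilstm_backward <- function(dH, enc, params_fwd, params_bwd) {
  n <- nrow(dH)
  rev_idx <- rev(seq_len(n))
  bf <- lstm_backward(dH / 2, enc$fw, params_fwd)
  bb <- lstm_backward(dH[rev_idx, , drop = FALSE] / 2, enc$bw, params_bwd)
  list(dX = bf$dX + bb$dX[rev_idx, , drop = FALSE],
       grads_fwd = bf$grads, grads_bwd = bb$grads)
}

#' Initialize the three node-type embeddings
#'
#' @param d_t node-type embedding dimension (default 50).
#' @return list with vectors `t_m`, `t_e`, `t_s`.
#' @export
init_type_embeddings <- function(d_t = 50L) {
  list(t_m = stats::runif(d_t, -0.1, 0.1),
       t_e = stats::runif(d_t, -0.1, 0.1),
       t_s = stats::runif(d_t, -0.1, 0.1))
}

#' Build mention, entity and sentence node representations
#'
#' Mention nodes average the contextual vectors of the tokens in the mention
#' span; entity nodes average the hidden parts of their mentions; sentence
#' nodes average all token vectors of the sentence.  Each node row is the
#' hidden part with the node-type embedding appended, so all rows share the
#' dimension `d_h + d_t` required by the shared convolution filter.
#'
#' @param document a `cid_document`.
#' @param H_list list of per-sentence contextual matrices (from
#'   [bilstm_encode()]).
#' @param type_embeddings from [init_type_embeddings()].
#' @return a node set: `V` ((N+R+T) x (d_h+d_t)), `kinds`, and row maps
#'   `mention_row`, `entity_row` (named by concept id), `sentence_row`.
#' @export
build_nodes <- function(document, H_list, type_embeddings) {
  build_nodes_from_plan(node_plan(document), H_list, type_embeddings)
}

# Static averaging structure of a document (plain vectors, computed once).
node_plan <- function(document) {
  if (any(vapply(document$concepts$mention_idx, length, integer(1)) == 0L)) {
    stop("concept without mentions")
  }
  list(N = nrow(document$mentions),
       R = nrow(document$concepts),
       T_ = length(document$sentences),
       m_sent = document$mentions$sentence_index,
       m_tok = lapply(seq_len(nrow(document$mentions)), function(j) {
         seq(document$mentions$tok_start[j], document$mentions$tok_end[j])
       }),
       concept_idx = document$concepts$mention_idx,
       concept_ids = document$concepts$concept_id)
}

build_nodes_from_plan <- function(plan, H_list, type_embeddings) {
  N <- plan$N; R <- plan$R; T_ <- plan$T_
  stopifnot(length(H_list) == T_)
  d_h <- ncol(H_list[[1]])
  d_t <- length(type_embeddings$t_m)

  M_hidden <- matrix(0, N, d_h)
  for (j in seq_len(N)) {
    rows <- plan$m_tok[[j]]
    H <- H_list[[plan$m_sent[j]]]
    M_hidden[j, ] <- if (length(rows) == 1L) H[rows, ]
                     else colMeans(H[rows, , drop = FALSE])
  }
  E_hidden <- matrix(0, R, d_h)
  for (j in seq_len(R)) {
    idx <- plan$concept_idx[[j]]
    E_hidden[j, ] <- if (length(idx) == 1L) M_hidden[idx, ]
                     else colMeans(M_hidden[idx, , drop = FALSE])
  }
  S_hidden <- t(vapply(H_list, colMeans, numeric(d_h)))

  V <- rbind(
    cbind(M_hidden, matrix(type_embeddings$t_m, N, d_t, byrow = TRUE)),
    cbind(E_hidden, matrix(type_embeddings$t_e, R, d_t, byrow = TRUE)),
    cbind(S_hidden, matrix(type_embeddings$t_s, T_, d_t, byrow = TRUE)))

  list(V = V,
       kinds = c(rep("mention", N), rep("entity", R), rep("sentence", T_)),
       n_mention = N, n_entity = R, n_sentence = T_,
       mention_row = seq_len(N),
       entity_row = stats::setNames(N + seq_len(R), plan$concept_ids),
       sentence_row = N + R + seq_len(T_))
}

# Distribute node-level gradients back onto the contextual matrices and the
# type embeddings.
nodes_backward <- function(dV, document, H_list, d_h, d_t) {
  nodes_backward_from_plan(dV, node_plan(document), H_list, d_h, d_t)
}

nodes_backward_from_plan <- function(dV, plan, H_list, d_h, d_t) {
  N <- plan$N; R <- plan$R; T_ <- plan$T_
  hid <- seq_len(d_h); typ <- d_h + seq_len(d_t)

  dM_hidden <- dV[seq_len(N), hid, drop = FALSE]
  for (j in seq_len(R)) {
    idx <- plan$concept_idx[[j]]
    share <- dV[N + j, hid] / length(idx)
    dM_hidden[idx, ] <- dM_hidden[idx, , drop = FALSE] +
      matrix(share, length(idx), d_h, byrow = TRUE)
  }
  dH_list <- lapply(H_list, function(H) {
    n <- nrow(H)
    matrix(0, n, d_h)
  })
  for (j in seq_len(N)) {
    rows <- plan$m_tok[[j]]
    s <- plan$m_sent[j]
    share <- dM_hidden[j, ] / length(rows)
    dH_list[[s]][rows, ] <- dH_list[[s]][rows, , drop = FALSE] +
      matrix(share, length(rows), d_h, byrow = TRUE)
  }
  for (s in seq_len(T_)) {
    n <- nrow(H_list[[s]])
    dH_list[[s]] <- dH_list[[s]] +
      matrix(dV[N + R + s, hid] / n, n, d_h, byrow = TRUE)
  }
  list(dH_list = dH_list,
       dt_m = colSums(dV[seq_len(N), typ, drop = FALSE]),
       dt_e = colSums(dV[N + seq_len(R), typ, drop = FALSE]),
       dt_s = colSums(dV[N + R + seq_len(T_), typ, drop = FALSE]))
}
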