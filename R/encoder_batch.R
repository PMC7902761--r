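# Batched document encoder.
#
# All sentences of a document run through the LSTM together: sequences are
# padded to the longest sentence and a mask turns padded steps into
# identity updates, so the per-step work is a handful of (T x d) matrix
# products instead of one tiny product per token.  Numerically identical to
# the per-sentence recurrence in encoder.R (cross-checked in the tests).

combine_lstm_params <- function(p) {
  list(W = cbind(p$W_i, p$W_f, p$W_o, p$W_c),
       U = cbind(p$U_i, p$U_f, p$U_o, p$U_c),
       b = c(p$b_i, p$b_f, p$b_o, p$b_c))
}

split_gate_cols <- function(M, d_h) {
  list(i = M[, seq_len(d_h), drop = FALSE],
       f = M[, d_h + seq_len(d_h), drop = FALSE],
       o = M[, 2L * d_h + seq_len(d_h), drop = FALSE],
       g = M[, 3L * d_h + seq_len(d_h), drop = FALSE])
}

# seqs: list of integer id vectors (already reversed for the backward
# direction).  Returns hidden states per step plus caches.
batch_lstm_forward <- function(E, seqs, params) {
  cp <- combine_lstm_params(params)
  B <- length(seqs); lens <- lengths(seqs); L <- max(lens)
  d_h <- ncol(params$U_i)
  idx <- matrix(1L, B, L)
  for (b in seq_len(B)) idx[b, seq_len(lens[b])] <- seqs[[b]]
  mask <- outer(seq_len(B), seq_len(L), function(b, t) as.numeric(t <= lens[b]))
  Xflat <- E[as.vector(idx), , drop = FALSE]        # (B*L) x d_w, col-major
  XWflat <- Xflat %*% cp$W
  bias <- matrix(cp$b, B, 4L * d_h, byrow = TRUE)
  H_prev <- matrix(0, B, d_h); C_prev <- matrix(0, B, d_h)
  Hs <- vector("list", L); Cs <- vector("list", L)
  Is <- vector("list", L); Fs <- vector("list", L)
  Os <- vector("list", L); Gs <- vector("list", L)
  for (t in seq_len(L)) {
    rows <- (t - 1L) * B + seq_len(B)
    S <- XWflat[rows, , drop = FALSE] + H_prev %*% cp$U + bias
    gt <- split_gate_cols(S, d_h)
    i <- sigmoid(gt$i); f <- sigmoid(gt$f); o <- sigmoid(gt$o); g <- tanh(gt$g)
    C_new <- i * g + f * C_prev
    h_new <- o * tanh(C_new)
    m <- mask[, t]
    C <- m * C_new + (1 - m) * C_prev
    H <- m * h_new + (1 - m) * H_prev
    Is[[t]] <- i; Fs[[t]] <- f; Os[[t]] <- o; Gs[[t]] <- g
    Cs[[t]] <- C; Hs[[t]] <- H
    H_prev <- H; C_prev <- C
  }
  list(Hs = Hs, cache = list(idx = idx, mask = mask, lens = lens,
                             Xflat = Xflat, Is = Is, Fs = Fs, Os = Os,
                             Gs = Gs, Cs = Cs, Hs = Hs, B = B, L = L))
}

# dHs: list over steps of B x d_h gradients on the (post-mask) hidden states.
batch_lstm_backward <- function(dHs, cache, params, n_embed_rows) {
  cp <- combine_lstm_params(params)
  B <- cache$B; L <- cache$L
  d_h <- ncol(params$U_i)
  dh_next <- matrix(0, B, d_h); dC_next <- matrix(0, B, d_h)
  dGflat <- matrix(0, B * L, 4L * d_h)
  dU <- matrix(0, d_h, 4L * d_h)
  db <- numeric(4L * d_h)
  for (t in rev(seq_len(L))) {
    m <- cache$mask[, t]
    dh <- dHs[[t]] + dh_next
    dC <- dC_next
    H_prev <- if (t > 1L) cache$Hs[[t - 1L]] else matrix(0, B, d_h)
    C_prev <- if (t > 1L) cache$Cs[[t - 1L]] else matrix(0, B, d_h)
    i <- cache$Is[[t]]; f <- cache$Fs[[t]]; o <- cache$Os[[t]]
    g <- cache$Gs[[t]]; tC <- tanh(cache$Cs[[t]])
    dh_new <- dh * m
    dC_new <- dC * m + dh_new * o * (1 - tC^2)
    do_a <- (dh_new * tC) * o * (1 - o)
    di_a <- (dC_new * g) * i * (1 - i)
    df_a <- (dC_new * C_prev) * f * (1 - f)
    dg_a <- (dC_new * i) * (1 - g^2)
    dG <- cbind(di_a, df_a, do_a, dg_a)
    rows <- (t - 1L) * B + seq_len(B)
    dGflat[rows, ] <- dG
    dU <- dU + crossprod(H_prev, dG)
    db <- db + colSums(dG)
    dh_next <- dh * (1 - m) + dG %*% t(cp$U)
    dC_next <- dC * (1 - m) + dC_new * f
  }
  dW <- crossprod(cache$Xflat, dGflat)
  dXflat <- dGflat %*% t(cp$W)
  dE_rows <- rowsum(dXflat, group = as.vector(cache$idx))
  dE <- matrix(0, n_embed_rows, ncol(cache$Xflat))
  dE[as.integer(rownames(dE_rows)), ] <- dE_rows
  sl <- function(M, k) M[, (k - 1L) * d_h + seq_len(d_h), drop = FALSE]
  grads <- list(W_i = sl(dW, 1), U_i = sl(dU, 1), b_i = db[seq_len(d_h)],
                W_f = sl(dW, 2), U_f = sl(dU, 2), b_f = db[d_h + seq_len(d_h)],
                W_o = sl(dW, 3), U_o = sl(dU, 3), b_o = db[2 * d_h + seq_len(d_h)],
                W_c = sl(dW, 4), U_c = sl(dU, 4), b_c = db[3 * d_h + seq_len(d_h)])
  grads <- grads[c("W_i", "U_i", "b_i", "W_f", "U_f", "b_f",
                   "W_o", "U_o", "b_o", "W_c", "U_c", "b_c")]
  list(grads = grads, dE = dE)
}

# Whole-document bidirectional encoding; returns per-sentence H matrices.
doc_bilstm_forward <- function(E, ids_list, params_fwd, params_bwd) {
  fw <- batch_lstm_forward(E, ids_list, params_fwd)
  bw <- batch_lstm_forward(E, lapply(ids_list, rev), params_bwd)
  lens <- lengths(ids_list)
  d_h <- ncol(fw$Hs[[1]])
  Hf_cat <- do.call(cbind, fw$Hs)   # B x (d_h * L), step-major
  Hb_cat <- do.call(cbind, bw$Hs)
  H_list <- lapply(seq_along(ids_list), function(b) {
    n <- lens[b]
    Hf <- matrix(Hf_cat[b, seq_len(n * d_h)], n, d_h, byrow = TRUE)
    Hb <- matrix(Hb_cat[b, seq_len(n * d_h)], n, d_h, byrow = TRUE)
    (Hf + Hb[rev(seq_len(n)), , drop = FALSE]) / 2
  })
  list(H_list = H_list, fw = fw, bw = bw, lens = lens)
}

doc_bilstm_backward <- function(dH_list, enc, params_fwd, params_bwd,
                                n_embed_rows) {
  lens <- enc$lens
  B <- length(dH_list)
  d_h <- ncol(dH_list[[1]])
  L <- max(lens)
  dHf_cat <- matrix(0, B, d_h * L)
  dHb_cat <- matrix(0, B, d_h * L)
  for (b in seq_len(B)) {
    n <- lens[b]
    dHf_cat[b, seq_len(n * d_h)] <- as.vector(t(dH_list[[b]])) / 2
    dHb_cat[b, seq_len(n * d_h)] <-
      as.vector(t(dH_list[[b]][rev(seq_len(n)), , drop = FALSE])) / 2
  }
  cols <- function(t) (t - 1L) * d_h + seq_len(d_h)
  dHf <- lapply(seq_len(L), function(t) dHf_cat[, cols(t), drop = FALSE])
  dHb <- lapply(seq_len(L), function(t) dHb_cat[, cols(t), drop = FALSE])
  bf <- batch_lstm_backward(dHf, enc$fw$cache, params_fwd, n_embed_rows)
  bb <- batch_lstm_backward(dHb, enc$bw$cache, params_bwd, n_embed_rows)
  list(grads_fwd = bf$grads, grads_bwd = bb$grads, dE = bf$dE + bb$dE)
}
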