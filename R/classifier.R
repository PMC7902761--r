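# Bilinear pair classifier and document-level negative log-likelihood.
#
# For a chemical entity vector e_i and disease entity vector e_j the label
# logits are z_r = e_i' W_cls[, r, ] e_j for r in {0, 1}; the predicted
# distribution is softmax(z).  The chemical is always the left argument.

#' Initialize the bilinear classifier tensor
#'
#' @param d entity vector dimension.
#' @param k number of labels (2: no-relation / CID).
#' @return d x k x d array.
#' @export
init_bilinear_params <- function(d, k = 2L) {
  array(stats::runif(d * k * d, -1 / sqrt(d), 1 / sqrt(d)), dim = c(d, k, d))
}

pair_logits <- function(e_i, e_j, W_cls) {
  k <- dim(W_cls)[2]
  vapply(seq_len(k), function(r) {
    drop(e_i %*% W_cls[, r, ] %*% e_j)
  }, numeric(1))
}

#' Score one chemical-disease entity pair
#'
#' @param e_i final chemical entity-node vector (length d).
#' @param e_j final disease entity-node vector (length d).
#' @param W_cls bilinear tensor from [init_bilinear_params()].
#' @return probability vector of length k (softmax over the bilinear
#'   logits); components positive, summing to 1.
#' @export
score_pair <- function(e_i, e_j, W_cls) {
  if (length(e_i) != dim(W_cls)[1] || length(e_j) != dim(W_cls)[3]) {
    stop("entity vector / classifier dimension mismatch")
  }
  z <- pair_logits(e_i, e_j, W_cls)
  p <- exp(z - log_sum_exp(z))
  p / sum(p)
}

#' Negative log-likelihood of gold labels under predicted distributions
#'
#' @param probs list (or matrix rows) of probability vectors, one per
#'   candidate pair.
#' @param gold integer vector of gold labels (0/1).
#' @return total NLL, a non-negative scalar.
#' @export
document_loss <- function(probs, gold) {
  if (is.matrix(probs)) probs <- split(probs, row(probs))
  stopifnot(length(probs) == length(gold))
  -sum(vapply(seq_along(gold), function(q) {
    log(max(probs[[q]][gold[q] + 1L], .Machine$double.xmin))
  }, numeric(1)))
}

# Backward pass for a set of pairs of one document.
# rows_i/rows_j index the entity rows in V; returns dV and dW_cls.
classifier_backward <- function(V, rows_i, rows_j, probs, gold, W_cls) {
  d <- dim(W_cls)[1]; k <- dim(W_cls)[2]
  dV <- matrix(0, nrow(V), ncol(V))
  dW <- array(0, dim = dim(W_cls))
  for (q in seq_along(gold)) {
    e_i <- V[rows_i[q], ]; e_j <- V[rows_j[q], ]
    dz <- probs[[q]]
    dz[gold[q] + 1L] <- dz[gold[q] + 1L] - 1
    for (r in seq_len(k)) {
      if (dz[r] == 0) next
      dW[, r, ] <- dW[, r, ] + dz[r] * outer(e_i, e_j)
      dV[rows_i[q], ] <- dV[rows_i[q], ] + dz[r] * drop(W_cls[, r, ] %*% e_j)
      dV[rows_j[q], ] <- dV[rows_j[q], ] + dz[r] * drop(e_i %*% W_cls[, r, ])
    }
  }
  list(dV = dV, dW_cls = dW)
}
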