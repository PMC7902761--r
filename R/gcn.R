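# Graph convolution layers with four connection mechanisms.
#
#   plain    : V_{l+1} = leakyrelu(A V_l W_l)
#   residual : V_{l+1} = leakyrelu(A V_l W_l) + V_l
#   dense    : all layer outputs [V_0; V_1; ...; V_L] are concatenated and
#              projected back to d by a learned linear map
#   gated    : g = sigmoid(V_raw W_g + V_l U_g + b_g),
#              V_{l+1} = V_raw * g + V_l * (1 - g)
#
# The gate interpolates coordinatewise between the convolution output and
# the previous representation, preserving node-specific information across
# depth and thereby mitigating over-smoothing.

#' GCN stack configuration
#'
#' @param n_layers number of convolution layers (default 4).
#' @param mode connection mechanism: `"gated"` (default), `"plain"`,
#'   `"residual"` or `"dense"`.
#' @param leaky_slope negative slope of the LeakyReLU activation.
#' @param adjacency_mode normalization handed to [normalize_adjacency()].
#' @return a `gcn_config` list.
#' @export
gcn_config <- function(n_layers = 4L,
                       mode = c("gated", "plain", "residual", "dense"),
                       leaky_slope = 0.01,
                       adjacency_mode = "none") {
  mode <- match.arg(mode)
  stopifnot(n_layers >= 0L)
  list(n_layers = as.integer(n_layers), mode = mode,
       leaky_slope = leaky_slope, adjacency_mode = adjacency_mode)
}

#' Initialize per-layer GCN parameters
#'
#' Every layer gets its own convolution filter `W` (d x d); in gated mode
#' also gate parameters `W_g`, `U_g` (d x d) and bias `b_g` (d, zero so the
#' gate starts balanced at 0.5); in dense mode a shared `(L+1)d x d`
#' projection restores the classifier dimension.
#'
#' @param d node dimension.
#' @param config a [gcn_config()].
#' @return list with `layers` (per-layer parameter lists) and optional `proj`.
#' @export
init_gcn_params <- function(d, config = gcn_config()) {
  # Convolution filters are Glorot-uniform (unit gain): with contractive
  # filters a deep stack shrinks activations and gradients geometrically
  # and neither plain nor gated stacks can train at depth.
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  layers <- lapply(seq_len(config$n_layers), function(l) {
    p <- list(W = glorot(d, d))
    if (config$mode == "gated") {
      p$W_g <- init_matrix(d, d, fan_in = d)
      p$U_g <- init_matrix(d, d, fan_in = d)
      p$b_g <- numeric(d)
    }
    p
  })
  out <- list(layers = layers)
  if (config$mode == "dense") {
    out$proj <- glorot((config$n_layers + 1L) * d, d)
  }
  out
}

#' One graph convolution
#'
#' @param V n x d node matrix.
#' @param A n x n (possibly normalized) adjacency.
#' @param W d x d convolution filter.
#' @param slope LeakyReLU negative slope.
#' @return activation of `A V W`; row i equals the activated sum over the
#'   neighbours selected by row i of `A` (self included).
#' @export
gcn_layer <- function(V, A, W, slope = 0.01) {
  stopifnot(ncol(A) == nrow(V), ncol(V) == nrow(W))
  leaky_relu(A %*% V %*% W, slope)
}

#' Gated interpolation between convolution output and previous layer
#'
#' @param V_raw convolution output (n x d).
#' @param V_prev previous node representations (n x d).
#' @param W_g,U_g,b_g gate parameters.
#' @return `V_raw * g + V_prev * (1 - g)` with
#'   `g = sigmoid(V_raw W_g + V_prev U_g + b_g)`; every output coordinate
#'   lies between the corresponding coordinates of `V_raw` and `V_prev`.
#' @export
gated_update <- function(V_raw, V_prev, W_g, U_g, b_g) {
  stopifnot(all(dim(V_raw) == dim(V_prev)))
  g <- sigmoid(sweep(V_raw %*% W_g + V_prev %*% U_g, 2, b_g, `+`))
  V_raw * g + V_prev * (1 - g)
}

#' Run the GCN stack
#'
#' @param V0 initial node matrix (n x d).
#' @param A adjacency (already normalized per the configuration).
#' @param params from [init_gcn_params()].
#' @param config a [gcn_config()].
#' @param keep_cache keep intermediates for backpropagation.
#' @return final n x d node matrix, or a list with `V` and `cache`.
#' @export
gcn_forward <- function(V0, A, params, config = gcn_config(),
                        keep_cache = FALSE) {
  L <- config$n_layers
  if (length(params$layers) < L) stop("insufficient per-layer parameter sets")
  slope <- config$leaky_slope
  V <- V0
  cache <- vector("list", L)
  Vs <- vector("list", L + 1L); Vs[[1]] <- V0
  for (l in seq_len(L)) {
    p <- params$layers[[l]]
    P <- A %*% V
    M <- P %*% p$W
    V_raw <- leaky_relu(M, slope)
    st <- list(V_in = V, P = P, M = M, V_raw = V_raw)
    V_next <- switch(config$mode,
      plain = V_raw,
      residual = V_raw + V,
      dense = V_raw,
      gated = {
        g <- sigmoid(sweep(V_raw %*% p$W_g + V %*% p$U_g, 2, p$b_g, `+`))
        st$g <- g
        V_raw * g + V * (1 - g)
      })
    cache[[l]] <- st
    V <- V_next
    Vs[[l + 1L]] <- V
  }
  if (config$mode == "dense") {
    C <- do.call(cbind, Vs)
    V <- C %*% params$proj
  }
  if (!keep_cache) return(V)
  list(V = V, cache = list(layers = cache, Vs = Vs))
}

gcn_backward <- function(dV_out, cache, A, params, config) {
  L <- config$n_layers
  slope <- config$leaky_slope
  tA <- t(A)
  grads <- list(layers = vector("list", L))
  dVs <- NULL
  if (config$mode == "dense") {
    C <- do.call(cbind, cache$Vs)
    grads$proj <- crossprod(C, dV_out)
    dC <- dV_out %*% t(params$proj)
    d <- ncol(cache$Vs[[1]])
    dVs <- lapply(seq_len(L + 1L), function(l) {
      dC[, (l - 1L) * d + seq_len(d), drop = FALSE]
    })
    dV <- dVs[[L + 1L]]
  } else {
    dV <- dV_out
  }
  for (l in rev(seq_len(L))) {
    st <- cache$layers[[l]]
    p <- params$layers[[l]]
    gl <- list()
    if (config$mode == "gated") {
      dg <- dV * (st$V_raw - st$V_in)
      dS <- dg * st$g * (1 - st$g)
      dV_raw <- dV * st$g + dS %*% t(p$W_g)
      dV_in_gate <- dV * (1 - st$g) + dS %*% t(p$U_g)
      gl$W_g <- crossprod(st$V_raw, dS)
      gl$U_g <- crossprod(st$V_in, dS)
      gl$b_g <- colSums(dS)
    } else if (config$mode == "residual") {
      dV_raw <- dV
      dV_in_gate <- dV
    } else {
      dV_raw <- dV
      dV_in_gate <- matrix(0, nrow(dV), ncol(dV))
    }
    dM <- dV_raw * leaky_relu_grad(st$M, slope)
    gl$W <- crossprod(st$P, dM)
    dP <- dM %*% t(p$W)
    dV <- dV_in_gate + tA %*% dP
    if (config$mode == "dense" && l > 1L) dV <- dV + dVs[[l]]
    grads$layers[[l]] <- gl[c("W", intersect(names(gl), c("W_g", "U_g", "b_g")))]
  }
  if (config$mode == "dense") dV <- dV + dVs[[1]]
  list(dV0 = dV, grads = grads)
}

#' Mean pairwise cosine similarity of node rows
#'
#' A scalar over-smoothing diagnostic: 1 when all rows are parallel, near 0
#' for mutually orthogonal rows.
#'
#' @param V node matrix with at least two rows and no zero rows.
#' @return mean cosine similarity over all unordered row pairs.
#' @export
oversmoothing_metric <- function(V) {
  stopifnot(nrow(V) >= 2L)
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) stop("zero-norm row")
  Vn <- V / nrm
  C <- tcrossprod(Vn)
  mean(C[upper.tri(C)])
}
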