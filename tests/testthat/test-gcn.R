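# Graph convolution, gating, connection mechanisms, over-smoothing.

random_graph_case <- function(n, d, seed) {
  set.seed(seed)
  A <- random_connected_adjacency(n)
  V <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(d * d, sd = 0.5), d, d)
  list(A = A, V = V, W = W)
}

# explicit per-node neighbour sum (the generalization of the per-node
# expansion of the convolution), the independent oracle
gcn_layer_bruteforce <- function(V, A, W, slope) {
  n <- nrow(V)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    acc <- rep(0, ncol(V))
    for (j in seq_len(n)) {
      if (A[i, j] != 0) acc <- acc + A[i, j] * drop(V[j, ] %*% W)
    }
    out[i, ] <- leaky_relu(acc, slope)
  }
  out
}

test_that("the matrix convolution equals the per-node neighbour sum", {
  for (k in 1:20) {
    cs <- random_graph_case(n = sample(2:12, 1), d = sample(2:6, 1),
                            seed = 100 + k)
    got <- gcn_layer(cs$V, cs$A, cs$W, slope = 0.01)
    expect_equal(got, gcn_layer_bruteforce(cs$V, cs$A, cs$W, 0.01),
                 tolerance = 1e-8)
  }
})

test_that("a zero filter collapses the convolution to zero", {
  cs <- random_graph_case(5, 3, 1)
  expect_equal(gcn_layer(cs$V, cs$A, cs$W * 0), matrix(0, 5, 3))
})

test_that("gated update is a coordinatewise interpolation", {
  set.seed(2)
  n <- 6; d <- 4
  V_raw <- matrix(rnorm(n * d), n, d)
  V_prev <- matrix(rnorm(n * d), n, d)
  W_g <- matrix(rnorm(d * d), d, d); U_g <- matrix(rnorm(d * d), d, d)

  # equal inputs are a fixed point for any gate parameters
  expect_equal(gated_update(V_prev, V_prev, W_g, U_g, rnorm(d)), V_prev)

  # zero gate parameters give the exact midpoint
  expect_equal(gated_update(V_raw, V_prev, W_g * 0, U_g * 0, rep(0, d)),
               (V_raw + V_prev) / 2)

  # saturated bias selects one side
  expect_equal(gated_update(V_raw, V_prev, W_g * 0, U_g * 0, rep(20, d)),
               V_raw, tolerance = 1e-6)
  expect_equal(gated_update(V_raw, V_prev, W_g * 0, U_g * 0, rep(-20, d)),
               V_prev, tolerance = 1e-6)

  # interpolation property with arbitrary parameters
  out <- gated_update(V_raw, V_prev, W_g, U_g, rnorm(d))
  lo <- pmin(V_raw, V_prev); hi <- pmax(V_raw, V_prev)
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
})

test_that("the stacked forward pass composes the layer definitions", {
  cs <- random_graph_case(5, 4, 7)
  cfg <- gcn_config(n_layers = 1L, mode = "gated")
  params <- init_gcn_params(4, cfg)
  got <- gcn_forward(cs$V, cs$A, params, cfg)
  p <- params$layers[[1]]
  expect_equal(got, gated_update(gcn_layer(cs$V, cs$A, p$W), cs$V,
                                 p$W_g, p$U_g, p$b_g), tolerance = 1e-12)

  # residual mode with zero filters is the identity
  cfg_r <- gcn_config(n_layers = 3L, mode = "residual")
  params_r <- init_gcn_params(4, cfg_r)
  params_r$layers <- lapply(params_r$layers,
                            function(l) list(W = l$W * 0))
  expect_equal(gcn_forward(cs$V, cs$A, params_r, cfg_r), cs$V)

  # 4-layer plain equals a hand-unrolled fourfold application
  cfg_p <- gcn_config(n_layers = 4L, mode = "plain")
  params_p <- init_gcn_params(4, cfg_p)
  V <- cs$V
  for (l in 1:4) V <- gcn_layer(V, cs$A, params_p$layers[[l]]$W, 0.01)
  expect_equal(gcn_forward(cs$V, cs$A, params_p, cfg_p), V,
               tolerance = 1e-8)

  # dense mode restores the node dimension
  cfg_d <- gcn_config(n_layers = 3L, mode = "dense")
  params_d <- init_gcn_params(4, cfg_d)
  expect_equal(dim(gcn_forward(cs$V, cs$A, params_d, cfg_d)), c(5, 4))

  expect_error(gcn_forward(cs$V, cs$A, list(layers = params_p$layers[1:2]),
                           cfg_p), "insufficient")
})

test_that("node relabelling permutes the output identically", {
  cs <- random_graph_case(7, 3, 9)
  cfg <- gcn_config(n_layers = 2L, mode = "gated")
  params <- init_gcn_params(3, cfg)
  out <- gcn_forward(cs$V, cs$A, params, cfg)
  perm <- sample(7)
  out_p <- gcn_forward(cs$V[perm, ], cs$A[perm, perm], params, cfg)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
})

test_that("the over-smoothing metric matches hand-computed cosines", {
  expect_equal(oversmoothing_metric(matrix(1, 4, 3)), 1.0)
  expect_equal(oversmoothing_metric(rbind(c(1, 0), c(0, 2))), 0.0)
  V <- rbind(c(1, 0), c(0, 1), c(1, 1))
  cos12 <- 0; cos13 <- 1 / sqrt(2); cos23 <- 1 / sqrt(2)
  expect_equal(oversmoothing_metric(V), mean(c(cos12, cos13, cos23)))
  expect_error(oversmoothing_metric(rbind(c(0, 0), c(1, 1))), "zero")
})

test_that("deep plain propagation smooths while a closed gate preserves", {
  prof_plain <- smoothing_profile(n_nodes = 10, d = 8, depth = 64,
                                  mode = "plain", seed = 1)
  expect_gte(prof_plain$metric[65], 0.999)
  prof_gated <- smoothing_profile(n_nodes = 10, d = 8, depth = 64,
                                  mode = "gated", gate_bias = -10, seed = 1)
  expect_lt(abs(prof_gated$metric[65] - prof_gated$metric[1]), 1e-3)
})
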