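#' @keywords internal
"_PACKAGE"

# ---- numeric helpers ---------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.01) {
  pmax(x, 0) + slope * pmin(x, 0)
}

# subgradient at 0 taken on the positive branch
leaky_relu_grad <- function(x, slope = 0.01) {
  g <- array(1, dim = dim(x))
  g[which(x < 0)] <- slope
  g
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# ---- independent RNG streams -------------------------------------------
# The generator draws structural decisions (counts, placements, labels) and
# lexical filler from separate streams so that structural statistics are
# invariant to vocabulary-affecting options.

new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  st <- new.env(parent = emptyenv())
  st$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  st
}

rng_with <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# ---- nested parameter containers ---------------------------------------
# Model parameters and their gradients share one nested-list shape; these
# walkers apply elementwise operations leaf by leaf.

param_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(seq_along(a), function(i) param_map(f, a[[i]]))
           else lapply(seq_along(a), function(i) param_map(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

param_zero_like <- function(p) param_map(function(x) x * 0, p)

param_add <- function(a, b) param_map(`+`, a, b)

param_scale <- function(p, s) param_map(function(x) x * s, p)

param_sq_norm <- function(p) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + sum(x^2)
    invisible(NULL)
  }
  walk(p)
  tot
}

# uniform init scaled by fan-in, the convention used throughout the model
init_matrix <- function(nrow, ncol, fan_in = nrow) {
  r <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}
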