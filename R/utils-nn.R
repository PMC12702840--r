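# Internal dense-network engine: small multilayer perceptrons with
# hand-derived gradients and Adam. All trainable components of the method
# (graph encoder, autoencoder teacher, contrastive learners, two-stage
# classifier) run on these primitives, so every training loop is
# deterministic under a caller-supplied seed.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# He-scaled initialisation for a stack of dense layers.
# dims = c(d_in, h1, ..., d_out); returns list of W (d_prev x d_next) and b.
mlp_init <- function(dims) {
  stopifnot(length(dims) >= 2)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    d_in <- dims[l]; d_out <- dims[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
      b = rep(0, d_out)
    )
  }
  layers
}

relu <- function(x) (x + abs(x)) / 2

# Forward pass; hidden layers use `activation`, output layer is linear.
# Returns the output and the per-layer inputs/preactivations for backprop.
mlp_forward <- function(layers, X, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  L <- length(layers)
  ins <- vector("list", L)
  pre <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    ins[[l]] <- H
    Z <- H %*% layers[[l]]$W
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    pre[[l]] <- Z
    H <- if (l < L && activation == "relu") relu(Z) else Z
  }
  list(out = H, ins = ins, pre = pre, activation = activation)
}

# Backprop dL/d(out) through the stack; returns per-layer grads and dL/dX.
mlp_backward <- function(layers, fwd, G) {
  L <- length(layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L && fwd$activation == "relu") G <- G * (fwd$pre[[l]] > 0)
    grads[[l]] <- list(
      W = crossprod(fwd$ins[[l]], G),
      b = colSums(G)
    )
    G <- tcrossprod(G, layers[[l]]$W)  # dL/d(input of layer l)
  }
  list(grads = grads, dX = G)
}

# Adam over an arbitrary nested list of numeric arrays.
adam_init <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else p * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# Numerically stable row-wise log-sum-exp.
row_logsumexp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# Row-wise softmax.
row_softmax <- function(M) {
  E <- exp(M - apply(M, 1, max))
  E / rowSums(E)
}

# L2-normalise rows; errors on zero-norm rows (cosine undefined).
l2_normalize_rows <- function(M, what = "embedding") {
  nrm <- sqrt(rowSums(M * M))
  if (any(nrm == 0))
    stop("zero-norm ", what, " row: cosine similarity undefined", call. = FALSE)
  M / nrm
}
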