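# Minimal dense-network engine: He-initialised layers, ReLU / softplus /
# sigmoid / linear activations, reverse-mode gradients (including gradients
# with respect to the input, needed by the expected-gradients explainer),
# and an Adam optimiser. Everything operates on row-major sample matrices
# (samples x features) so batches are single BLAS calls.

nn_act <- function(z, act) {
  switch(act,
    linear   = z,
    relu     = pmax(z, 0),
    softplus = ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
    sigmoid  = 1 / (1 + exp(-pmin(pmax(z, -30), 30))),
    stop("unknown activation: ", act)
  )
}

# derivative of the activation, expressed via pre-activation z
nn_act_grad <- function(z, act) {
  switch(act,
    linear   = array(1, dim = dim(z)),
    relu     = (z > 0) * 1,
    softplus = 1 / (1 + exp(-pmin(pmax(z, -30), 30))),
    sigmoid  = {
      s <- 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
      s * (1 - s)
    },
    stop("unknown activation: ", act)
  )
}

# layers: list of list(W = n_in x n_out, b = length n_out)
# acts:   one activation name per layer
nn_init <- function(widths, acts) {
  stopifnot(length(widths) >= 2, length(acts) == length(widths) - 1)
  layers <- vector("list", length(widths) - 1L)
  for (l in seq_along(layers)) {
    n_in <- widths[l]
    n_out <- widths[l + 1L]
    sd <- sqrt(2 / n_in)  # He; fine for the linear/softplus layers too
    layers[[l]] <- list(
      W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
      b = numeric(n_out),
      act = acts[l]
    )
  }
  layers
}

# forward pass; keep = TRUE retains pre-activations for backprop
nn_forward <- function(layers, X, keep = FALSE) {
  A <- X
  cache <- if (keep) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    Z <- A %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, "+")
    if (keep) cache[[l]] <- list(A_in = A, Z = Z)
    A <- nn_act(Z, layers[[l]]$act)
  }
  if (keep) list(out = A, cache = cache) else A
}

# reverse pass from dL/d(output activation); returns parameter grads and dL/dX
nn_backward <- function(layers, cache, d_out) {
  grads <- vector("list", length(layers))
  dA <- d_out
  for (l in rev(seq_along(layers))) {
    Z <- cache[[l]]$Z
    dZ <- dA * nn_act_grad(Z, layers[[l]]$act)
    grads[[l]] <- list(
      W = crossprod(cache[[l]]$A_in, dZ),
      b = colSums(dZ)
    )
    dA <- dZ %*% t(layers[[l]]$W)
  }
  list(grads = grads, d_input = dA)
}

# dL/dX only (no parameter grads materialised) - the hot path of the
# expected-gradients explainer
nn_input_gradient <- function(layers, X, d_out) {
  fw <- nn_forward(layers, X, keep = TRUE)
  dA <- d_out
  for (l in rev(seq_along(layers))) {
    dZ <- dA * nn_act_grad(fw$cache[[l]]$Z, layers[[l]]$act)
    dA <- dZ %*% t(layers[[l]]$W)
  }
  dA
}

nn_adam_init <- function(layers) {
  lapply(layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0,
    mb = ly$b * 0, vb = ly$b * 0
  ))
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# evaluate an expression under a local, restorable RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit sub-seed from a parent seed and a stage tag
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
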