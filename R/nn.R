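# Minimal dense neural-network machinery: He-initialized fully connected
# stacks with ReLU hidden units, manual backpropagation, and Adam. No
# deep-learning framework is available in the target environment, so the
# forward/backward passes are written out explicitly in vectorized R;
# matrices are (batch x features) and every layer is a plain W/b pair.

nn_linear_init <- function(n_in, n_out, gain = 2) {
  list(W = matrix(rnorm(n_in * n_out, 0, sqrt(gain / n_in)), n_in, n_out),
       b = numeric(n_out))
}

# Forward through hidden ReLU layers; returns activations (first = input).
mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (i in seq_along(layers)) {
    a <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1L]] <- pmax(a, 0)
  }
  acts
}

# Backward through the hidden stack. `dtop` is the gradient at the output
# of the last ReLU. Returns list(grads = per-layer list(W, b), dX).
mlp_backward <- function(layers, acts, dtop) {
  grads <- vector("list", length(layers))
  d <- dtop
  for (i in rev(seq_along(layers))) {
    d <- d * (acts[[i + 1L]] > 0)           # ReLU gate
    grads[[i]] <- list(W = crossprod(acts[[i]], d), b = colSums(d))
    d <- tcrossprod(d, layers[[i]]$W)
  }
  list(grads = grads, dX = d)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Adam optimizer state and update (PyTorch-style L2 weight decay folded
# into the gradient).
adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "replace", classes = "ANY")
}

# Flatten/apply: params and grads are arbitrarily nested lists of numeric
# arrays with identical shape.
adam_step <- function(params, grads, state, t, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.numeric(p)) {
      out_p <- p; out_s <- s
      for (k in seq_along(p)) {
        res <- walk(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- res$p; out_s[[k]] <- res$s
      }
      return(list(p = out_p, s = out_s))
    }
    g <- g + weight_decay * p
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}
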