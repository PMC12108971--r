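# Internal neural-network primitives: dense layers, batch normalization,
# activations, Adam updates, and forward/backward passes over layer stacks.
# Samples are rows; weights are (n_in x n_out) matrices.
#
# The final layer of every classifier stack is a dense layer producing one
# logit; the sigmoid is applied by the caller so the binary cross-entropy
# gradient can use the numerically stable (p - y) form.
#
# Per-column arithmetic uses column-major recycling (rep(v, each = n)) rather
# than sweep(); these paths run hundreds of thousands of times per
# leave-one-out experiment.

# add / multiply a length-k row parameter across the columns of an n x k matrix
col_add <- function(m, v) m + rep(v, each = nrow(m))
col_mul <- function(m, v) m * rep(v, each = nrow(m))

make_dense <- function(n_in, n_out) {
  # Glorot-uniform initialization; draws come from the caller's RNG stream.
  lim <- sqrt(6 / (n_in + n_out))
  list(
    type = "dense",
    W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
    b = matrix(0, 1, n_out)
  )
}

make_batchnorm <- function(d, eps = 1e-5, momentum = 0.9) {
  list(
    type = "batchnorm",
    gamma = matrix(1, 1, d), beta = matrix(0, 1, d),
    running_mean = matrix(0, 1, d), running_var = matrix(1, 1, d),
    eps = eps, momentum = momentum
  )
}

make_activation <- function(name = c("relu", "tanh", "sigmoid")) {
  list(type = "activation", fun = match.arg(name))
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      out <- col_add(x %*% layer$W, as.numeric(layer$b))
      list(out = out, cache = list(x = x), layer = layer)
    },
    batchnorm = {
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(x * x) - mu * mu # biased (mini-batch) variance
        layer$running_mean[] <- layer$momentum * layer$running_mean +
          (1 - layer$momentum) * mu
        layer$running_var[] <- layer$momentum * layer$running_var +
          (1 - layer$momentum) * v
      } else {
        mu <- as.numeric(layer$running_mean)
        v <- as.numeric(layer$running_var)
      }
      sd_inv <- 1 / sqrt(v + layer$eps)
      xc <- col_add(x, -mu)
      xhat <- col_mul(xc, sd_inv)
      out <- col_add(col_mul(xhat, as.numeric(layer$gamma)),
                     as.numeric(layer$beta))
      list(out = out,
           cache = list(xc = xc, xhat = xhat, sd_inv = sd_inv, training = training),
           layer = layer)
    },
    activation = {
      out <- switch(layer$fun,
        relu = pmax(x, 0),
        tanh = tanh(x),
        sigmoid = 1 / (1 + exp(-x))
      )
      list(out = out, cache = list(x = x, out = out), layer = layer)
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type))
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      list(
        dx = tcrossprod(dout, layer$W),
        grads = list(W = crossprod(cache$x, dout), b = matrix(colSums(dout), 1))
      )
    },
    batchnorm = {
      n <- nrow(dout)
      gamma <- as.numeric(layer$gamma)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- col_mul(dout, gamma)
      if (cache$training && n > 1L) {
        sd_inv <- cache$sd_inv
        dvar <- colSums(dxhat * cache$xc) * (-0.5) * sd_inv^3
        dmu <- colSums(col_mul(dxhat, -sd_inv)) + dvar * colMeans(-2 * cache$xc)
        dx <- col_mul(dxhat, sd_inv) +
          col_mul(cache$xc, 2 * dvar / n) +
          rep(dmu / n, each = n)
      } else {
        dx <- col_mul(dxhat, cache$sd_inv)
      }
      list(dx = dx, grads = list(gamma = matrix(dgamma, 1), beta = matrix(dbeta, 1)))
    },
    activation = {
      dx <- switch(layer$fun,
        relu = dout * (cache$x > 0),
        tanh = dout * (1 - cache$out^2),
        sigmoid = dout * cache$out * (1 - cache$out)
      )
      list(dx = dx, grads = NULL)
    }
  )
}

# Forward pass over a layer stack. Returns the output, per-layer caches, and
# the (possibly updated, for batch-norm running statistics) layers.
seq_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], x, training)
    x <- step$out
    caches[[i]] <- step$cache
    layers[[i]] <- step$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    step <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- step$dx
    grads[i] <- list(step$grads) # keep NULL slots (activation layers)
  }
  list(dx = dout, grads = grads)
}

# A hidden block: dense, optional batch norm (before the activation), then
# the nonlinearity.
hidden_block <- function(n_in, n_out, use_batch_norm, activation) {
  block <- list(make_dense(n_in, n_out))
  if (use_batch_norm) block <- c(block, list(make_batchnorm(n_out)))
  c(block, list(make_activation(activation)))
}

trainable_names <- function(layer) {
  switch(layer$type, dense = c("W", "b"), batchnorm = c("gamma", "beta"), character(0))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(layer) {
    lapply(setNames(nm = trainable_names(layer)), function(nm) {
      list(m = layer[[nm]] * 0, v = layer[[nm]] * 0)
    })
  })
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 / (1 - beta1^t)
  c2 <- 1 / (1 - beta2^t)
  for (i in seq_along(layers)) {
    for (nm in trainable_names(layers[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      layers[[i]][[nm]] <- layers[[i]][[nm]] -
        lr * (st$m * c1) / (sqrt(st$v * c2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# ---- loss ------------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
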