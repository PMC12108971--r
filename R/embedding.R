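# The categorical embedding layer: a one-hidden-layer classifier is
# pre-trained on the fracture label from the ordinal-encoded items, then its
# output nodes are stripped; the hidden activations become a dense
# representation of the 10 categorical items.

#' Configuration for embedding pre-training
#'
#' @param hidden_width Number of hidden nodes, which becomes the embedding
#'   dimensionality. Default 20, the smallest width found to give good
#'   identification on the study's categorical items.
#' @param input_representation How a vector of 10 global ordinal codes enters
#'   the pre-training network: `"scaled_ordinal"` (default) rescales each code
#'   linearly from the codebook range onto \[0, 1\]; `"one_hot"` expands the
#'   10 codes into a 30-length indicator vector with ten ones.
#' @param epochs,learning_rate,batch_size Mini-batch Adam settings for the
#'   pre-training run.
#' @param activation Hidden activation, `"relu"` (default) or `"tanh"`.
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(hidden_width = 20L,
                             input_representation = c("scaled_ordinal", "one_hot"),
                             epochs = 150L, learning_rate = 1e-3,
                             batch_size = 16L, activation = "relu",
                             seed = 1L) {
  check_scalar_number(hidden_width, "hidden_width", lo = 1)
  check_scalar_number(epochs, "epochs", lo = 1)
  check_scalar_number(learning_rate, "learning_rate", lo = 1e-12)
  check_scalar_number(batch_size, "batch_size", lo = 1)
  structure(
    list(
      hidden_width = as.integer(hidden_width),
      input_representation = match.arg(input_representation),
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      activation = activation,
      seed = as.integer(seed)
    ),
    class = "embedding_config"
  )
}

# Map an n x 10 matrix of global codes to the network input representation.
embedding_input <- function(codes, representation, code_range) {
  codes <- as.matrix(codes)
  lo <- code_range[1L]
  hi <- code_range[2L]
  if (representation == "scaled_ordinal") {
    (codes - lo) / max(hi - lo, 1)
  } else {
    n_codes <- hi - lo + 1L
    m <- matrix(0, nrow(codes), n_codes)
    for (j in seq_len(ncol(codes))) {
      m[cbind(seq_len(nrow(codes)), codes[, j] - lo + 1L)] <- 1
    }
    m
  }
}

# Mini-batch Adam over a single layer stack; caller owns the RNG state.
fit_layers <- function(layers, x, y, epochs, learning_rate, batch_size) {
  n <- nrow(x)
  state <- adam_init(layers)
  t <- 0L
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- idx[s:min(s + batch_size - 1L, n)]
      xb <- x[rows, , drop = FALSE]
      yb <- y[rows]
      fwd <- seq_forward(layers, xb, training = TRUE)
      layers <- fwd$layers
      p <- sigmoid(fwd$out[, 1L])
      ep_loss <- ep_loss + bce_loss(p, yb) * length(rows)
      dlogit <- matrix((p - yb) / length(rows), ncol = 1L)
      bwd <- seq_backward(layers, fwd$caches, dlogit)
      t <- t + 1L
      upd <- adam_update(layers, bwd$grads, state, learning_rate, t)
      layers <- upd$layers
      state <- upd$state
    }
    loss_hist[ep] <- ep_loss / n
  }
  list(layers = layers, loss = loss_hist)
}

#' Pre-train the categorical embedding layer
#'
#' Trains a one-hidden-layer network (input representation of the 10 ordinal
#' codes, `hidden_width` hidden nodes, one sigmoid output) on the binary
#' fracture label with cross-entropy loss, then removes the output nodes. The
#' surviving input-to-hidden transform is the embedding layer: it maps a
#' record's 10 global codes to a `hidden_width`-dimensional real vector.
#'
#' Pre-training is supervised by the label only; within cross-validation it
#' must be (and, in [loocv()], is) run on the training fold alone.
#'
#' @param codes Integer matrix, one row per record, one column per categorical
#'   item, entries being global ordinal codes (see [encode_categorical()]).
#' @param labels Binary vector (1 = fractured) of length `nrow(codes)`.
#' @param config An [embedding_config()].
#' @param code_range Integer vector `c(lo, hi)` of the codebook's code span;
#'   defaults to `c(1, 30)`, the default schema's span.
#' @return A list of class `embedding_layer` holding the stripped
#'   input-to-hidden weights, the input transform spec, the embedding
#'   dimensionality `output_dim`, and the pre-training record (`loss` history
#'   and final training accuracy of the un-stripped classifier).
#' @examples
#' d <- make_separable_fixture(12, seed = 7)
#' cb <- build_codebook()
#' layer <- pretrain_embedding(encode_categorical(d, cb), d$fractured,
#'                             embedding_config(epochs = 20))
#' dim(embed_codes(encode_categorical(d, cb), layer)) # 12 x 20
#' @export
pretrain_embedding <- function(codes, labels, config = embedding_config(),
                               code_range = c(1L, 30L)) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 2L) abort("Pre-training needs at least 2 records.")
  if (length(labels) != nrow(codes)) abort("`labels` length must match `codes` rows.")
  if (length(unique(labels)) < 2L) {
    abort("Pre-training needs both classes present in `labels`.")
  }
  x <- embedding_input(codes, config$input_representation, code_range)
  with_seed(config$seed, {
    layers <- c(
      list(make_dense(ncol(x), config$hidden_width),
           make_activation(config$activation)),
      list(make_dense(config$hidden_width, 1L))
    )
    fit <- fit_layers(layers, x, labels, config$epochs,
                      config$learning_rate, config$batch_size)
  })
  full <- fit$layers
  p <- sigmoid(seq_forward(full, x, training = FALSE)$out[, 1L])
  structure(
    list(
      layers = full[1:2], # output nodes stripped: dense + activation only
      input_representation = config$input_representation,
      code_range = as.integer(code_range),
      output_dim = config$hidden_width,
      n_items = ncol(codes),
      config = config,
      pretrain = list(
        layers = full,
        loss = fit$loss,
        train_accuracy = mean(as.integer(p >= 0.5) == labels)
      )
    ),
    class = "embedding_layer"
  )
}

#' Apply the embedding layer to encoded records
#'
#' Computes the hidden-layer activations of the stripped pre-training network,
#' i.e. the dense vector representation of the categorical items. Identical
#' categorical profiles map to identical embeddings; the transform is a pure
#' function of the layer weights.
#'
#' @param codes Integer matrix (or single vector) of global ordinal codes,
#'   one row per record.
#' @param layer An `embedding_layer` from [pretrain_embedding()].
#' @return A numeric matrix, `nrow(codes)` by `layer$output_dim`.
#' @export
embed_codes <- function(codes, layer) {
  stopifnot(inherits(layer, "embedding_layer"))
  if (is.vector(codes)) codes <- matrix(codes, nrow = 1L)
  codes <- as.matrix(codes)
  if (ncol(codes) != layer$n_items) {
    abort(sprintf("Expected %d categorical codes per record, got %d.",
                  layer$n_items, ncol(codes)))
  }
  if (any(codes < layer$code_range[1L] | codes > layer$code_range[2L])) {
    abort("Codes outside the codebook range.")
  }
  x <- embedding_input(codes, layer$input_representation, layer$code_range)
  seq_forward(layer$layers, x, training = FALSE)$out
}
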