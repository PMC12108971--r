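# Model specification, construction, training and prediction for the five
# architectures: plain ANN, numerical branch only (NNN), categorical branch
# only (CNN), two-way concatenation, and the three-stage fusion network
# (TSFNN) = numerical branch + categorical branch + fusion sub-network.

#' Specify a network architecture and its training settings
#'
#' The five architectures differ in which inputs they consume and how the two
#' data types meet:
#'
#' * `"ann"`: one input of width 17 -- the 7 min-max-normalized numerical
#'   items concatenated with the 10 range-scaled ordinal codes -- through a
#'   single hidden layer.
#' * `"nnn"`: numerical items only (width 7) through one hidden layer.
#' * `"cnn"`: categorical items only, either embedded (width 20) or as
#'   range-scaled ordinal codes (width 10), through one hidden layer.
#' * `"two_way"`: both branches, concatenated directly into the output node
#'   with no fusion sub-network.
#' * `"tsfnn"`: both branches feeding a fusion sub-network (hidden layer then
#'   output node). `two_way` and `tsfnn` share branch widths so the
#'   comparison between them uses a similar number of hidden nodes.
#'
#' Hidden layers are dense + optional batch normalization + activation; the
#' output node is a single sigmoid unit trained with binary cross-entropy and
#' mini-batch Adam. All randomness (initialization, shuffling, embedding
#' pre-training) derives from `seed`.
#'
#' @param architecture One of `"tsfnn"`, `"ann"`, `"nnn"`, `"cnn"`,
#'   `"two_way"`.
#' @param hidden_numerical,hidden_categorical Hidden widths of the numerical
#'   and categorical branches (defaults 16 each).
#' @param hidden_fusion Hidden width of the fusion sub-network (tsfnn only,
#'   default 16).
#' @param hidden_ann Hidden width of the plain ANN (default 32).
#' @param use_batch_norm Insert batch normalization after each hidden linear
#'   transform, before its activation (default `TRUE`).
#' @param use_embedding Use the pre-trained embedding layer for categorical
#'   inputs (cnn/two_way/tsfnn; default `TRUE`). When `FALSE`, the branch
#'   consumes the 10 range-scaled ordinal codes directly.
#' @param fine_tune_embedding Keep training the embedding weights inside the
#'   downstream network (default `FALSE`: the embedding is frozen after
#'   pre-training).
#' @param embedding An [embedding_config()] for the pre-training run; its
#'   seed is overridden by a stream derived from `seed`.
#' @param activation Hidden activation name (default `"relu"`).
#' @param epochs,learning_rate,batch_size Mini-batch Adam settings
#'   (defaults 300, 1e-3, 16).
#' @param class_weight Reweight the loss inversely to class frequency
#'   (default `FALSE`).
#' @param normalization `"standard"` or `"literal"` min-max mode (see
#'   [fit_minmax()]).
#' @param decision_threshold Probability cut for the positive class; a
#'   probability exactly equal to the threshold is classified positive.
#' @param seed Master seed for this model.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(architecture = c("tsfnn", "ann", "nnn", "cnn", "two_way"),
                       hidden_numerical = 16L, hidden_categorical = 16L,
                       hidden_fusion = 16L, hidden_ann = 32L,
                       use_batch_norm = TRUE, use_embedding = TRUE,
                       fine_tune_embedding = FALSE,
                       embedding = embedding_config(),
                       activation = "relu",
                       epochs = 300L, learning_rate = 1e-3, batch_size = 16L,
                       class_weight = FALSE,
                       normalization = c("standard", "literal"),
                       decision_threshold = 0.5, seed = 1L) {
  architecture <- match.arg(architecture)
  check_scalar_number(epochs, "epochs", lo = 1)
  check_scalar_number(learning_rate, "learning_rate", lo = 1e-12)
  check_scalar_number(batch_size, "batch_size", lo = 1)
  check_scalar_number(decision_threshold, "decision_threshold", lo = 0, hi = 1)
  check_flag(use_batch_norm, "use_batch_norm")
  check_flag(use_embedding, "use_embedding")
  check_flag(fine_tune_embedding, "fine_tune_embedding")
  structure(
    list(
      architecture = architecture,
      hidden_numerical = as.integer(hidden_numerical),
      hidden_categorical = as.integer(hidden_categorical),
      hidden_fusion = as.integer(hidden_fusion),
      hidden_ann = as.integer(hidden_ann),
      use_batch_norm = use_batch_norm,
      use_embedding = use_embedding,
      fine_tune_embedding = fine_tune_embedding,
      embedding = embedding,
      activation = activation,
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      class_weight = class_weight,
      normalization = match.arg(normalization),
      decision_threshold = decision_threshold,
      seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

# Input widths per branch for a spec under a schema.
spec_widths <- function(spec, schema) {
  n_num <- nrow(numerical_items(schema))
  n_cat <- nrow(categorical_items(schema))
  cat_width <- if (spec$use_embedding && spec$architecture %in% c("cnn", "two_way", "tsfnn")) {
    spec$embedding$hidden_width
  } else {
    n_cat
  }
  list(num = n_num, cat = cat_width, all = n_num + n_cat)
}

#' Build an untrained network from a specification
#'
#' Constructs the branch and head layer stacks for the requested architecture
#' with seeded Glorot-uniform weight initialization. The same seed always
#' yields identical initial weights.
#'
#' @param spec A [model_spec()].
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return A list of class `tsfnn_net` with elements `branches` (named list
#'   of layer stacks, each tagged with the input it consumes) and `head` (the
#'   layer stack applied to the concatenated branch outputs, ending in the
#'   one-logit output node).
#' @export
build_model <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "model_spec"))
  w <- spec_widths(spec, schema)
  bn <- spec$use_batch_norm
  act <- spec$activation
  with_seed(derive_seed(spec$seed, 1L), {
    net <- switch(spec$architecture,
      ann = list(
        branches = list(main = list(
          input = "all",
          layers = hidden_block(w$all, spec$hidden_ann, bn, act)
        )),
        head = list(make_dense(spec$hidden_ann, 1L))
      ),
      nnn = list(
        branches = list(num = list(
          input = "num",
          layers = hidden_block(w$num, spec$hidden_numerical, bn, act)
        )),
        head = list(make_dense(spec$hidden_numerical, 1L))
      ),
      cnn = list(
        branches = list(cat = list(
          input = "cat",
          layers = hidden_block(w$cat, spec$hidden_categorical, bn, act)
        )),
        head = list(make_dense(spec$hidden_categorical, 1L))
      ),
      two_way = list(
        branches = list(
          num = list(input = "num",
                     layers = hidden_block(w$num, spec$hidden_numerical, bn, act)),
          cat = list(input = "cat",
                     layers = hidden_block(w$cat, spec$hidden_categorical, bn, act))
        ),
        head = list(make_dense(spec$hidden_numerical + spec$hidden_categorical, 1L))
      ),
      tsfnn = list(
        branches = list(
          num = list(input = "num",
                     layers = hidden_block(w$num, spec$hidden_numerical, bn, act)),
          cat = list(input = "cat",
                     layers = hidden_block(w$cat, spec$hidden_categorical, bn, act))
        ),
        head = c(
          hidden_block(spec$hidden_numerical + spec$hidden_categorical,
                       spec$hidden_fusion, bn, act),
          list(make_dense(spec$hidden_fusion, 1L))
        )
      )
    )
  })
  structure(net, class = "tsfnn_net")
}

# Forward pass through branches + head. `inputs` is a named list of matrices
# keyed by the input tags the branches consume. Returns logits and caches.
net_forward <- function(net, inputs, training = FALSE) {
  bnames <- names(net$branches)
  bout <- vector("list", length(bnames))
  bcache <- vector("list", length(bnames))
  for (i in seq_along(bnames)) {
    br <- net$branches[[i]]
    fwd <- seq_forward(br$layers, inputs[[br$input]], training)
    net$branches[[i]]$layers <- fwd$layers
    bout[[i]] <- fwd$out
    bcache[[i]] <- fwd$caches
  }
  concat <- do.call(cbind, bout)
  hfwd <- seq_forward(net$head, concat, training)
  net$head <- hfwd$layers
  list(
    logit = hfwd$out[, 1L],
    net = net,
    caches = list(branches = bcache, head = hfwd$caches,
                  widths = vapply(bout, ncol, integer(1)))
  )
}

net_backward <- function(net, caches, dlogit) {
  hbwd <- seq_backward(net$head, caches$head, matrix(dlogit, ncol = 1L))
  grads <- list(head = hbwd$grads, branches = vector("list", length(net$branches)))
  offs <- cumsum(c(0L, caches$widths))
  for (i in seq_along(net$branches)) {
    dslice <- hbwd$dx[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    bbwd <- seq_backward(net$branches[[i]]$layers, caches$branches[[i]], dslice)
    grads$branches[[i]] <- bbwd$grads
  }
  grads
}

# Mini-batch Adam over the whole net; caller owns the RNG state.
fit_net <- function(net, inputs, y, spec) {
  n <- length(y)
  state <- list(
    head = adam_init(net$head),
    branches = lapply(net$branches, function(b) adam_init(b$layers))
  )
  wts <- if (isTRUE(spec$class_weight)) {
    n / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))
  } else {
    rep(1, n)
  }
  t <- 0L
  loss_hist <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- idx[s:min(s + spec$batch_size - 1L, n)]
      batch_in <- lapply(inputs, function(m) m[rows, , drop = FALSE])
      yb <- y[rows]
      fwd <- net_forward(net, batch_in, training = TRUE)
      net <- fwd$net
      p <- sigmoid(fwd$logit)
      loss <- bce_loss(p, yb)
      if (!is.finite(loss)) {
        abort(sprintf(
          "Training diverged (non-finite loss) at epoch %d; lower the learning rate.",
          ep
        ))
      }
      ep_loss <- ep_loss + loss * length(rows)
      dlogit <- wts[rows] * (p - yb) / length(rows)
      grads <- net_backward(net, fwd$caches, dlogit)
      t <- t + 1L
      hu <- adam_update(net$head, grads$head, state$head, spec$learning_rate, t)
      net$head <- hu$layers
      state$head <- hu$state
      for (i in seq_along(net$branches)) {
        bu <- adam_update(net$branches[[i]]$layers, grads$branches[[i]],
                          state$branches[[i]], spec$learning_rate, t)
        net$branches[[i]]$layers <- bu$layers
        state$branches[[i]] <- bu$state
      }
    }
    loss_hist[ep] <- ep_loss / n
  }
  list(net = net, loss = loss_hist)
}

# Assemble the named input matrices a trained or in-training model consumes.
model_inputs <- function(data, spec, params, codebook, embedding) {
  num <- normalize_numeric(data, params)
  codes <- encode_categorical(data, codebook)
  code_range <- c(1L, max(codebook$code))
  out <- list()
  if (spec$architecture == "ann") {
    scaled <- embedding_input(codes, "scaled_ordinal", code_range)
    out$all <- cbind(num, scaled)
  }
  if (spec$architecture %in% c("nnn", "two_way", "tsfnn")) out$num <- num
  if (spec$architecture %in% c("cnn", "two_way", "tsfnn")) {
    out$cat <- if (spec$use_embedding) {
      embed_codes(codes, embedding)
    } else {
      embedding_input(codes, "scaled_ordinal", code_range)
    }
  }
  out
}

#' Train a network on a record table
#'
#' Fits the full pipeline on `data` and nothing else: min-max parameters and
#' (when used) the embedding pre-training see only these records, so calling
#' this on a cross-validation training fold is leakage-free. Pre-training
#' runs first when the architecture uses the embedding layer; the complete
#' network is then trained end-to-end with the embedding frozen (default) or
#' fine-tuned.
#'
#' @param data A validated record tibble with a `fractured` column.
#' @param spec A [model_spec()].
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return A list of class `tsfnn_model` bundling the spec, preprocessing
#'   artifacts (normalization parameters, codebook, embedding layer), the
#'   trained net, and the per-epoch training-loss history. Use
#'   [predict.tsfnn_model()] to score new records, [tidy()] for the loss
#'   history and [glance()] for a one-row summary.
#' @examples
#' d <- make_separable_fixture(16, seed = 2)
#' m <- train_model(d, model_spec("nnn", epochs = 40, seed = 2))
#' glance(m)
#' @export
train_model <- function(data, spec, schema = default_schema()) {
  train_model_impl(data, spec, schema, prefit = NULL)
}

# Internal trainer; `prefit`, when non-NULL, supplies pre-fitted normalization
# parameters and/or embedding layer (the "global" preprocessing scope of
# loocv()) instead of refitting them on `data`.
train_model_impl <- function(data, spec, schema = default_schema(),
                             prefit = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  data <- validate_dataset(data, schema)
  y <- as.numeric(data$fractured)
  if (length(unique(y)) < 2L) {
    abort("Training data must contain both classes.")
  }
  params <- prefit$params %||% fit_minmax(data, schema, mode = spec$normalization)
  codebook <- build_codebook(schema)
  embedding <- prefit$embedding
  if (is.null(embedding) &&
      spec$use_embedding && spec$architecture %in% c("cnn", "two_way", "tsfnn")) {
    codes <- encode_categorical(data, codebook)
    emb_cfg <- spec$embedding
    emb_cfg$seed <- derive_seed(spec$seed, 2L)
    embedding <- pretrain_embedding(codes, y, emb_cfg,
                                    code_range = c(1L, max(codebook$code)))
  }
  net <- build_model(spec, schema)
  if (!is.null(embedding) && isTRUE(spec$fine_tune_embedding)) {
    # Splice the pre-trained input-to-hidden transform in as trainable layers;
    # the categorical branch then consumes the raw scaled codes.
    net$branches$cat$layers <- c(embedding$layers, net$branches$cat$layers)
    net$branches$cat$input <- "cat_raw"
  }
  inputs <- model_inputs(data, spec, params, codebook, embedding)
  if (!is.null(embedding) && isTRUE(spec$fine_tune_embedding)) {
    codes <- encode_categorical(data, codebook)
    inputs$cat_raw <- embedding_input(codes, embedding$input_representation,
                                      embedding$code_range)
  }
  fit <- with_seed(derive_seed(spec$seed, 3L), fit_net(net, inputs, y, spec))
  structure(
    list(
      spec = spec,
      schema = schema,
      params = params,
      codebook = codebook,
      embedding = embedding,
      net = fit$net,
      loss = fit$loss,
      n_train = nrow(data),
      class_counts = c(positive = sum(y == 1), negative = sum(y == 0))
    ),
    class = "tsfnn_model"
  )
}

#' Predict fracture probability and class for new records
#'
#' A pure function of the trained model and the records: preprocessing uses
#' the stored fit-time artifacts, batch normalization uses its running
#' statistics, and the class rule is positive iff the probability is greater
#' than or equal to the decision threshold.
#'
#' @param object A `tsfnn_model` from [train_model()].
#' @param newdata A record tibble (the `fractured` column, if present, is
#'   ignored for scoring).
#' @param ... Unused.
#' @return A tibble with columns `.prob` (probability of fracture, in
#'   \[0, 1\]) and `.pred` (0/1 class).
#' @export
predict.tsfnn_model <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  if (!"fractured" %in% names(newdata)) newdata$fractured <- 0L
  newdata <- validate_dataset(newdata, object$schema)
  spec <- object$spec
  inputs <- model_inputs(newdata, spec, object$params, object$codebook,
                         object$embedding)
  if (!is.null(object$embedding) && isTRUE(spec$fine_tune_embedding)) {
    codes <- encode_categorical(newdata, object$codebook)
    inputs$cat_raw <- embedding_input(codes, object$embedding$input_representation,
                                      object$embedding$code_range)
    inputs$cat <- NULL
  }
  p <- sigmoid(net_forward(object$net, inputs, training = FALSE)$logit)
  tibble(.prob = p, .pred = as.integer(p >= spec$decision_threshold))
}

#' @export
print.tsfnn_model <- function(x, ...) {
  cat(sprintf(
    "<tsfnn_model> architecture=%s, trained on %d records (%d+/%d-)\n",
    x$spec$architecture, x$n_train, x$class_counts[["positive"]],
    x$class_counts[["negative"]]
  ))
  cat(sprintf("  batch_norm=%s, embedding=%s, epochs=%d, final loss=%.4f\n",
              x$spec$use_batch_norm,
              x$spec$use_embedding && x$spec$architecture %in% c("cnn", "two_way", "tsfnn"),
              x$spec$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' Tidy the training history of a fitted network
#'
#' @param x A `tsfnn_model`.
#' @param ... Unused.
#' @return A tibble with columns `epoch` and `loss` (mean training binary
#'   cross-entropy per epoch).
#' @method tidy tsfnn_model
#' @export
tidy.tsfnn_model <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' One-row summary of a fitted network
#'
#' @param x A `tsfnn_model`.
#' @param ... Unused.
#' @return A tibble with the architecture, flags, training size, epoch count
#'   and final training loss.
#' @method glance tsfnn_model
#' @export
glance.tsfnn_model <- function(x, ...) {
  tibble(
    architecture = x$spec$architecture,
    use_batch_norm = x$spec$use_batch_norm,
    use_embedding = x$spec$use_embedding &&
      x$spec$architecture %in% c("cnn", "two_way", "tsfnn"),
    n_train = x$n_train,
    epochs = x$spec$epochs,
    final_loss = x$loss[length(x$loss)]
  )
}
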