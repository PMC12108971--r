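# Model persistence: a trained model serializes to one versioned JSON file
# bundling network weights with its preprocessing artifacts (normalization
# parameters, codebook, embedding layer), so train and predict can run in
# separate sessions.

MODEL_FILE_VERSION <- 1L

enc_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
dec_mat <- function(o) matrix(as.numeric(o$data), o$dim[[1]], o$dim[[2]])

enc_layers <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      dense = list(type = "dense", W = enc_mat(l$W), b = enc_mat(l$b)),
      batchnorm = list(
        type = "batchnorm", gamma = enc_mat(l$gamma), beta = enc_mat(l$beta),
        running_mean = enc_mat(l$running_mean), running_var = enc_mat(l$running_var),
        eps = l$eps, momentum = l$momentum
      ),
      activation = list(type = "activation", fun = l$fun)
    )
  })
}

dec_layers <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      dense = list(type = "dense", W = dec_mat(l$W), b = dec_mat(l$b)),
      batchnorm = list(
        type = "batchnorm", gamma = dec_mat(l$gamma), beta = dec_mat(l$beta),
        running_mean = dec_mat(l$running_mean), running_var = dec_mat(l$running_var),
        eps = l$eps, momentum = l$momentum
      ),
      activation = list(type = "activation", fun = l$fun)
    )
  })
}

#' Save or load a trained model
#'
#' @param model A `tsfnn_model` from [train_model()].
#' @param path Path of the JSON model file.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns a
#'   `tsfnn_model` whose predictions are identical to the original's.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tsfnn_model"))
  sch <- model$schema
  obj <- list(
    format = "tsfnn_model",
    version = MODEL_FILE_VERSION,
    spec = unclass_spec(model$spec),
    schema = purrr::pmap(sch, function(item_id, name, column, kind, options, lo, hi) {
      list(item_id = item_id, name = name, column = column, kind = kind,
           options = as.list(options), lo = lo, hi = hi)
    }),
    params = list(mode = attr(model$params, "mode"),
                  table = as.data.frame(model$params)),
    codebook = as.data.frame(model$codebook),
    embedding = if (!is.null(model$embedding)) {
      e <- model$embedding
      list(
        layers = enc_layers(e$layers),
        input_representation = e$input_representation,
        code_range = e$code_range,
        output_dim = e$output_dim,
        n_items = e$n_items,
        config = unclass(e$config),
        pretrain = list(loss = e$pretrain$loss,
                        train_accuracy = e$pretrain$train_accuracy)
      )
    },
    net = list(
      branches = lapply(model$net$branches, function(b) {
        list(input = b$input, layers = enc_layers(b$layers))
      }),
      head = enc_layers(model$net$head)
    ),
    loss = model$loss,
    n_train = model$n_train,
    class_counts = as.list(model$class_counts)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

unclass_spec <- function(spec) {
  s <- unclass(spec)
  s$embedding <- unclass(s$embedding)
  s
}

reclass_spec <- function(s) {
  s$embedding <- structure(s$embedding, class = "embedding_config")
  int_fields <- c("hidden_numerical", "hidden_categorical", "hidden_fusion",
                  "hidden_ann", "epochs", "batch_size", "seed")
  for (f in int_fields) s[[f]] <- as.integer(s[[f]])
  structure(s, class = "model_spec")
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "tsfnn_model")) {
    abort(sprintf("'%s' is not a model file.", path))
  }
  if (obj$version > MODEL_FILE_VERSION) {
    abort(sprintf("Model file version %s is newer than this package supports.",
                  obj$version))
  }
  sch <- purrr::map_dfr(obj$schema, function(it) {
    tibble(
      item_id = as.integer(it$item_id), name = it$name, column = it$column,
      kind = it$kind, options = list(as.character(unlist(it$options))),
      lo = as.numeric(it$lo %||% NA_real_), hi = as.numeric(it$hi %||% NA_real_)
    )
  })
  params_tb <- as_tibble(purrr::map_dfr(obj$params$table, as_tibble))
  cb_tb <- purrr::map_dfr(obj$codebook, as_tibble)
  cb_tb$item_id <- as.integer(cb_tb$item_id)
  cb_tb$code <- as.integer(cb_tb$code)
  embedding <- NULL
  if (!is.null(obj$embedding)) {
    e <- obj$embedding
    embedding <- structure(
      list(
        layers = dec_layers(e$layers),
        input_representation = e$input_representation,
        code_range = as.integer(unlist(e$code_range)),
        output_dim = as.integer(e$output_dim),
        n_items = as.integer(e$n_items),
        config = structure(e$config, class = "embedding_config"),
        pretrain = list(loss = as.numeric(unlist(e$pretrain$loss)),
                        train_accuracy = e$pretrain$train_accuracy)
      ),
      class = "embedding_layer"
    )
  }
  structure(
    list(
      spec = reclass_spec(obj$spec),
      schema = new_schema(sch),
      params = structure(params_tb, mode = obj$params$mode,
                         class = c("minmax_params", class(tibble()))),
      codebook = structure(cb_tb, class = c("ordinal_codebook", class(tibble()))),
      embedding = embedding,
      net = structure(
        list(
          branches = lapply(obj$net$branches, function(b) {
            list(input = b$input, layers = dec_layers(b$layers))
          }),
          head = dec_layers(obj$net$head)
        ),
        class = "tsfnn_net"
      ),
      loss = as.numeric(unlist(obj$loss)),
      n_train = as.integer(obj$n_train),
      class_counts = unlist(obj$class_counts)
    ),
    class = "tsfnn_model"
  )
}
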