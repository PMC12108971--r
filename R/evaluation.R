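# Leave-one-out cross-validation, confusion counting, and the four pooled
# metrics (accuracy, precision, recall, F1), plus the multi-architecture
# comparison runner.

#' Confusion counts for binary predictions
#'
#' Fractured teeth are the positive class: TP counts positives predicted
#' positive, FN positives predicted negative, FP negatives predicted
#' positive, TN negatives predicted negative.
#'
#' @param predictions Binary 0/1 vector of predicted classes.
#' @param labels Binary 0/1 vector of true classes, same length.
#' @return A one-row tibble of class `confusion_counts` with columns `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length.")
  }
  if (!all(predictions %in% c(0, 1)) || !all(labels %in% c(0, 1))) {
    abort("`predictions` and `labels` must be 0/1.")
  }
  out <- tibble(
    tp = sum(predictions == 1 & labels == 1),
    fp = sum(predictions == 1 & labels == 0),
    fn = sum(predictions == 0 & labels == 1),
    tn = sum(predictions == 0 & labels == 0)
  )
  structure(out, class = c("confusion_counts", class(tibble())))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + FP + TN + FN); Precision = TP / (TP + FP);
#' Recall = TP / (TP + FN); F1 = 2 / (1/Precision + 1/Recall), the harmonic
#' mean. A metric whose denominator is zero (e.g. precision when nothing is
#' predicted positive) is returned as `NA`, never silently 0.
#'
#' @param counts A `confusion_counts` row (or anything with `tp`, `fp`, `fn`,
#'   `tn` columns summing to a positive total).
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @examples
#' classification_metrics(confusion(c(1, 1, 0, 1), c(1, 0, 0, 1)))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  total <- tp + fp + fn + tn
  if (length(total) != 1L || is.na(total) || total <= 0) {
    abort("Confusion counts must sum to a positive total.")
  }
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble(
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = f1
  )
}

#' Leave-one-out cross-validation of one architecture
#'
#' For each record i, the entire pipeline -- min-max parameters, embedding
#' pre-training (when used) and network training -- is refitted on all other
#' records, and record i is scored once. With n records this trains n models
#' on n - 1 records each. The n single predictions are pooled into one
#' confusion matrix from which the four metrics are computed once; for
#' accuracy this pooling equals the average of the n per-fold 0/1 accuracies
#' exactly, and it is the only well-defined aggregation for precision,
#' recall and F1 when every fold holds a single test sample.
#'
#' Each fold's seed is derived deterministically from the spec's master seed
#' and the fold index, so the whole run is reproducible. A training fold
#' degenerating to a single class is skipped with a warning and reported in
#' the effective fold count.
#'
#' @param data A validated record tibble (n >= 3, both classes present).
#' @param spec A [model_spec()].
#' @param schema A schema tibble; defaults to [default_schema()].
#' @param preprocess_scope `"fold"` (default) refits normalization and
#'   embedding inside every fold; `"global"` fits them once on all records
#'   before the loop (a variant that leaks the held-out record's values into
#'   preprocessing, provided for comparison).
#' @param progress Print a dot every 10 folds.
#' @return A list of class `loocv_result`: `folds` (tibble of fold index,
#'   true label, predicted label, probability), pooled `counts` and
#'   `metrics`, the `spec`, and fold accounting.
#' @export
loocv <- function(data, spec, schema = default_schema(),
                  preprocess_scope = c("fold", "global"),
                  progress = FALSE) {
  preprocess_scope <- match.arg(preprocess_scope)
  data <- validate_dataset(data, schema)
  n <- nrow(data)
  if (n < 3L) abort("Leave-one-out needs at least 3 records.")
  if (length(unique(data$fractured)) < 2L) {
    abort("Leave-one-out needs both classes present.")
  }
  prefit <- NULL
  if (preprocess_scope == "global") {
    params <- fit_minmax(data, schema, mode = spec$normalization)
    embedding <- NULL
    if (spec$use_embedding && spec$architecture %in% c("cnn", "two_way", "tsfnn")) {
      cb <- build_codebook(schema)
      cfg <- spec$embedding
      cfg$seed <- derive_seed(spec$seed, 2L)
      embedding <- pretrain_embedding(encode_categorical(data, cb),
                                      as.numeric(data$fractured), cfg,
                                      code_range = c(1L, max(cb$code)))
    }
    prefit <- list(params = params, embedding = embedding)
  }
  fold_rows <- vector("list", n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    train_data <- data[-i, , drop = FALSE]
    if (length(unique(train_data$fractured)) < 2L) {
      warn(sprintf("Fold %d skipped: training records are single-class.", i))
      skipped <- c(skipped, i)
      next
    }
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, 100L + i)
    model <- train_model_impl(train_data, fold_spec, schema, prefit = prefit)
    pr <- predict(model, data[i, , drop = FALSE])
    fold_rows[[i]] <- tibble(
      fold = i,
      truth = as.integer(data$fractured[i]),
      estimate = pr$.pred,
      prob = pr$.prob
    )
    if (progress && i %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  folds <- bind_rows(fold_rows)
  counts <- confusion(folds$estimate, folds$truth)
  structure(
    list(
      folds = folds,
      counts = counts,
      metrics = classification_metrics(counts),
      spec = spec,
      n = n,
      n_folds = n - length(skipped),
      skipped = skipped,
      train_size = n - 1L,
      preprocess_scope = preprocess_scope
    ),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s: %d folds (train size %d each)\n",
              x$spec$architecture, x$n_folds, x$train_size))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
              m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

#' Per-fold predictions of a leave-one-out run
#'
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @return A tibble with one row per evaluated fold: `fold`, `truth`,
#'   `estimate`, `prob`.
#' @method tidy loocv_result
#' @export
tidy.loocv_result <- function(x, ...) x$folds

#' One-row summary of a leave-one-out run
#'
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @return A tibble with architecture, flags, fold accounting, pooled
#'   confusion counts and the four pooled metrics.
#' @method glance loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      architecture = x$spec$architecture,
      use_batch_norm = x$spec$use_batch_norm,
      use_embedding = x$spec$use_embedding &&
        x$spec$architecture %in% c("cnn", "two_way", "tsfnn"),
      n = x$n,
      n_folds = x$n_folds,
      train_size = x$train_size
    ),
    as_tibble(x$counts),
    x$metrics
  )
}

#' Compare architectures under leave-one-out cross-validation
#'
#' Runs [loocv()] once per specification and assembles a comparison table:
#' one metrics row per model followed, for each consecutive pair, by an
#' improvement row (later minus earlier), mirroring the ablation-table layout
#' used to report batch-normalization, embedding and fusion effects.
#'
#' @param data A validated record tibble.
#' @param specs A list of [model_spec()] objects (at least 2).
#' @param names Optional character labels, one per spec; defaults to the
#'   architecture names (made unique).
#' @param schema A schema tibble; defaults to [default_schema()].
#' @param progress Passed to [loocv()].
#' @return A tibble of class `model_comparison` with columns `model`, `row`
#'   (`"model"` or `"improvement"`), `accuracy`, `precision`, `recall`, `f1`.
#'   The full `loocv_result` objects and a per-model seed manifest are
#'   attached as attributes `results` and `manifest`.
#' @export
compare_models <- function(data, specs, names = NULL,
                           schema = default_schema(), progress = FALSE) {
  if (!is.list(specs) || length(specs) < 2L) {
    abort("`specs` must be a list of at least two model_spec objects.")
  }
  if (is.null(names)) {
    names <- make.unique(vapply(specs, function(s) s$architecture, character(1)))
  }
  results <- lapply(specs, function(s) loocv(data, s, schema, progress = progress))
  model_rows <- purrr::map2_dfr(results, names, function(r, nm) {
    dplyr::bind_cols(tibble(model = nm, row = "model"), r$metrics)
  })
  improvement_rows <- purrr::map_dfr(seq_len(length(results) - 1L), function(i) {
    a <- results[[i]]$metrics
    b <- results[[i + 1L]]$metrics
    tibble(
      model = sprintf("improvement (%s - %s)", names[i + 1L], names[i]),
      row = "improvement",
      accuracy = b$accuracy - a$accuracy,
      precision = b$precision - a$precision,
      recall = b$recall - a$recall,
      f1 = b$f1 - a$f1
    )
  })
  out <- bind_rows(model_rows, improvement_rows)
  attr(out, "results") <- setNames(results, names)
  attr(out, "manifest") <- tibble(
    model = names,
    architecture = vapply(specs, function(s) s$architecture, character(1)),
    seed = vapply(specs, function(s) s$seed, integer(1)),
    epochs = vapply(specs, function(s) s$epochs, integer(1))
  )
  structure(out, class = c("model_comparison", class(tibble())))
}

#' Write a comparison report to disk
#'
#' Emits the comparison table as CSV together with a JSON metrics file that
#' carries the per-model pooled confusion counts, metrics and the seed
#' manifest, so a run is fully reconstructable.
#'
#' @param comparison A `model_comparison` from [compare_models()].
#' @param path Output stem; `<path>.csv` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "model_comparison"))
  readr::write_csv(as_tibble(comparison), paste0(path, ".csv"), progress = FALSE)
  results <- attr(comparison, "results")
  obj <- list(
    manifest = as.data.frame(attr(comparison, "manifest")),
    models = lapply(results, function(r) {
      list(counts = as.list(as.data.frame(r$counts)),
           metrics = as.list(as.data.frame(r$metrics)),
           n_folds = r$n_folds, train_size = r$train_size)
    })
  )
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
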