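# Independent oracles used across tests: deliberately naive implementations
# that never share code with the package's own paths.

# Confusion counting by explicit enumeration of the four outcome cells,
# one pair at a time.
brute_force_confusion <- function(pred, truth) {
  cells <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (i in seq_along(pred)) {
    cell <- if (truth[i] == 1 && pred[i] == 1) "tp"
    else if (truth[i] == 0 && pred[i] == 1) "fp"
    else if (truth[i] == 1 && pred[i] == 0) "fn"
    else "tn"
    cells[cell] <- cells[cell] + 1L
  }
  cells
}

# The four metric formulas coded directly from their definitions.
independent_metrics <- function(tp, fp, fn, tn) {
  acc <- (tp + tn) / (tp + fp + tn + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec > 0 && rec > 0) {
    2 / (1 / prec + 1 / rec)
  } else if (!is.na(prec) && !is.na(rec)) {
    NA_real_
  } else {
    NA_real_
  }
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

# A fast spec for tests that exercise training without needing convergence.
quick_spec <- function(architecture = "tsfnn", epochs = 10L, seed = 1L, ...) {
  model_spec(architecture,
    epochs = epochs, seed = seed,
    embedding = embedding_config(epochs = 10L),
    ...
  )
}

# Small mixed-signal dataset for smoke tests.
tiny_dataset <- function(n_pos = 14L, n_neg = 7L, seed = 11L) {
  generate_dataset(synthetic_spec(n_positive = n_pos, n_negative = n_neg, seed = seed))
}
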