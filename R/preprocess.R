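# Front ends of the two branches: min-max normalization for the 7 numerical
# items and global ordinal encoding for the 10 categorical items.

#' Fit min-max normalization parameters
#'
#' Records, per numerical item, the minimum and maximum observed in `data`
#' (and only in `data`, so fold-local fitting inside cross-validation is
#' leakage-free). Two application modes exist:
#'
#' * `"standard"` (default): `y = (x - min) / (max - min)`, mapping the fitted
#'   range onto \[0, 1\].
#' * `"literal"`: `y = x / (max - min)`, dividing by the range without
#'   centring. This range-scaling variant coincides with `"standard"` only
#'   when `min = 0`, and differs from it by the constant `min / (max - min)`
#'   otherwise, so it does not in general land in \[0, 1\].
#'
#' Items whose observed range is degenerate (`max == min`) are flagged and
#' normalize to 0 in both modes, so a constant training fold never aborts a
#' cross-validation run.
#'
#' @param data A record tibble (see [validate_dataset()]).
#' @param schema A schema tibble; defaults to [default_schema()].
#' @param items Optional integer vector of item ids to fit; defaults to all
#'   numerical items.
#' @param mode `"standard"` or `"literal"` (see above).
#' @return A tibble of class `minmax_params` with columns `item_id`, `column`,
#'   `min`, `max`, `degenerate`, and the mode stored as an attribute.
#' @examples
#' d <- make_separable_fixture(8, seed = 1)
#' p <- fit_minmax(d)
#' apply_minmax(c(30, 50), "age", p)
#' @export
fit_minmax <- function(data, schema = default_schema(), items = NULL,
                       mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("Cannot fit normalization on an empty dataset.")
  num <- numerical_items(schema)
  if (!is.null(items)) num <- num[num$item_id %in% items, , drop = FALSE]
  if (nrow(num) == 0L) abort("No numerical items selected.")
  missing_cols <- setdiff(num$column, names(data))
  if (length(missing_cols)) {
    abort(paste0("Data lacks numerical column(s): ", paste(missing_cols, collapse = ", ")))
  }
  params <- tibble(
    item_id = num$item_id,
    column = num$column,
    min = unname(vapply(num$column, function(cl) min(data[[cl]]), numeric(1))),
    max = unname(vapply(num$column, function(cl) max(data[[cl]]), numeric(1)))
  )
  params$degenerate <- params$max == params$min
  structure(params, mode = mode,
            class = c("minmax_params", class(tibble())))
}

#' Apply min-max normalization to values of one item
#'
#' In `"standard"` mode, values inside the fitted range map to \[0, 1\] and
#' values outside it are clamped to \[0, 1\] (out-of-range values arise when
#' parameters fitted on a training fold meet a held-out record). In
#' `"literal"` mode the value is divided by the fitted range with no centring
#' and no clamping. Degenerate items map to 0.
#'
#' @param x Numeric vector of raw values.
#' @param item Item id (integer) or column key (character).
#' @param params A `minmax_params` object from [fit_minmax()].
#' @return Numeric vector of normalized values.
#' @export
apply_minmax <- function(x, item, params) {
  stopifnot(inherits(params, "minmax_params"))
  row <- if (is.character(item)) which(params$column == item) else which(params$item_id == item)
  if (length(row) != 1L) {
    abort(sprintf("No fitted normalization parameters for item '%s'.", as.character(item)))
  }
  if (params$degenerate[row]) {
    return(rep(0, length(x)))
  }
  rng <- params$max[row] - params$min[row]
  if (attr(params, "mode") == "literal") {
    x / rng
  } else {
    pmin(pmax((x - params$min[row]) / rng, 0), 1)
  }
}

# All numerical items of a record table as an n x 7 normalized matrix.
normalize_numeric <- function(data, params) {
  stopifnot(inherits(params, "minmax_params"))
  cols <- params$column
  m <- vapply(seq_along(cols),
              function(j) apply_minmax(data[[cols[j]]], cols[j], params),
              numeric(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- cols
  m
}

#' Build the global ordinal codebook
#'
#' Assigns consecutive integer codes to every (item, option) pair, walking the
#' categorical items in schema order and each item's options in printed order
#' and starting at 1. The encoding is global: codes do not restart per item,
#' so with the default 30-option vocabulary the codes span exactly 1 to 30
#' (sex Male = 1, Female = 2, ..., root amputation = 30). This gives all
#' categorical data a shared pseudo-continuous axis that the downstream
#' embedding layer re-represents.
#'
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return A tibble of class `ordinal_codebook` with columns `item_id`,
#'   `column`, `option`, `code`.
#' @examples
#' cb <- build_codebook()
#' cb[cb$column == "tooth_position", ] # codes 13..18
#' @export
build_codebook <- function(schema = default_schema()) {
  validate_schema(schema)
  cats <- categorical_items(schema)
  cb <- purrr::pmap_dfr(
    cats[, c("item_id", "column", "options")],
    function(item_id, column, options) {
      tibble(item_id = item_id, column = column, option = options)
    }
  )
  cb$code <- seq_len(nrow(cb))
  structure(cb, class = c("ordinal_codebook", class(tibble())))
}

#' Encode the categorical items of records as global ordinal codes
#'
#' @param data A record tibble.
#' @param codebook An `ordinal_codebook` from [build_codebook()].
#' @return An integer matrix with one row per record and one column per
#'   categorical item; entry (i, j) is the global code of record i's selected
#'   option for categorical item j. With the default schema every entry lies
#'   in 1..30 and rows differing in any item differ in the corresponding code
#'   (codes are globally unique).
#' @export
encode_categorical <- function(data, codebook) {
  stopifnot(inherits(codebook, "ordinal_codebook"))
  data <- as_tibble(data)
  cols <- unique(codebook$column)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Data lacks categorical column(s): ", paste(missing_cols, collapse = ", ")))
  }
  m <- vapply(cols, function(cl) {
    sub <- codebook[codebook$column == cl, ]
    idx <- match(data[[cl]], sub$option)
    if (anyNA(idx)) {
      r <- which(is.na(idx))[1L]
      abort(sprintf("Row %d: option '%s' of item '%s' is not in the codebook.",
                    r, data[[cl]][r], cl))
    }
    as.integer(sub$code[idx])
  }, integer(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(as.integer(m), nrow = 1L)
  colnames(m) <- cols
  m
}

#' Serialize preprocessing artifacts to JSON
#'
#' Normalization parameters and the ordinal codebook serialize to plain JSON
#' key-value files so a model trained in one session can be applied in
#' another.
#'
#' @param x A `minmax_params` or `ordinal_codebook` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preprocess <- function(x, path) {
  if (inherits(x, "minmax_params")) {
    obj <- list(type = "minmax_params", mode = attr(x, "mode"),
                table = as.data.frame(x))
  } else if (inherits(x, "ordinal_codebook")) {
    obj <- list(type = "ordinal_codebook", table = as.data.frame(x))
  } else {
    abort("`x` must be a minmax_params or ordinal_codebook object.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- as_tibble(obj$table)
  if (identical(obj$type, "minmax_params")) {
    structure(tb, mode = obj$mode, class = c("minmax_params", class(tibble())))
  } else if (identical(obj$type, "ordinal_codebook")) {
    tb$code <- as.integer(tb$code)
    tb$item_id <- as.integer(tb$item_id)
    structure(tb, class = c("ordinal_codebook", class(tibble())))
  } else {
    abort(sprintf("Unknown preprocessing artifact type '%s'.", obj$type))
  }
}
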