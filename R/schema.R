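# The 17-item clinical schema: 10 categorical items describing dental history
# and status, 7 numerical items, plus a binary fracture label.

#' The default 17-item clinical schema
#'
#' Returns the schema of the study's clinical records: items 1--10 are
#' categorical (sex, prior fractures and prostheses, pain status, endodontic
#' retreatment, tooth position, post placement, abutment role, previous apical
#' surgery) and items 11--17 are numerical (age, remaining tooth walls, time to
#' prosthetic installation, wear and periodontal scores, remaining canal wall
#' and pericervical dentin thickness). The categorical option vocabularies
#' total 30 options across the 10 items, which is what makes the global
#' ordinal codebook span codes 1 to 30 (see [build_codebook()]).
#'
#' Numeric ranges attached to numerical items are advisory: out-of-range
#' values raise a warning during validation, never an error, because the
#' schema fixes no hard physical bounds.
#'
#' @return A tibble of class `tsfnn_schema` with one row per item and columns
#'   `item_id`, `name` (descriptive item name), `column` (the CSV column key),
#'   `kind` (`"categorical"` or `"numerical"`), `options` (list column of
#'   option labels; empty for numerical items), `lo`, `hi` (advisory bounds,
#'   `NA` for categorical items).
#' @examples
#' sch <- default_schema()
#' sum(sch$kind == "categorical") # 10
#' sch$options[[7]] # the six tooth positions
#' @export
default_schema <- function() {
  opt <- function(...) list(c(...))
  yn <- opt("Yes", "No")
  sch <- tibble(
    item_id = 1:17,
    name = c(
      "sex",
      "previous dental fractures",
      "previous prostheses",
      "preoperative pain",
      "percussion pain",
      "endodontical retreatment",
      "tooth position",
      "posts placement",
      "abutment of removable dentures or fixed partial dental prostheses",
      "previous sapicoectomy or root amputation",
      "the age at the time of treatment",
      "quantity of remaining tooth walls",
      "duration from completion of root canal treatment until the date of prosthetic installation",
      "tooth wear condition",
      "periodontal condition",
      "remaining root canal wall thickness",
      "pericervical dentin thickness"
    ),
    column = c(
      "sex", "prior_fracture", "prior_prosthesis", "preop_pain",
      "percussion_pain", "retreatment", "tooth_position", "post_type",
      "abutment_type", "apical_surgery",
      "age", "remaining_walls", "time_to_prosthesis", "tooth_wear",
      "periodontal_condition", "canal_wall_thickness", "pericervical_dentin"
    ),
    kind = rep(c("categorical", "numerical"), c(10L, 7L)),
    options = c(
      opt("Male", "Female"), yn, yn, yn, yn, yn,
      opt(
        "Maxillary anterior teeth", "maxillary molars", "maxillary premolar",
        "Mandibular front teeth", "Mandibular molars", "Mandibular premolar"
      ),
      opt("None", "Para post", "Casting post", "Fiber post", "Screw post"),
      opt(
        "None", "Abutment of removable dentures",
        "fixed partial dental prostheses", "Both of them"
      ),
      opt("None", "Previous sapicoectomy", "Root amputation"),
      rep(list(character(0)), 7L)
    ),
    lo = c(rep(NA_real_, 10L), 10, 0, 0, 0, 0, 0, 0),
    hi = c(rep(NA_real_, 10L), 110, 4, 120, 4, 4, 6, 8)
  )
  new_schema(sch)
}

new_schema <- function(x) {
  structure(x, class = c("tsfnn_schema", class(tibble())))
}

#' Validate a schema definition
#'
#' Checks the structural invariants a schema must satisfy: unique item ids and
#' column keys, non-empty duplicate-free option lists for categorical items,
#' and empty option lists for numerical items.
#'
#' @param schema A schema tibble as returned by [default_schema()] or
#'   [read_schema()].
#' @return The schema, invisibly, if valid; otherwise an error.
#' @export
validate_schema <- function(schema) {
  needed <- c("item_id", "name", "column", "kind", "options")
  missing_cols <- setdiff(needed, names(schema))
  if (length(missing_cols)) {
    abort(paste0("Schema is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(schema$item_id)) abort("Schema item ids must be unique.")
  if (anyDuplicated(schema$column)) abort("Schema column keys must be unique.")
  if (!all(schema$kind %in% c("categorical", "numerical"))) {
    abort("Schema `kind` must be 'categorical' or 'numerical'.")
  }
  for (i in seq_len(nrow(schema))) {
    opts <- schema$options[[i]]
    if (schema$kind[i] == "categorical") {
      if (length(opts) == 0L) {
        abort(sprintf("Categorical item %d ('%s') has no options.",
                      schema$item_id[i], schema$name[i]))
      }
      if (anyDuplicated(opts)) {
        abort(sprintf("Item %d ('%s') has duplicate option labels.",
                      schema$item_id[i], schema$name[i]))
      }
    } else if (length(opts) != 0L) {
      abort(sprintf("Numerical item %d ('%s') must not list options.",
                    schema$item_id[i], schema$name[i]))
    }
  }
  invisible(schema)
}

categorical_items <- function(schema) schema[schema$kind == "categorical", , drop = FALSE]
numerical_items <- function(schema) schema[schema$kind == "numerical", , drop = FALSE]

#' Validate clinical records against a schema
#'
#' Every record must carry all 17 items: categorical values must be members of
#' their item's option vocabulary and numerical values must be finite numbers.
#' Missing values are a hard error -- the pipeline assumes conforming records
#' and defines no imputation. Values outside an item's advisory numeric range
#' raise a warning only.
#'
#' @param data A data frame with one row per record, one column per schema
#'   `column` key, and a `fractured` column coded 0/1 (1 = fractured, the
#'   positive class).
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return `data` as a tibble, invisibly, if valid.
#' @export
validate_dataset <- function(data, schema = default_schema()) {
  validate_schema(schema)
  data <- as_tibble(data)
  expected <- c(schema$column, "fractured")
  unknown <- setdiff(names(data), expected)
  if (length(unknown)) {
    abort(paste0("Unknown column(s): ", paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(expected, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  lab <- data$fractured
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    abort("`fractured` must be 0 (nonfractured) or 1 (fractured), no missing values.")
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    v <- data[[col]]
    if (anyNA(v)) {
      abort(sprintf("Item %d ('%s') has missing values in row(s) %s.",
                    schema$item_id[i], col,
                    paste(head(which(is.na(v)), 5L), collapse = ", ")))
    }
    if (schema$kind[i] == "categorical") {
      bad <- !(v %in% schema$options[[i]])
      if (any(bad)) {
        r <- which(bad)[1L]
        abort(sprintf(
          "Row %d, item %d ('%s'): value '%s' is not in the option list.",
          r, schema$item_id[i], col, v[r]
        ))
      }
    } else {
      if (!is.numeric(v)) {
        abort(sprintf("Item %d ('%s') must be numeric.", schema$item_id[i], col))
      }
      if (any(!is.finite(v))) {
        abort(sprintf("Item %d ('%s') has non-finite values.", schema$item_id[i], col))
      }
      if (!is.na(schema$lo[i]) && any(v < schema$lo[i] | v > schema$hi[i])) {
        warn(sprintf(
          "Item %d ('%s') has values outside the advisory range [%g, %g].",
          schema$item_id[i], col, schema$lo[i], schema$hi[i]
        ))
      }
    }
  }
  invisible(data)
}

#' Read a clinical record table from CSV
#'
#' Reads a comma-separated, UTF-8, headered file whose columns are the schema
#' column keys plus a trailing `fractured` label column, and validates every
#' row against the schema. Row order is preserved; downstream leave-one-out
#' fold indices refer to this order.
#'
#' @param path Path to a CSV file.
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return A validated tibble of records.
#' @seealso [write_dataset()] for the inverse; the pair round-trips losslessly.
#' @export
read_dataset <- function(path, schema = default_schema()) {
  validate_schema(schema)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cat_cols <- categorical_items(schema)$column
  num_cols <- numerical_items(schema)$column
  types <- do.call(
    readr::cols,
    c(
      setNames(rep(list(readr::col_character()), length(cat_cols)), cat_cols),
      setNames(rep(list(readr::col_double()), length(num_cols)), num_cols),
      list(fractured = readr::col_integer(), .default = readr::col_guess())
    )
  )
  data <- suppressWarnings(readr::read_csv(path, col_types = types, progress = FALSE))
  probs <- readr::problems(data)
  if (nrow(probs) > 0L) {
    abort(sprintf(
      "Parse error at row %d, column '%s': expected %s, got '%s'.",
      probs$row[1L], names(data)[probs$col[1L]], probs$expected[1L], probs$actual[1L]
    ))
  }
  validate_dataset(data, schema)
  data
}

#' Write a clinical record table to CSV
#'
#' Writes one header row plus one row per record, with the `fractured` label
#' column last and option labels stored verbatim, so that
#' [read_dataset()] recovers an identical table.
#'
#' @param data A validated record tibble.
#' @param path Output file path.
#' @param schema A schema tibble; defaults to [default_schema()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, schema = default_schema()) {
  data <- as_tibble(validate_dataset(data, schema))
  data <- data[, c(schema$column, "fractured")]
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read or write a schema as a YAML config file
#'
#' Alternative schemas (different items or vocabularies) can be supplied as a
#' plain config file: a list of items, each with `item_id`, `name`, `column`,
#' `kind` and, for categorical items, an `options` list.
#'
#' @param path Path to a YAML file.
#' @return For `read_schema()`, a validated schema tibble.
#' @export
read_schema <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read schema config files.")
  }
  raw <- yaml::read_yaml(path)
  sch <- purrr::map_dfr(raw, function(it) {
    tibble(
      item_id = as.integer(it$item_id),
      name = it$name,
      column = it$column,
      kind = it$kind,
      options = list(as.character(it$options %||% character(0))),
      lo = as.numeric(it$lo %||% NA_real_),
      hi = as.numeric(it$hi %||% NA_real_)
    )
  })
  validate_schema(new_schema(sch))
  new_schema(sch)
}

#' @param schema A schema tibble to serialize.
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to write schema config files.")
  }
  validate_schema(schema)
  items <- purrr::pmap(schema, function(item_id, name, column, kind, options, lo, hi) {
    out <- list(item_id = item_id, name = name, column = column, kind = kind)
    if (kind == "categorical") out$options <- as.list(options)
    if (!is.na(lo)) {
      out$lo <- lo
      out$hi <- hi
    }
    out
  })
  yaml::write_yaml(items, path)
  invisible(path)
}
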