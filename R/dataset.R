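#' Construct a validated mixed-type dataset
#'
#' Binds a data frame of raw values to a [feature_schema()], coercing
#' continuous columns to numeric and categorical columns to character, and
#' checking every value against its feature specification (finite numeric
#' for continuous; declared level membership for ordinal/nominal).
#'
#' @param data A data frame containing at least all schema columns.
#' @param schema A `feature_schema`.
#' @param row_ids Optional character vector of unique row identifiers;
#'   defaults to `row_1 ... row_n`.
#' @return An object of class `mixed_dataset` with elements `schema`,
#'   `data` (columns in schema order) and `row_ids`.
#' @export
mixed_dataset <- function(data, schema, row_ids = NULL) {
  stopifnot(inherits(schema, "feature_schema"), is.data.frame(data))
  missing_cols <- setdiff(feature_names(schema), names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(data) < 1L) stop("dataset must contain at least one row")
  data <- data[, feature_names(schema), drop = FALSE]
  ft <- feature_types(schema)
  for (nm in names(ft)) {
    data[[nm]] <- if (ft[[nm]] == "continuous") as.numeric(data[[nm]])
                  else as.character(data[[nm]])
  }
  if (is.null(row_ids)) row_ids <- paste0("row_", seq_len(nrow(data)))
  row_ids <- as.character(row_ids)
  if (length(row_ids) != nrow(data) || anyDuplicated(row_ids))
    stop("row_ids must be unique and match the number of rows")
  bad <- which(!valid_row_mask(data, schema))
  if (length(bad))
    stop("invalid value(s) in row(s): ",
         paste(utils::head(row_ids[bad], 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  rownames(data) <- NULL
  structure(list(schema = schema, data = data, row_ids = row_ids),
            class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  cat("<mixed_dataset> ", nrow(x$data), " rows x ", ncol(x$data),
      " features\n", sep = "")
  print(x$schema)
  invisible(x)
}

#' Number of rows of a mixed dataset
#' @param dataset A `mixed_dataset`.
#' @return Integer row count.
#' @export
n_rows <- function(dataset) {
  stopifnot(inherits(dataset, "mixed_dataset"))
  nrow(dataset$data)
}

# TRUE for rows whose every value conforms to its feature spec
valid_row_mask <- function(data, schema) {
  ok <- rep(TRUE, nrow(data))
  for (f in schema$features) {
    v <- data[[f$name]]
    ok <- ok & if (f$type == "continuous") {
      num <- suppressWarnings(as.numeric(v))
      !is.na(num) & is.finite(num)
    } else {
      !is.na(v) & (as.character(v) %in% f$levels)
    }
  }
  ok
}

#' Load a delimited mixed-type table
#'
#' Reads a CSV/TSV file with a header row, validates every value against
#' the schema, and either drops offending rows (`policy = "drop"`, the
#' count is reported via `message()`) or fails on the first offending row
#' (`policy = "strict"`). Empty cells and `NA` count as missing.
#'
#' @param path Path to a delimited text file. The delimiter is inferred
#'   from the extension (`.csv` comma, anything else tab) unless `delim`
#'   is given.
#' @param schema A `feature_schema`; all schema names must appear as
#'   columns.
#' @param policy `"drop"` (default) or `"strict"`.
#' @param delim Optional single-character field delimiter override.
#' @param id_col Name of an optional identifier column; used as `row_ids`
#'   when present.
#' @return A `mixed_dataset`; attribute `"dropped"` holds the number of
#'   removed rows under `policy = "drop"`.
#' @export
load_table <- function(path, schema, policy = c("drop", "strict"),
                       delim = NULL, id_col = "row_id") {
  policy <- match.arg(policy)
  stopifnot(inherits(schema, "feature_schema"))
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(delim))
    delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(feature_names(schema), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  row_ids <- if (id_col %in% names(raw)) as.character(raw[[id_col]])
             else paste0("row_", seq_len(nrow(raw)))
  keep <- valid_row_mask(raw[, feature_names(schema), drop = FALSE], schema)
  if (!all(keep)) {
    if (policy == "strict") {
      first <- which(!keep)[1L]
      stop("invalid or missing value in row '", row_ids[first],
           "' under policy = \"strict\"")
    }
    message("load_table: dropped ", sum(!keep), " of ", length(keep),
            " rows with missing or invalid values")
  }
  if (!any(keep)) stop("no valid rows remain after filtering")
  ds <- mixed_dataset(raw[keep, , drop = FALSE], schema,
                      row_ids = row_ids[keep])
  attr(ds, "dropped") <- sum(!keep)
  ds
}

#' Write a mixed dataset to a delimited file
#'
#' Inverse of [load_table()]: writes a header row, a `row_id` column and
#' all feature columns. Extension picks the delimiter (`.csv` comma,
#' otherwise tab).
#'
#' @param dataset A `mixed_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "mixed_dataset"))
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  out <- cbind(row_id = dataset$row_ids, dataset$data)
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Encode a mixed dataset into per-type numeric blocks
#'
#' Splits the table into three aligned numeric matrices: continuous values
#' passed through; ordinal levels mapped to consecutive integer codes
#' starting at 1 in declared rank order (so the Canberra denominators are
#' never 0+0); nominal levels mapped to stable integers in the order the
#' schema lists them.
#'
#' @param dataset A `mixed_dataset`.
#' @return An object of class `encoded_blocks`: list with matrices
#'   `continuous`, `ordinal`, `nominal` (0-column matrices when a type is
#'   absent), plus `row_ids` and `schema`.
#' @seealso [decode_features()] for the inverse.
#' @export
encode_features <- function(dataset) {
  stopifnot(inherits(dataset, "mixed_dataset"))
  schema <- dataset$schema
  n <- n_rows(dataset)
  block <- function(type) {
    nms <- features_of_type(schema, type)
    m <- matrix(0, nrow = n, ncol = length(nms),
                dimnames = list(NULL, nms))
    for (nm in nms) {
      f <- schema$features[[nm]]
      m[, nm] <- if (type == "continuous") dataset$data[[nm]]
                 else match(dataset$data[[nm]], f$levels)
    }
    if (type != "continuous") storage.mode(m) <- "integer"
    m
  }
  structure(list(continuous = block("continuous"),
                 ordinal    = block("ordinal"),
                 nominal    = block("nominal"),
                 row_ids    = dataset$row_ids,
                 schema     = schema),
            class = "encoded_blocks")
}

#' @export
print.encoded_blocks <- function(x, ...) {
  cat("<encoded_blocks> ", length(x$row_ids), " rows; continuous ",
      ncol(x$continuous), ", ordinal ", ncol(x$ordinal), ", nominal ",
      ncol(x$nominal), " features\n", sep = "")
  invisible(x)
}

#' Decode numeric blocks back into a mixed dataset
#'
#' @param blocks An `encoded_blocks` object.
#' @return The `mixed_dataset` whose encoding produced `blocks`.
#' @export
decode_features <- function(blocks) {
  stopifnot(inherits(blocks, "encoded_blocks"))
  schema <- blocks$schema
  n <- length(blocks$row_ids)
  cols <- lapply(schema$features, function(f) {
    switch(f$type,
      continuous = blocks$continuous[, f$name],
      ordinal    = f$levels[blocks$ordinal[, f$name]],
      nominal    = f$levels[blocks$nominal[, f$name]])
  })
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- feature_names(schema)
  mixed_dataset(df, schema, row_ids = blocks$row_ids)
}

#' Remove continuous-feature outliers by Tukey fences
#'
#' Applies the distribution-free 1.5 x IQR rule independently per named
#' continuous feature: fences are `[Q1 - k*IQR, Q3 + k*IQR]` computed on
#' the incoming data, and a row is removed if it falls outside the fence
#' of any named feature. Per-feature removal counts are reported via
#' `message()` and stored in the `"outlier_counts"` attribute.
#'
#' @param dataset A `mixed_dataset`.
#' @param features Continuous feature names to screen; defaults to all
#'   continuous features of the schema.
#' @param k IQR multiplier (default 1.5; `Inf` disables removal).
#' @return The filtered `mixed_dataset`.
#' @export
remove_outliers <- function(dataset, features = NULL, k = 1.5) {
  stopifnot(inherits(dataset, "mixed_dataset"), is.numeric(k), k >= 0)
  cont <- features_of_type(dataset$schema, "continuous")
  if (is.null(features)) features <- cont
  bad_names <- setdiff(features, cont)
  if (length(bad_names))
    stop("not continuous feature(s): ", paste(bad_names, collapse = ", "))
  keep <- rep(TRUE, n_rows(dataset))
  counts <- integer(length(features))
  names(counts) <- features
  for (nm in features) {
    x <- dataset$data[[nm]]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    inside <- if (is.infinite(k)) rep(TRUE, length(x))
              else x >= q[1L] - k * iqr & x <= q[2L] + k * iqr
    counts[nm] <- sum(!inside)
    keep <- keep & inside
  }
  if (any(counts > 0))
    message("remove_outliers: ",
            paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
            " row(s) outside fences; ", sum(!keep), " removed in total")
  out <- mixed_dataset(dataset$data[keep, , drop = FALSE], dataset$schema,
                       row_ids = dataset$row_ids[keep])
  attr(out, "outlier_counts") <- counts
  out
}
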