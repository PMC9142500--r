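#' Declare a single feature of a mixed-type table
#'
#' A feature is one column of an individuals-by-features survey table. Its
#' type decides which distance metric and which encoding the clustering
#' pipeline applies: continuous features keep their numeric values and are
#' compared with the Euclidean metric, ordinal features are rank-coded and
#' compared with the Canberra metric, and nominal features are arbitrarily
#' (but stably) coded and compared with the Hamming metric.
#'
#' @param name Feature (column) name; non-empty string.
#' @param type One of `"continuous"`, `"ordinal"`, `"nominal"`.
#' @param levels For ordinal features, the level labels in increasing rank
#'   order (the order IS the ranking); for nominal features, the set of
#'   admissible labels (order only fixes the integer coding). Must be `NULL`
#'   for continuous features.
#' @param category Optional free-text grouping tag (e.g. `"comorbidity"`,
#'   `"food"`, `"addiction"`, `"sociodemographic"`, `"living"`).
#'
#' @return An object of class `feature_spec`.
#' @seealso [feature_schema()], [nfhs4_schema()]
#' @export
#' @examples
#' feature_spec("milk_curd_freq", "ordinal",
#'              levels = c("Never", "Weekly", "Occasionally", "Daily"),
#'              category = "food")
feature_spec <- function(name, type = c("continuous", "ordinal", "nominal"),
                         levels = NULL, category = NULL) {
  type <- match.arg(type)
  if (!is.character(name) || length(name) != 1L || !nzchar(name) || is.na(name))
    stop("feature 'name' must be a single non-empty string")
  if (type == "continuous") {
    if (!is.null(levels))
      stop("continuous feature '", name, "' must not declare levels")
  } else {
    if (is.null(levels) || length(levels) == 0L)
      stop(type, " feature '", name, "' requires a non-empty 'levels' vector")
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop("levels of feature '", name, "' must be unique")
    if (any(is.na(levels)))
      stop("levels of feature '", name, "' must not contain NA")
  }
  if (!is.null(category)) {
    stopifnot(is.character(category), length(category) == 1L)
  }
  structure(list(name = name, type = type, levels = levels,
                 category = category),
            class = "feature_spec")
}

#' Assemble feature specifications into a schema
#'
#' @param features A list of [feature_spec()] objects with unique names.
#' @return An object of class `feature_schema`.
#' @export
#' @examples
#' feature_schema(list(
#'   feature_spec("age", "continuous"),
#'   feature_spec("sex", "nominal", levels = c("Male", "Female"))
#' ))
feature_schema <- function(features) {
  if (!is.list(features) || length(features) == 0L)
    stop("'features' must be a non-empty list of feature_spec objects")
  ok <- vapply(features, inherits, logical(1), what = "feature_spec")
  if (!all(ok))
    stop("all elements of 'features' must be feature_spec objects")
  nms <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(features) <- nms
  structure(list(features = features), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cnt <- schema_counts(x)
  cat("<feature_schema> ", n_features(x), " features (",
      cnt[["continuous"]], " continuous, ",
      cnt[["ordinal"]], " ordinal, ",
      cnt[["nominal"]], " nominal)\n", sep = "")
  invisible(x)
}

#' Feature names of a schema
#' @param schema A `feature_schema`.
#' @return Character vector of feature names, in schema order.
#' @export
feature_names <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  names(schema$features)
}

#' Feature types of a schema
#' @param schema A `feature_schema`.
#' @return Named character vector mapping feature name to its type.
#' @export
feature_types <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  vapply(schema$features, `[[`, character(1), "type")
}

#' Number of features in a schema
#' @param schema A `feature_schema`.
#' @return Integer count.
#' @export
n_features <- function(schema) length(feature_names(schema))

#' Feature counts by type
#' @param schema A `feature_schema`.
#' @return Named integer vector with entries `continuous`, `ordinal`, `nominal`.
#' @export
schema_counts <- function(schema) {
  ft <- feature_types(schema)
  c(continuous = sum(ft == "continuous"),
    ordinal    = sum(ft == "ordinal"),
    nominal    = sum(ft == "nominal"))
}

#' Feature counts by category tag
#' @param schema A `feature_schema`.
#' @return Named integer vector of counts per category (untagged features
#'   are counted under `"<none>"`).
#' @export
category_counts <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  cats <- vapply(schema$features, function(f)
    if (is.null(f$category)) "<none>" else f$category, character(1))
  table_to_named(table(cats))
}

table_to_named <- function(tb) {
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

#' Names of features of a given type
#' @param schema A `feature_schema`.
#' @param type `"continuous"`, `"ordinal"` or `"nominal"`.
#' @return Character vector of feature names, in schema order.
#' @export
features_of_type <- function(schema, type = c("continuous", "ordinal", "nominal")) {
  type <- match.arg(type)
  ft <- feature_types(schema)
  names(ft)[ft == type]
}

#' Read a schema configuration file
#'
#' The config is YAML or JSON with a top-level `features` list; each entry
#' has `name`, `type` and (for categorical types) `levels` as an ordered
#' list, plus an optional `category`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A `feature_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported schema format '", ext, "' (use yaml or json)"))
  if (is.null(raw$features)) stop("schema file lacks a 'features' entry")
  specs <- lapply(raw$features, function(f) {
    feature_spec(name = f$name, type = f$type,
                 levels = if (!is.null(f$levels)) unlist(f$levels),
                 category = f$category)
  })
  feature_schema(specs)
}

#' Write a schema configuration file
#' @param schema A `feature_schema`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  lst <- list(features = lapply(unname(schema$features), function(f) {
    out <- list(name = f$name, type = f$type)
    if (!is.null(f$levels)) out$levels <- as.list(f$levels)
    if (!is.null(f$category)) out$category <- f$category
    out
  }))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported schema format '", ext, "'"))
  invisible(path)
}

#' The packaged 36-feature national health survey schema
#'
#' The schema of the T2DM patient table the package's workflow is designed
#' around: 36 features of which 4 are continuous (age, BMI, haemoglobin,
#' time to drinking water source), 7 nominal (sex, religion, caste,
#' household structure, residence type, cooking fuel, drinking water
#' source) and 25 ordinal (binary comorbidity and addiction indicators,
#' four-level food-frequency items, wealth quintile, education level,
#' household possessions, indoor smoking frequency). Features carry the
#' category tags comorbidity (6), food (9), addiction (2),
#' sociodemographic (8) and living (11).
#'
#' Food-frequency levels are ordered Never < Weekly < Occasionally < Daily.
#'
#' @return A `feature_schema` with 36 features.
#' @export
#' @examples
#' sch <- nfhs4_schema()
#' schema_counts(sch)
#' category_counts(sch)
nfhs4_schema <- function() {
  path <- system.file("extdata", "nfhs4_schema.yaml", package = "mixedclust")
  if (!nzchar(path)) stop("packaged schema file not found")
  read_schema(path)
}
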