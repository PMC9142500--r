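#' Per-cluster feature summaries (Table-1 style)
#'
#' Summarizes every feature within every cluster the way epidemiological
#' baseline tables are reported: continuous features as mean and standard
#' error of the mean (SEM = sample SD / sqrt(cluster size), using the
#' n - 1 SD), categorical features as the count and percentage of each
#' level within the cluster (percentages to 2 decimals). Noise rows
#' (label -1) are excluded unless `include_noise = TRUE`, in which case
#' they are summarized as a pseudo-cluster labelled `-1`.
#'
#' @param dataset A `mixed_dataset`.
#' @param labels A `cluster_labels` vector (or plain integer vector with
#'   `-1` = noise) aligned with the dataset rows.
#' @param clusters Optional integer vector restricting which cluster ids
#'   are summarized; default: all non-noise clusters.
#' @param include_noise Summarize noise rows as cluster `-1`
#'   (default `FALSE`).
#' @return An object of class `cluster_summary`: `sizes` (named vector),
#'   `continuous` (data frame: cluster, feature, mean, sem, degenerate)
#'   and `categorical` (data frame: cluster, feature, level, count,
#'   percent).
#' @export
summarize_clusters <- function(dataset, labels, clusters = NULL,
                               include_noise = FALSE) {
  stopifnot(inherits(dataset, "mixed_dataset"))
  labels <- as.integer(labels)
  if (length(labels) != n_rows(dataset))
    stop("labels must align with dataset rows")
  ids <- sort(unique(labels[labels > 0L]))
  if (include_noise && any(labels == -1L)) ids <- c(ids, -1L)
  if (!is.null(clusters)) ids <- ids[ids %in% clusters]
  if (!length(ids)) stop("no clusters to summarize")
  schema <- dataset$schema
  cont_feats <- features_of_type(schema, "continuous")
  cat_feats <- setdiff(feature_names(schema), cont_feats)

  sizes <- vapply(ids, function(k) sum(labels == k), integer(1))
  names(sizes) <- ids

  cont_rows <- list()
  cat_rows <- list()
  for (k in ids) {
    rows <- labels == k
    nk <- sum(rows)
    for (nm in cont_feats) {
      x <- dataset$data[[nm]][rows]
      degenerate <- nk < 2L
      sem <- if (degenerate) 0 else stats::sd(x) / sqrt(nk)
      cont_rows[[length(cont_rows) + 1L]] <-
        data.frame(cluster = k, feature = nm, mean = mean(x), sem = sem,
                   degenerate = degenerate, stringsAsFactors = FALSE)
    }
    for (nm in cat_feats) {
      lv <- schema$features[[nm]]$levels
      cnt <- vapply(lv, function(l) sum(dataset$data[[nm]][rows] == l),
                    integer(1))
      cat_rows[[length(cat_rows) + 1L]] <-
        data.frame(cluster = k, feature = nm, level = lv,
                   count = as.integer(cnt),
                   percent = round(100 * cnt / nk, 2),
                   stringsAsFactors = FALSE)
    }
  }
  continuous <- do.call(rbind, cont_rows)
  categorical <- do.call(rbind, cat_rows)
  rownames(continuous) <- NULL
  rownames(categorical) <- NULL
  structure(list(sizes = sizes, continuous = continuous,
                 categorical = categorical),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("<cluster_summary> ", length(x$sizes), " cluster(s); sizes: ",
      paste(sprintf("%s:%d", names(x$sizes), x$sizes), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Write a cluster summary as a long-format CSV
#'
#' One row per (cluster, feature, level, statistic): continuous features
#' contribute `mean` and `sem` rows with an empty level, categorical
#' features contribute `count` and `percent` rows per level; cluster
#' sizes appear as statistic `size`. The file round-trips through
#' [read_summary()].
#'
#' @param summary A `cluster_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cluster_summary"))
  long <- rbind(
    data.frame(cluster = as.integer(names(summary$sizes)), feature = "",
               level = "", statistic = "size",
               value = as.numeric(summary$sizes),
               stringsAsFactors = FALSE),
    data.frame(cluster = summary$continuous$cluster,
               feature = summary$continuous$feature, level = "",
               statistic = "mean", value = summary$continuous$mean,
               stringsAsFactors = FALSE),
    data.frame(cluster = summary$continuous$cluster,
               feature = summary$continuous$feature, level = "",
               statistic = "sem", value = summary$continuous$sem,
               stringsAsFactors = FALSE),
    data.frame(cluster = summary$categorical$cluster,
               feature = summary$categorical$feature,
               level = summary$categorical$level,
               statistic = "count",
               value = as.numeric(summary$categorical$count),
               stringsAsFactors = FALSE),
    data.frame(cluster = summary$categorical$cluster,
               feature = summary$categorical$feature,
               level = summary$categorical$level,
               statistic = "percent", value = summary$categorical$percent,
               stringsAsFactors = FALSE))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format cluster summary CSV
#'
#' @param path Path written by [write_summary()].
#' @return A `cluster_summary`.
#' @export
read_summary <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(cluster = "integer",
                                         feature = "character",
                                         level = "character",
                                         statistic = "character",
                                         value = "numeric"))
  long$level[is.na(long$level)] <- ""
  long$feature[is.na(long$feature)] <- ""
  sz <- long[long$statistic == "size", ]
  sizes <- as.integer(sz$value)
  names(sizes) <- sz$cluster
  mu <- long[long$statistic == "mean", ]
  se <- long[long$statistic == "sem", ]
  continuous <- data.frame(cluster = mu$cluster, feature = mu$feature,
                           mean = mu$value, sem = se$value,
                           degenerate = sizes[as.character(mu$cluster)] < 2L,
                           stringsAsFactors = FALSE)
  rownames(continuous) <- NULL
  cnt <- long[long$statistic == "count", ]
  pct <- long[long$statistic == "percent", ]
  categorical <- data.frame(cluster = cnt$cluster, feature = cnt$feature,
                            level = cnt$level,
                            count = as.integer(cnt$value),
                            percent = pct$value, stringsAsFactors = FALSE)
  rownames(categorical) <- NULL
  structure(list(sizes = sizes, continuous = continuous,
                 categorical = categorical),
            class = "cluster_summary")
}

#' Render a cluster summary as a human-readable wide table
#'
#' Mirrors the conventional baseline-table layout: one column per
#' cluster, continuous cells as `"mean +/- SEM"`, categorical cells as
#' `"count (percent)"` with percentages printed to 2 decimals.
#'
#' @param summary A `cluster_summary`.
#' @param digits Digits for continuous means/SEMs (default 2).
#' @return Character matrix (rows = feature or feature:level, columns =
#'   clusters), suitable for `write.table()` or printing.
#' @export
render_summary <- function(summary, digits = 2) {
  stopifnot(inherits(summary, "cluster_summary"))
  ids <- names(summary$sizes)
  fmt_num <- function(v) formatC(v, format = "fg", digits = digits,
                                 flag = "#")
  rows <- list(`Cluster size (N)` = as.character(summary$sizes))
  for (nm in unique(summary$continuous$feature)) {
    sub <- summary$continuous[summary$continuous$feature == nm, ]
    sub <- sub[match(ids, as.character(sub$cluster)), ]
    rows[[nm]] <- sprintf("%s ± %s",
                          signif(sub$mean, 4), signif(sub$sem, 2))
  }
  key <- paste(summary$categorical$feature, summary$categorical$level,
               sep = ": ")
  for (kk in unique(key)) {
    sub <- summary$categorical[key == kk, ]
    sub <- sub[match(ids, as.character(sub$cluster)), ]
    rows[[kk]] <- sprintf("%d (%.2f)", sub$count, sub$percent)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- paste("Cluster", ids)
  out
}
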