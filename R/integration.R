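#' Select the maximum-variance embedding dimension
#'
#' Used to collapse the nominal-block embedding to a single coordinate:
#' Hamming embeddings of nominal features retain a lot of variance and
#' scatter into many small groups, so only the most informative (highest
#' sample variance) dimension is carried into the integrated
#' representation. Ties go to the lowest column index.
#'
#' @param embedding A `block_embedding` or a numeric matrix.
#' @return List with `index` (selected column) and `coords` (n x 1
#'   matrix of that column).
#' @export
select_max_variance_dim <- function(embedding) {
  coords <- if (inherits(embedding, "block_embedding")) embedding$coords
            else as.matrix(embedding)
  if (ncol(coords) < 1L) stop("embedding must have at least one column")
  vars <- apply(coords, 2L, stats::var)
  idx <- which.max(vars)              # ties: first (lowest index)
  list(index = as.integer(idx),
       coords = coords[, idx, drop = FALSE])
}

#' Integrate per-block embeddings into the 5-D representation
#'
#' Concatenates, without rescaling, the two continuous-block coordinates,
#' the two ordinal-block coordinates, and the single maximum-variance
#' nominal coordinate, yielding the n x 5 matrix that density clustering
#' operates on. `standardize_blocks = TRUE` optionally centres and scales
#' every output column to unit variance (raw coordinate scales are
#' engine-dependent).
#'
#' @param cont `block_embedding` of the continuous block, exactly 2
#'   columns.
#' @param ordn `block_embedding` of the ordinal block, exactly 2 columns.
#' @param nom `block_embedding` of the nominal block, >= 1 column; the
#'   max-variance column is used.
#' @param standardize_blocks Scale each output column to unit variance
#'   (default `FALSE`).
#' @return An object of class `integrated_embedding`: `coords` (n x 5),
#'   `provenance` (column origin labels) and `nominal_dim` (which nominal
#'   column was selected).
#' @export
integrate_embeddings <- function(cont, ordn, nom,
                                 standardize_blocks = FALSE) {
  stopifnot(inherits(cont, "block_embedding"),
            inherits(ordn, "block_embedding"),
            inherits(nom, "block_embedding"))
  if (ncol(cont$coords) != 2L)
    stop("continuous embedding must have exactly 2 columns")
  if (ncol(ordn$coords) != 2L)
    stop("ordinal embedding must have exactly 2 columns")
  n <- nrow(cont$coords)
  if (nrow(ordn$coords) != n || nrow(nom$coords) != n)
    stop("row counts differ across block embeddings")
  sel <- select_max_variance_dim(nom)
  coords <- cbind(cont$coords, ordn$coords, sel$coords)
  colnames(coords) <- c("cont_1", "cont_2", "ord_1", "ord_2", "nom_1")
  if (standardize_blocks) {
    for (j in seq_len(ncol(coords))) {
      s <- stats::sd(coords[, j])
      coords[, j] <- if (is.finite(s) && s > 0)
        (coords[, j] - mean(coords[, j])) / s else coords[, j]
    }
  }
  structure(list(coords = coords,
                 provenance = c("continuous", "continuous", "ordinal",
                                "ordinal", "nominal"),
                 nominal_dim = sel$index),
            class = "integrated_embedding")
}

#' @export
print.integrated_embedding <- function(x, ...) {
  cat("<integrated_embedding> ", nrow(x$coords),
      " x 5 (2 continuous + 2 ordinal + 1 nominal; nominal source dim ",
      x$nominal_dim, ")\n", sep = "")
  invisible(x)
}
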