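#' Euclidean distance between two vectors
#'
#' \eqn{d(x,y) = \sqrt{\sum_i (x_i - y_i)^2}} — the metric used for the
#' continuous feature block.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
#' @examples
#' dist_euclidean(c(3, 4), c(0, 0))  # 5
dist_euclidean <- function(x, y) {
  check_pair(x, y)
  sqrt(sum((x - y)^2))
}

#' Hamming distance between two code vectors
#'
#' The fraction of positions at which the two vectors disagree (mean
#' mismatch) — the metric used for the nominal feature block. Being a
#' pure match/mismatch count it is invariant under any relabeling of the
#' nominal codes. `normalize = FALSE` returns the raw mismatch count.
#'
#' @param x,y Vectors of equal length (any type comparable with `!=`).
#' @param normalize Divide the mismatch count by the vector length
#'   (default `TRUE`).
#' @return A single number in `[0, 1]` (normalized) or `[0, length(x)]`.
#' @export
#' @examples
#' dist_hamming(c("a", "b", "c"), c("a", "b", "d"))  # 1/3
dist_hamming <- function(x, y, normalize = TRUE) {
  check_pair(x, y)
  m <- sum(x != y)
  if (normalize) m / length(x) else m
}

#' Canberra distance between two non-negative vectors
#'
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / (|x_i| + |y_i|)}, with a term
#' defined as 0 when both coordinates are 0 — the metric used for the
#' ordinal feature block, where each coordinate difference is weighted by
#' the magnitude of the ranks so that a one-step disagreement matters more
#' at the low end of a scale. Ordinal codes start at 1, so the both-zero
#' convention is never exercised on ordinal blocks. `sqrt_transform`
#' applies a square root to the sum; the ranking of neighbours is
#' unchanged by this monotone transform.
#'
#' @param x,y Numeric vectors of equal length, entries `>= 0`.
#' @param sqrt_transform Return the square root of the sum (default
#'   `FALSE`).
#' @return A single non-negative number.
#' @export
#' @examples
#' dist_canberra(c(1, 3), c(3, 1))  # 2/4 + 2/4 = 1
dist_canberra <- function(x, y, sqrt_transform = FALSE) {
  check_pair(x, y)
  den <- abs(x) + abs(y)
  term <- ifelse(den == 0, 0, abs(x - y) / den)
  s <- sum(term)
  if (sqrt_transform) sqrt(s) else s
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length (", length(x), " vs ",
         length(y), ")")
  invisible(TRUE)
}

#' Pairwise distance matrix over a feature block
#'
#' Applies one of the three per-type metrics to every row pair of a
#' numeric block, returning the full symmetric matrix with zero diagonal.
#'
#' @param block Numeric matrix (rows = individuals).
#' @param metric `"euclidean"`, `"hamming"` or `"canberra"` (lower case).
#' @param ... Passed to the scalar metric (`normalize`, `sqrt_transform`).
#' @return An n x n matrix of class `dist_matrix` with attributes
#'   `metric` and `block_name`.
#' @export
pairwise_distances <- function(block, metric = c("euclidean", "hamming",
                                                 "canberra"), ...) {
  if (!is.matrix(block)) block <- as.matrix(block)
  if (nrow(block) < 1L || !is.numeric(block))
    stop("'block' must be a non-empty numeric matrix")
  if (!is.character(metric))
    stop("unknown metric")
  metric <- match.arg(metric)
  n <- nrow(block)
  p <- ncol(block)
  D <- switch(metric,
    euclidean = {
      rs <- rowSums(block^2)
      d2 <- outer(rs, rs, "+") - 2 * tcrossprod(block)
      d2[d2 < 0] <- 0
      sqrt(d2)
    },
    hamming = {
      dots <- list(...)
      normalize <- if (is.null(dots$normalize)) TRUE else dots$normalize
      M <- matrix(0, n, n)
      for (j in seq_len(p)) {
        v <- block[, j]
        M <- M + (outer(v, v, "!=") * 1)
      }
      if (normalize && p > 0) M / p else M
    },
    canberra = {
      dots <- list(...)
      sqrt_transform <- if (is.null(dots$sqrt_transform)) FALSE
                        else dots$sqrt_transform
      M <- matrix(0, n, n)
      for (j in seq_len(p)) {
        v <- abs(block[, j])
        den <- outer(v, v, "+")
        num <- abs(outer(block[, j], block[, j], "-"))
        term <- num / den
        term[den == 0] <- 0
        M <- M + term
      }
      if (sqrt_transform) sqrt(M) else M
    })
  diag(D) <- 0
  D <- (D + t(D)) / 2  # enforce exact symmetry against fp noise
  structure(D, class = c("dist_matrix", class(D)),
            metric = metric, block_name = deparse(substitute(block)))
}
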