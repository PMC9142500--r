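#' Density-based clustering (DBSCAN)
#'
#' From-scratch DBSCAN on Euclidean neighbourhoods: a core point has at
#' least `min_points` neighbours within `eps` (itself included); clusters
#' are the connected components of core points under eps-adjacency, with
#' non-core points attached as border points to the first cluster whose
#' expansion reaches them in a deterministic row-order scan; everything
#' else is noise. Returned labels are renumbered by decreasing cluster
#' size (ties: smallest member row index), with `-1` marking noise.
#'
#' @param x Numeric matrix or `integrated_embedding`.
#' @param eps Neighbourhood radius (default 1, the workflow's setting on
#'   the integrated 5-D representation).
#' @param min_points Core-point threshold (default 200, calibrated to a
#'   study population of ~10,000; about 2 percent).
#' @param min_frac Alternative to `min_points`: resolved as
#'   `ceiling(min_frac * n)` so the density requirement scales with the
#'   population size.
#' @return Integer vector of class `cluster_labels` (length n; clusters
#'   `1..K` by decreasing size, noise `-1`), with attributes `eps`,
#'   `min_points` and `sizes` (named vector of cluster sizes).
#' @export
#' @examples
#' x <- matrix(c(0, 0.5, 1, 10, 10.5, 11), ncol = 1)
#' dbscan_cluster(x, eps = 1, min_points = 2)
dbscan_cluster <- function(x, eps = 1, min_points = 200L,
                           min_frac = NULL) {
  if (inherits(x, "integrated_embedding")) x <- x$coords
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("input contains non-finite values")
  stopifnot(eps > 0)
  n <- nrow(x)
  if (!is.null(min_frac)) {
    stopifnot(min_frac > 0, min_frac <= 1)
    min_points <- ceiling(min_frac * n)
  }
  min_points <- as.integer(min_points)
  stopifnot(min_points >= 1L)

  # neighbourhoods (self included) from the full Euclidean matrix
  rs <- rowSums(x^2)
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  within <- d2 <= eps^2 + 1e-12
  nbrs <- apply(within, 1L, which, simplify = FALSE)
  core <- lengths(nbrs) >= min_points

  labels <- integer(n)                 # 0 = unassigned
  cid <- 0L
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (labels[s] != 0L || !core[s]) next
    cid <- cid + 1L
    labels[s] <- cid
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      if (!core[v]) next               # border points do not expand
      for (u in nbrs[[v]]) {
        if (labels[u] == 0L) {
          labels[u] <- cid
          tail <- tail + 1L
          queue[tail] <- u
        }
      }
    }
  }
  labels[labels == 0L] <- -1L

  # renumber by decreasing size, ties by smallest member index
  if (cid > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = cid)
    firsts <- vapply(seq_len(cid), function(k) which(labels == k)[1L],
                     integer(1))
    new_order <- order(-sizes, firsts)
    remap <- integer(cid)
    remap[new_order] <- seq_len(cid)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    sizes <- sizes[new_order]
    names(sizes) <- seq_len(cid)
  } else {
    sizes <- integer(0)
  }
  structure(labels, class = "cluster_labels", eps = eps,
            min_points = min_points, sizes = sizes)
}

#' @export
print.cluster_labels <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("<cluster_labels> n = ", length(x), ", ", length(sizes),
      " cluster(s), ", sum(unclass(x) == -1L), " noise point(s)\n",
      sep = "")
  if (length(sizes)) {
    cat("sizes:", paste(sprintf("%s:%d", names(sizes), sizes),
                        collapse = " "), "\n")
  }
  invisible(x)
}

#' Significant clusters under the 10 percent rule
#'
#' A sub-population is called significant when it contains at least
#' `min_frac` of the total study population (noise rows included in the
#' denominator).
#'
#' @param labels A `cluster_labels` vector.
#' @param min_frac Minimum population fraction (default 0.10).
#' @return Integer vector of significant cluster ids, ordered by
#'   decreasing size.
#' @export
significant_clusters <- function(labels, min_frac = 0.10) {
  stopifnot(inherits(labels, "cluster_labels"), min_frac >= 0)
  n <- length(labels)
  sizes <- attr(labels, "sizes")
  if (!length(sizes)) return(integer(0))
  ids <- as.integer(names(sizes)[sizes >= min_frac * n])
  ids[order(-sizes[as.character(ids)])]
}
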