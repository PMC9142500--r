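#' Embedding parameters
#'
#' Parameter bundle for per-block dimensionality reduction. The defaults
#' (`n_neighbors = 30`, `min_dist = 0.1`) are the neighbourhood settings
#' the workflow uses for every feature type. `min_dist` only shapes the
#' attractive kernel of stochastic-optimizer engines; the built-in
#' spectral engine accepts and records it but its coordinates do not
#' depend on it.
#'
#' @param n_neighbors Number of directed neighbours per point (>= 2).
#' @param min_dist Minimum embedding distance parameter, passed through to
#'   external engines.
#' @param n_components Embedding dimensionality (>= 1).
#' @param metric Metric name for the block (`"euclidean"`, `"hamming"`,
#'   `"canberra"`).
#' @param seed Integer seed forwarded to the engine.
#' @param engine `"reference_spectral"` (the built-in deterministic
#'   engine) or a function `f(block, params)` returning an
#'   `n x n_components` coordinate matrix (the external-engine contract).
#' @param dim_scale Per-dimension standard deviation of the spectral
#'   engine's coordinates (default 1.25). This sets the coordinate scale
#'   on which the workflow's downstream density parameters
#'   (`eps`, `min_points`) operate; see [spectral_embed()].
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(n_neighbors = 30L, min_dist = 0.1,
                             n_components = 2L, metric = "euclidean",
                             seed = 1L, engine = "reference_spectral",
                             dim_scale = 1.25) {
  stopifnot(n_neighbors >= 2, n_components >= 1, min_dist >= 0,
            dim_scale > 0)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist,
                 n_components = as.integer(n_components),
                 metric = metric, seed = as.integer(seed),
                 engine = engine, dim_scale = dim_scale),
            class = "embedding_params")
}

#' Directed smooth-kNN graph from a distance matrix
#'
#' For each point i, takes its `n_neighbors` nearest neighbours (ties
#' broken by row index), sets `rho_i` to the distance of the nearest
#' *distinct* neighbour, and calibrates a per-point bandwidth `sigma_i` by
#' bisection so that the neighbour weights
#' `w_ij = exp(-max(0, d_ij - rho_i) / sigma_i)` sum to `log2(n_neighbors)`.
#' The nearest neighbour therefore always receives weight 1, and duplicated
#' points (`rho = 0`) stay finite through the `max(0, .)` guard.
#'
#' @param D Symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param n_neighbors Neighbourhood size; must be `< nrow(D)`.
#' @return An object of class `neighbor_graph`: sparse n x n weight matrix
#'   `w` (directed, rows = sources), `rho`, `sigma`, `n_neighbors`,
#'   logical `degenerate` (all-zero distance matrix; uniform weights) and
#'   `directed = TRUE`.
#' @export
smooth_knn_graph <- function(D, n_neighbors) {
  D <- unclass(D)
  n <- nrow(D)
  k <- as.integer(n_neighbors)
  if (k >= n) stop("n_neighbors must be smaller than the number of points")
  if (k < 2) stop("n_neighbors must be at least 2")

  idx <- matrix(0L, n, k)
  dmat <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf                        # exclude self
    ord <- order(d)[seq_len(k)]        # stable: ties broken by index
    idx[i, ] <- ord
    dmat[i, ] <- d[ord]
  }

  degenerate <- all(dmat == 0)
  if (degenerate) {
    w <- matrix(1, n, k)
    rho <- rep(0, n)
    sigma <- rep(1, n)
  } else {
    rho <- apply(dmat, 1L, function(d) {
      pos <- d[d > 0]
      if (length(pos)) min(pos) else 0
    })
    adj <- pmax(dmat - rho, 0)
    target <- log2(k)
    lo <- rep(0, n)
    hi <- rep(1, n)
    for (rep_i in 1:60) {                        # grow hi until f(hi) >= target
      f_hi <- rowSums(exp(-adj / hi))
      grow <- f_hi < target
      if (!any(grow)) break
      hi[grow] <- hi[grow] * 2
    }
    for (it in 1:64) {                           # bisection, tol << 1e-5
      mid <- (lo + hi) / 2
      f_mid <- rowSums(exp(-adj / mid))
      ge <- f_mid >= target
      hi[ge] <- mid[ge]
      lo[!ge] <- mid[!ge]
    }
    sigma <- (lo + hi) / 2
    w <- exp(-adj / sigma)
    # rows whose neighbourhood is all duplicates: sigma -> 0, keep the
    # indicator limit exp(0) = 1 on zero-adjusted distances
    zero_sigma <- sigma <= 0 | !is.finite(sigma)
    if (any(zero_sigma))
      w[zero_sigma, ] <- (adj[zero_sigma, , drop = FALSE] == 0) * 1
  }

  W <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                            x = as.vector(w), dims = c(n, n))
  structure(list(w = W, rho = rho, sigma = sigma, n_neighbors = k,
                 degenerate = degenerate, directed = TRUE),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", nrow(x$w), " nodes, ",
      if (x$directed) "directed" else "symmetric",
      ", k = ", x$n_neighbors,
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Fuzzy-union symmetrization of a directed neighbour graph
#'
#' Combines the two directed weights of each edge by the probabilistic
#' t-conorm `w + w' - w * w'`, producing a symmetric graph whose weights
#' remain in `[0, 1]`.
#'
#' @param graph A directed `neighbor_graph` from [smooth_knn_graph()].
#' @return A symmetric `neighbor_graph` (`directed = FALSE`).
#' @export
symmetrize_graph <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  W <- graph$w
  Wt <- Matrix::t(W)
  S <- W + Wt - W * Wt
  Matrix::diag(S) <- 0
  out <- graph
  out$w <- Matrix::drop0(S)
  out$directed <- FALSE
  out
}

# connected component labels of a symmetric sparse adjacency matrix
graph_components <- function(W) {
  n <- nrow(W)
  Wt <- methods::as(W, "TsparseMatrix")
  nbr <- split(Wt@i + 1L, factor(Wt@j + 1L, levels = seq_len(n)))
  lab <- integer(n)
  comp <- 0L
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    lab[s] <- comp
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (u in nbr[[v]]) {
        if (lab[u] == 0L) {
          lab[u] <- comp
          tail <- tail + 1L
          queue[tail] <- u
        }
      }
    }
  }
  lab
}

#' Deterministic spectral embedding of a neighbour graph
#'
#' The built-in reference engine: coordinates are eigenvectors 2..d+1
#' (ascending eigenvalues) of the symmetric normalized graph Laplacian
#' `I - D^{-1/2} W D^{-1/2}`, computed per connected component, with the
#' sign convention that the first nonzero loading of each eigenvector is
#' positive. Components (common for Hamming graphs on nominal blocks)
#' are embedded separately and offset to disjoint ranges along the first
#' coordinate, 10 units apart, so distinct components never overlap.
#'
#' Each eigenvector is winsorized at its 5th/95th percentile (so a
#' handful of rows exiled by a spiky eigenvector rejoin their bulk,
#' while any split whose minority side holds at least 5 percent of the
#' component survives), then scaled to standard deviation
#' `dim_scale * (1 - lambda/lambda_max)^3 * sqrt(m/n)`, where `lambda`
#' is the mode's eigenvalue, `lambda_max` the component's largest
#' eigenvalue, and `m` the component size. The cubic factor lets
#' strong-cut modes (`lambda` near 0) span the full scale while bulk
#' modes of unstructured or near-clique components collapse towards a
#' point; `sqrt(m/n)` keeps the scale global rather than inflating
#' small components.
#'
#' `dim_scale` fixes the engine's coordinate units: spectral
#' eigenvectors are scale-free, and the downstream density clustering
#' stage operates at a fixed radius, so the engine must commit to a
#' scale. The default 1.25 places well-separated cluster modes several
#' radii apart while keeping within-cluster point density high.
#'
#' @param graph A symmetric `neighbor_graph`.
#' @param d Number of embedding dimensions; must satisfy `d < n`.
#' @param dim_scale Target per-dimension standard deviation (default 1.25).
#' @return An n x d numeric coordinate matrix.
#' @export
spectral_embed <- function(graph, d, dim_scale = 1.25) {
  stopifnot(inherits(graph, "neighbor_graph"), !graph$directed)
  W <- graph$w
  n <- nrow(W)
  d <- as.integer(d)
  if (n <= d) stop("need more points than embedding dimensions")
  coords <- matrix(0, n, d)
  if (graph$degenerate) {
    attr(coords, "degenerate") <- TRUE
    return(coords)
  }
  lab <- graph_components(W)
  comp_order <- order(vapply(split(seq_len(n), lab), min, integer(1)))
  running_max <- NULL
  for (ci in comp_order) {
    members <- which(lab == ci)
    m <- length(members)
    if (m == 1L) {
      sub <- matrix(0, 1L, d)
    } else {
      Wd <- as.matrix(W[members, members, drop = FALSE])
      deg <- rowSums(Wd)
      deg[deg <= 0] <- 1
      dsq <- 1 / sqrt(deg)
      L <- diag(m) - Wd * tcrossprod(dsq)
      eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
      vecs <- eig$vectors[, m:1, drop = FALSE]   # ascending eigenvalues
      vals <- rev(eig$values)
      take <- seq(2L, min(d + 1L, m))
      sub <- matrix(0, m, d)
      sub[, seq_along(take)] <- vecs[, take, drop = FALSE]
      lam_max <- max(vals[m], 1e-12)
      rel <- (lam_max - c(vals[take], rep(lam_max, d - length(take)))) /
        lam_max
      for (j in seq_len(d)) {
        v <- sub[, j]
        nz <- which(abs(v) > 1e-12)
        if (length(nz) && v[nz[1L]] < 0) v <- -v
        # winsorize at the 5th/95th percentile: a split whose minority
        # side holds >= 5 percent of the component survives intact,
        # while spiky eigenvectors that exile only a handful of rows
        # are pulled back into the bulk
        q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
        v <- pmin(pmax(v, q[1L]), q[2L])
        s <- stats::sd(v)
        # amplitude follows the mode's position in the component's
        # spectrum: eigenvectors of strong cuts (lambda << lambda_max)
        # keep the full dim_scale, bulk modes of near-clique components
        # (lambda ~ lambda_max) collapse to a point. sqrt(m/n) keeps the
        # scale global: a component holding a fraction f of all rows
        # spans sqrt(f) of the linear extent
        if (is.finite(s) && s > 1e-12)
          v <- (v - mean(v)) / s * dim_scale * max(0, rel[j])^3 *
            sqrt(m / n)
        else v <- v - mean(v)
        sub[, j] <- v
      }
    }
    if (!is.null(running_max))
      sub[, 1L] <- sub[, 1L] - min(sub[, 1L]) + running_max + 10
    running_max <- max(c(running_max, sub[, 1L]))
    coords[members, ] <- sub
  }
  coords
}

#' Embed one feature block
#'
#' Runs the configured engine on a numeric block. The reference pipeline
#' is [pairwise_distances()] under the block's metric, then
#' [smooth_knn_graph()], [symmetrize_graph()] and [spectral_embed()].
#' An external engine (a function in `params$engine`) receives the block
#' and the full parameter bundle, including the seed, and must honour the
#' same contract: `n x n_components` finite coordinates, identical output
#' for identical input and seed.
#'
#' @param block Numeric matrix (rows = individuals).
#' @param params An [embedding_params()] bundle.
#' @param block_name Label stored with the result.
#' @return An object of class `block_embedding`: `coords`
#'   (n x n_components), `block_name`, `params`, logical `degenerate`.
#' @export
embed_block <- function(block, params, block_name = "block") {
  stopifnot(inherits(params, "embedding_params"))
  if (!is.matrix(block)) block <- as.matrix(block)
  if (nrow(block) < params$n_neighbors + 1L)
    stop("block must have at least n_neighbors + 1 rows")
  degenerate <- FALSE
  if (is.function(params$engine)) {
    set.seed(params$seed)
    coords <- params$engine(block, params)
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(block) || ncol(coords) != params$n_components)
      stop("external engine returned coordinates of the wrong shape")
  } else if (identical(params$engine, "reference_spectral")) {
    D <- pairwise_distances(block, params$metric)
    g <- symmetrize_graph(smooth_knn_graph(D, params$n_neighbors))
    coords <- spectral_embed(g, params$n_components, params$dim_scale)
    degenerate <- isTRUE(attr(coords, "degenerate")) || g$degenerate
    attr(coords, "degenerate") <- NULL
  } else {
    stop("unknown embedding engine: ", params$engine)
  }
  if (!all(is.finite(coords)))
    stop("embedding produced non-finite coordinates")
  structure(list(coords = coords, block_name = block_name,
                 params = params, degenerate = degenerate),
            class = "block_embedding")
}

#' @export
print.block_embedding <- function(x, ...) {
  cat("<block_embedding> '", x$block_name, "': ", nrow(x$coords), " x ",
      ncol(x$coords), " (metric ", x$params$metric, ")",
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}
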