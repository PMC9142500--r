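manual_graph <- function(W, directed = FALSE, degenerate = FALSE,
                         n_neighbors = 2L) {
  structure(list(w = methods::as(W, "CsparseMatrix"),
                 rho = rep(0, nrow(W)), sigma = rep(1, nrow(W)),
                 n_neighbors = n_neighbors, degenerate = degenerate,
                 directed = directed),
            class = "neighbor_graph")
}

test_that("smooth-kNN calibration hits the log2(k) weight budget", {
  set.seed(1)
  X <- matrix(rnorm(80 * 3), 80, 3)
  D <- pairwise_distances(X, "euclidean")
  g <- smooth_knn_graph(D, 8)
  expect_s3_class(g, "neighbor_graph")
  expect_true(g$directed)
  sums <- Matrix::rowSums(g$w)
  expect_lt(max(abs(sums - log2(8))), 1e-4)
  # the nearest neighbour always carries weight 1
  for (i in 1:10) {
    d <- D[i, ]; d[i] <- Inf
    expect_equal(g$w[i, which.min(d)], 1)
  }
  expect_error(smooth_knn_graph(D, 80), "smaller")
})

test_that("duplicated and degenerate inputs stay finite", {
  X <- rbind(matrix(rnorm(20), 10, 2),
             matrix(1.5, 5, 2))          # five exact duplicates
  g <- smooth_knn_graph(pairwise_distances(X, "euclidean"), 4)
  expect_true(all(is.finite(g$w@x)))
  expect_true(all(g$w@x >= 0 & g$w@x <= 1))

  Dz <- pairwise_distances(matrix(2, 12, 3), "euclidean")  # all identical
  gz <- smooth_knn_graph(Dz, 4)
  expect_true(gz$degenerate)
  expect_true(all(gz$w@x == 1))
})

test_that("fuzzy union symmetrization follows w + w' - w w'", {
  W <- Matrix::sparseMatrix(i = c(1, 2, 1, 3), j = c(2, 1, 3, 2),
                            x = c(0.5, 0.5, 1, 0.25), dims = c(3, 3))
  g <- symmetrize_graph(manual_graph(W, directed = TRUE))
  S <- as.matrix(g$w)
  expect_false(g$directed)
  expect_equal(S[1, 2], 0.5 + 0.5 - 0.25)   # 0.75
  expect_equal(S[2, 1], 0.75)
  expect_equal(S[1, 3], 1)                  # 1 + 0 - 0
  expect_equal(S[3, 1], 1)
  expect_equal(S[2, 3], 0.25)
  expect_true(isSymmetric(S))
  expect_true(all(diag(S) == 0))
})

test_that("spectral embedding solves the 3-node path in closed form", {
  W <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2),
                            x = 1, dims = c(3, 3))
  co <- spectral_embed(manual_graph(W), 1)
  # second Laplacian eigenvector of the path is (1, 0, -1)/sqrt(2):
  # middle node sits strictly between the endpoints, first loading positive
  expect_gt(co[1, 1], co[2, 1])
  expect_gt(co[2, 1], co[3, 1])
  expect_lt(abs(co[2, 1] - (co[1, 1] + co[3, 1]) / 2), 1e-8)
  # deterministic
  expect_identical(co, spectral_embed(manual_graph(W), 1))
})

test_that("disconnected components occupy disjoint offset ranges", {
  clique <- function(members, n) {
    idx <- expand.grid(i = members, j = members)
    idx <- idx[idx$i != idx$j, ]
    Matrix::sparseMatrix(i = idx$i, j = idx$j, x = 1, dims = c(n, n))
  }
  W <- clique(1:3, 6) + clique(4:6, 6)
  co <- spectral_embed(manual_graph(W), 1)
  expect_gte(min(co[4:6, 1]) - max(co[1:3, 1]), 10)
  # within a clique the non-trivial modes carry no structure: collapsed
  expect_lt(max(abs(co[1:3, 1] - mean(co[1:3, 1]))), 1e-8)
  expect_error(spectral_embed(manual_graph(W), 6), "more points")
})

test_that("embed_block separates well-separated blobs", {
  set.seed(3)
  X <- rbind(matrix(rnorm(150 * 3), ncol = 3),
             matrix(rnorm(150 * 3, mean = 8), ncol = 3))
  lab <- rep(1:2, each = 150)
  e <- embed_block(X, embedding_params(n_neighbors = 15,
                                       metric = "euclidean"), "blobs")
  expect_equal(dim(e$coords), c(300L, 2L))
  sil <- cluster::silhouette(lab, stats::dist(e$coords))
  expect_gt(mean(sil[, 3]), 0.5)
  # neighborhood preservation: 10-NN purity in the embedding
  D <- as.matrix(stats::dist(e$coords))
  pur <- vapply(1:300, function(i) {
    d <- D[i, ]; d[i] <- Inf
    mean(lab[order(d)[1:10]] == lab[i])
  }, numeric(1))
  expect_gte(mean(pur), 0.9)
})

test_that("embedding is reproducible and stable under row permutation", {
  set.seed(8)
  # one elongated connected cloud: the leading non-trivial mode is
  # unique, so row order can enter only through a global sign
  X <- cbind(rnorm(100, sd = 4), rnorm(100, sd = 0.5))
  par <- embedding_params(n_neighbors = 10, metric = "euclidean",
                          n_components = 1L)
  e1 <- embed_block(X, par, "b")
  expect_identical(e1$coords, embed_block(X, par, "b")$coords)
  perm <- sample(nrow(X))
  e2 <- embed_block(X[perm, ], par, "b")
  back <- e2$coords[order(perm), , drop = FALSE]
  expect_gt(abs(stats::cor(e1$coords[, 1], back[, 1])), 0.999)
})

test_that("engine contract: external engines and degeneracy propagate", {
  X <- matrix(rnorm(100), 50, 2)
  ext <- function(block, params) {
    set.seed(params$seed)
    matrix(stats::rnorm(nrow(block) * params$n_components),
           ncol = params$n_components)
  }
  par <- embedding_params(n_neighbors = 5, seed = 99, engine = ext)
  e1 <- embed_block(X, par, "x")
  e2 <- embed_block(X, par, "x")
  expect_identical(e1$coords, e2$coords)   # seeded determinism contract

  bad <- function(block, params) matrix(0, 2, 2)
  expect_error(embed_block(X, embedding_params(n_neighbors = 5,
                                               engine = bad), "x"),
               "wrong shape")
  expect_error(embed_block(X, embedding_params(n_neighbors = 5,
                                               engine = "umap_gpu"), "x"),
               "unknown embedding engine")
  expect_error(embed_block(X[1:4, ], embedding_params(n_neighbors = 5), "x"),
               "at least")

  # a block of identical rows is degenerate: flat coordinates, flag set
  flat <- embed_block(matrix(1, 30, 3), embedding_params(n_neighbors = 5), "x")
  expect_true(flat$degenerate)
  expect_true(all(flat$coords == 0))
})
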