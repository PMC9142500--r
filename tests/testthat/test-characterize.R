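two_cluster_fixture <- function() {
  sch <- feature_schema(list(
    feature_spec("x", "continuous"),
    feature_spec("vote", "nominal", levels = c("yes", "no", "abstain"))))
  ds <- mixed_dataset(data.frame(
    x = c(1, 2, 3, 10, 20),
    vote = c("yes", "yes", "no", "no", "no"),
    stringsAsFactors = FALSE), sch)
  labels <- c(1L, 1L, 1L, 2L, 2L)
  list(ds = ds, labels = labels)
}

test_that("continuous cells report mean and n-1 SEM, categorical count (percent)", {
  fx <- two_cluster_fixture()
  s <- summarize_clusters(fx$ds, fx$labels)
  expect_equal(unname(s$sizes), c(3L, 2L))
  c1 <- s$continuous[s$continuous$cluster == 1, ]
  expect_equal(c1$mean, 2)
  expect_equal(c1$sem, 1 / sqrt(3), tolerance = 1e-4)  # sd 1 / sqrt(3) = 0.577
  v1 <- s$categorical[s$categorical$cluster == 1, ]
  expect_equal(v1$count[v1$level == "yes"], 2L)
  expect_equal(v1$percent[v1$level == "yes"], 66.67)
  expect_equal(v1$count[v1$level == "no"], 1L)
  expect_equal(v1$percent[v1$level == "no"], 33.33)
  # a level absent from the cluster still appears with count 0, percent 0
  expect_equal(v1$count[v1$level == "abstain"], 0L)
  expect_equal(v1$percent[v1$level == "abstain"], 0)
})

test_that("a size-1 cluster reports SEM 0 with a degeneracy flag", {
  fx <- two_cluster_fixture()
  s <- summarize_clusters(fx$ds, c(1L, 1L, 1L, 1L, 2L))
  c2 <- s$continuous[s$continuous$cluster == 2, ]
  expect_equal(c2$sem, 0)
  expect_true(c2$degenerate)
})

test_that("noise rows are excluded unless requested", {
  fx <- two_cluster_fixture()
  labels <- c(1L, 1L, 1L, -1L, -1L)
  s <- summarize_clusters(fx$ds, labels)
  expect_equal(names(s$sizes), "1")
  s2 <- summarize_clusters(fx$ds, labels, include_noise = TRUE)
  expect_true("-1" %in% names(s2$sizes))
  expect_equal(unname(s2$sizes["-1"]), 2L)
})

test_that("counts sum to cluster size and percentages to 100 on synthetic data", {
  sim <- generate_mixed_data(default_nfhs_like_config(400, 3, 1, seed = 5))
  s <- summarize_clusters(sim$dataset, sim$labels)
  for (k in names(s$sizes)) {
    sub <- s$categorical[s$categorical$cluster == as.integer(k), ]
    for (nm in unique(sub$feature)) {
      rows <- sub[sub$feature == nm, ]
      expect_equal(sum(rows$count), unname(s$sizes[k]))
      expect_gte(sum(rows$percent), 99.95)
      expect_lte(sum(rows$percent), 100.05)
    }
  }
})

test_that("summaries are invariant under row permutation", {
  sim <- generate_mixed_data(default_nfhs_like_config(200, 2, 1, seed = 6))
  s1 <- summarize_clusters(sim$dataset, sim$labels)
  perm <- sample(200)
  ds_p <- mixed_dataset(sim$dataset$data[perm, , drop = FALSE],
                        sim$dataset$schema,
                        row_ids = sim$dataset$row_ids[perm])
  s2 <- summarize_clusters(ds_p, sim$labels[perm])
  expect_equal(s1$sizes, s2$sizes)
  expect_equal(s1$continuous, s2$continuous)
  expect_equal(s1$categorical, s2$categorical)
})

test_that("the long-format file round-trips and the wide rendering matches Table-1 style", {
  fx <- two_cluster_fixture()
  s <- summarize_clusters(fx$ds, fx$labels)
  p <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, p)
  back <- read_summary(p)
  expect_equal(back$sizes, s$sizes)
  expect_equal(back$continuous, s$continuous, tolerance = 1e-12)
  expect_equal(back$categorical, s$categorical, tolerance = 1e-12)

  wide <- render_summary(s)
  expect_equal(colnames(wide), c("Cluster 1", "Cluster 2"))
  # percentages printed to two decimals inside "count (percent)" cells
  expect_equal(unname(wide["vote: yes", "Cluster 1"]), "2 (66.67)")
  expect_equal(unname(wide["vote: no", "Cluster 2"]), "2 (100.00)")
  expect_match(unname(wide["x", "Cluster 1"]), "±")
})

test_that("cluster means track configured generator means within 3 SEM", {
  cfg <- default_nfhs_like_config(2000, 3, 1, seed = 17)
  sim <- generate_mixed_data(cfg)
  s <- summarize_clusters(sim$dataset, sim$labels)
  amap <- ((1:3 - 1) %% 4) + 1
  ok <- 0; total <- 0
  for (nm in features_of_type(cfg$schema, "continuous")) {
    mu <- cfg$continuous_params[[nm]]$mean
    for (k in 1:3) {
      row <- s$continuous[s$continuous$cluster == k &
                            s$continuous$feature == nm, ]
      total <- total + 1
      ok <- ok + (abs(row$mean - mu[k]) <= 3 * row$sem)
    }
  }
  expect_gte(ok / total, 0.99 - 1e-9)
})
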