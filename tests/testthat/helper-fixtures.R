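# Shared fixtures: built in code, no files.

tiny_schema <- function() {
  feature_schema(list(
    feature_spec("age", "continuous", category = "sociodemographic"),
    feature_spec("bmi", "continuous", category = "sociodemographic"),
    feature_spec("milk", "ordinal",
                 levels = c("Never", "Weekly", "Occasionally", "Daily"),
                 category = "food"),
    feature_spec("smoker", "ordinal", levels = c("No", "Yes"),
                 category = "addiction"),
    feature_spec("sex", "nominal", levels = c("Male", "Female")),
    feature_spec("residence", "nominal", levels = c("Urban", "Rural"))
  ))
}

tiny_dataset <- function() {
  mixed_dataset(data.frame(
    age = c(30, 45, 52), bmi = c(22.5, 27.1, 24.8),
    milk = c("Daily", "Never", "Weekly"),
    smoker = c("No", "Yes", "No"),
    sex = c("Male", "Female", "Female"),
    residence = c("Urban", "Rural", "Urban"),
    stringsAsFactors = FALSE), tiny_schema())
}

# near-degenerate planted mixture over the packaged schema: continuous
# means 10 SD apart, 99.95 percent of categorical mass on one
# cluster-specific level
strong_separation_config <- function(n, k = 3, seed = 1) {
  sch <- nfhs4_schema()
  cont <- list(); ordp <- list(); nomp <- list()
  for (nm in features_of_type(sch, "continuous"))
    cont[[nm]] <- list(mean = 10 * (seq_len(k) - 1), sd = rep(1, k))
  peak <- function(L, j) {
    p <- rep(5e-4 / (L - 1), L)
    p[(j %% L) + 1] <- 0.9995
    p
  }
  for (nm in features_of_type(sch, "ordinal")) {
    L <- length(sch$features[[nm]]$levels)
    ordp[[nm]] <- t(vapply(seq_len(k), function(j) peak(L, j), numeric(L)))
  }
  for (nm in features_of_type(sch, "nominal")) {
    L <- length(sch$features[[nm]]$levels)
    nomp[[nm]] <- t(vapply(seq_len(k), function(j) peak(L, j), numeric(L)))
  }
  synth_config(n, k, rep(1 / k, k), sch, cont, ordp, nomp, seed = seed)
}

# canonical form of a clustering: clusters renumbered by first
# appearance, noise kept as -1; two labelings are the same partition iff
# their canonical forms are identical
canonical_partition <- function(labels) {
  labels <- as.integer(labels)
  out <- labels
  seen <- integer(0)
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l == -1L) next
    pos <- match(l, seen)
    if (is.na(pos)) {
      seen <- c(seen, l)
      pos <- length(seen)
    }
    out[i] <- pos
  }
  out
}

# adjusted Rand index via mclust (independent of the package under test)
ari <- function(a, b) mclust::adjustedRandIndex(as.integer(a), as.integer(b))

# scalar-loop oracle for pairwise distance matrices
pairwise_oracle <- function(block, fn) {
  n <- nrow(block)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- fn(block[i, ], block[j, ])
  D
}
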