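test_that("feature_spec enforces its typing invariants", {
  expect_s3_class(feature_spec("age", "continuous"), "feature_spec")
  expect_error(feature_spec("", "continuous"), "non-empty")
  expect_error(feature_spec("x", "ordinal"), "levels")
  expect_error(feature_spec("x", "nominal", levels = c("a", "a")), "unique")
  expect_error(feature_spec("x", "continuous", levels = c("a")), "levels")
  expect_error(feature_schema(list(feature_spec("a", "continuous"),
                                   feature_spec("a", "continuous"))),
               "duplicate")
})

test_that("packaged survey schema has the published structure", {
  sch <- nfhs4_schema()
  expect_equal(n_features(sch), 36L)
  cnt <- schema_counts(sch)
  expect_equal(unname(cnt["continuous"]), 4L)
  expect_equal(unname(cnt["nominal"]), 7L)
  expect_equal(unname(cnt["ordinal"]), 25L)
  cat_cnt <- category_counts(sch)
  expect_equal(unname(cat_cnt["comorbidity"]), 6L)
  expect_equal(unname(cat_cnt["food"]), 9L)
  expect_equal(unname(cat_cnt["addiction"]), 2L)
  expect_equal(unname(cat_cnt["sociodemographic"]), 8L)
  expect_equal(unname(cat_cnt["living"]), 11L)
  # food-frequency order is rank order Never < Weekly < Occasionally < Daily
  expect_equal(sch$features[["milk_curd_freq"]]$levels,
               c("Never", "Weekly", "Occasionally", "Daily"))
})

test_that("schema files round-trip through yaml and json", {
  sch <- tiny_schema()
  for (ext in c("yaml", "json")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_schema(sch, p)
    back <- read_schema(p)
    expect_equal(feature_names(back), feature_names(sch))
    expect_equal(feature_types(back), feature_types(sch))
    expect_equal(back$features[["milk"]]$levels, sch$features[["milk"]]$levels)
  }
})

test_that("load_table validates, drops and errors per policy", {
  sch <- tiny_schema()
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,bmi,milk,smoker,sex,residence",
               "30,22.5,Daily,No,Male,Urban",
               "45,27.1,Never,Yes,Female,Rural",
               "52,24.8,Weekly,No,Female,Urban"), p)
  ds <- load_table(p, sch)
  expect_s3_class(ds, "mixed_dataset")
  expect_equal(n_rows(ds), 3L)

  # one row with an empty cell: dropped under the default policy
  writeLines(c("age,bmi,milk,smoker,sex,residence",
               "30,22.5,Daily,No,Male,Urban",
               "45,,Never,Yes,Female,Rural",
               "52,24.8,Weekly,No,Female,Urban"), p)
  expect_message(ds2 <- load_table(p, sch), "dropped 1 of 3")
  expect_equal(n_rows(ds2), 2L)
  expect_equal(attr(ds2, "dropped"), 1L)
  expect_error(load_table(p, sch, policy = "strict"), "row_2")

  # unknown level is invalid, not silently coerced
  writeLines(c("age,bmi,milk,smoker,sex,residence",
               "30,22.5,Hourly,No,Male,Urban"), p)
  expect_error(suppressMessages(load_table(p, sch)), "no valid rows")

  # a missing schema column is a hard error naming the column
  writeLines(c("age,bmi,milk,smoker,sex",
               "30,22.5,Daily,No,Male"), p)
  expect_error(load_table(p, sch), "residence")
})

test_that("write_table / load_table is the identity on valid data", {
  ds <- tiny_dataset()
  for (ext in c(".csv", ".tsv")) {
    p <- withr::local_tempfile(fileext = ext)
    write_table(ds, p)
    back <- load_table(p, tiny_schema())
    expect_equal(back$data, ds$data)
    expect_equal(back$row_ids, ds$row_ids)
  }
})

test_that("encoding is rank-preserving, stable and invertible", {
  ds <- tiny_dataset()
  blocks <- encode_features(ds)
  expect_s3_class(blocks, "encoded_blocks")
  expect_equal(ncol(blocks$continuous) + ncol(blocks$ordinal) +
                 ncol(blocks$nominal), n_features(ds$schema))
  # "Daily" is rank 4 of the four food-frequency levels
  expect_equal(unname(blocks$ordinal[1L, "milk"]), 4L)
  expect_equal(unname(blocks$ordinal[2L, "milk"]), 1L)
  # equal nominal values share a code
  expect_equal(blocks$nominal[2L, "sex"], blocks$nominal[3L, "sex"])
  # codes are 1-based consecutive ranks in declared order
  sch <- ds$schema
  for (nm in features_of_type(sch, "ordinal")) {
    lv <- sch$features[[nm]]$levels
    codes <- match(ds$data[[nm]], lv)
    expect_identical(as.integer(blocks$ordinal[, nm]), as.integer(codes))
  }
  expect_equal(decode_features(blocks)$data, ds$data)
})

test_that("ordinal encoding preserves declared rank order as a property", {
  sch <- nfhs4_schema()
  sim <- generate_mixed_data(default_nfhs_like_config(60, 2, 1, seed = 3))
  blocks <- encode_features(sim$dataset)
  for (nm in features_of_type(sch, "ordinal")) {
    lv <- sch$features[[nm]]$levels
    ranks <- match(sim$dataset$data[[nm]], lv)
    expect_true(all((blocks$ordinal[, nm] < max(blocks$ordinal[, nm])) ==
                      (ranks < max(ranks))))
    expect_identical(order(blocks$ordinal[, nm]), order(ranks))
  }
})

test_that("IQR outlier fences remove extreme rows independently per feature", {
  sch <- feature_schema(list(feature_spec("x", "continuous"),
                             feature_spec("g", "nominal", levels = "a")))
  df <- data.frame(x = c(rep(1, 10), 100), g = "a",
                   stringsAsFactors = FALSE)
  ds <- mixed_dataset(df, sch)
  out <- suppressMessages(remove_outliers(ds, "x"))
  expect_equal(n_rows(out), 10L)
  expect_equal(unname(attr(out, "outlier_counts")["x"]), 1L)
  # IQR = 0: fences collapse to the common value, nothing removed
  ds_eq <- mixed_dataset(data.frame(x = rep(2, 8), g = "a",
                                    stringsAsFactors = FALSE), sch)
  expect_equal(n_rows(remove_outliers(ds_eq, "x")), 8L)
  # disabled fence leaves the data untouched
  expect_equal(n_rows(remove_outliers(ds, "x", k = Inf)), 11L)
  expect_error(remove_outliers(ds, "g"), "not continuous")
})
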