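test_that("schema defines the 18 parameters with the published groupings", {
  sch <- hsct_schema()
  expect_length(sch$features, 18)
  expect_false(anyDuplicated(schema_feature_names(sch)) > 0)
  expect_identical(sch$outcome_levels, c("alive", "dead", "alive_lt24"))

  # spot checks of the coded groupings and clinical ranges
  expect_identical(sch$features$gender$levels, c(male = 1, female = 2))
  expect_identical(unname(sch$features$donor_type$levels), c(1, 2, 3))
  expect_equal(sch$features$crea_day2$range, c(0.6, 5.3))
  expect_equal(sch$features$plt_day2$range, c(3, 922.2))
  expect_equal(sch$features$age$range, c(18, 88))

  # every categorical feature uses consecutive integer codes
  for (f in sch$features) {
    if (f$kind == "categorical") {
      codes <- sort(unname(f$levels))
      expect_identical(diff(codes), rep(1, length(codes) - 1))
    } else {
      expect_lt(f$range[1], f$range[2])
    }
  }
})

test_that("report abbreviations map one-to-one onto schema features", {
  ab <- parameter_abbreviations()
  expect_length(ab, 18)
  expect_setequal(unname(ab), schema_feature_names())
  expect_false(anyDuplicated(names(ab)) > 0)
})

test_that("schema JSON export round-trips the feature definitions", {
  js <- jsonlite::fromJSON(schema_to_json(), simplifyVector = FALSE)
  expect_length(js$features, 18)
  expect_identical(unlist(js$outcome_levels), c("alive", "dead", "alive_lt24"))
  crea <- Filter(function(f) f$name == "crea_day2", js$features)[[1]]
  expect_equal(unlist(crea$range), c(0.6, 5.3))
})

test_that("cohort validation enforces the schema contract", {
  df <- tiny_cohort_df()
  co <- as_cohort(df)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co), 3)

  expect_error(as_cohort(df[, setdiff(names(df), "cgvhd")]), "cgvhd")
  bad <- df; bad$disease[2] <- 4
  expect_error(as_cohort(bad), "disease.*row.*2")
  bad <- df; bad$crea_day2[3] <- 9.9
  expect_error(as_cohort(bad), "crea_day2.*row.*3")
  bad <- df; bad$age[1] <- NA
  expect_error(as_cohort(bad), "missing")
  bad <- df; bad$outcome[1] <- "lost"
  expect_error(as_cohort(bad), "outcome")
})

test_that("long-form outcome labels and shuffled headers are accepted", {
  df <- tiny_cohort_df()
  df$outcome <- c("Alive", "DEAD", "Alive but follow-up less than 24 months")
  names(df)[names(df) == "age"] <- " Age "
  df <- df[, sample(ncol(df))]
  co <- as_cohort(df)
  expect_identical(as.character(co$outcome),
                   c("alive", "dead", "alive_lt24"))
  # columns come back in schema order regardless of file order
  expect_identical(names(co), c(schema_feature_names(), "outcome"))
})

test_that("read/write round-trip is exact on generated cohorts", {
  for (seed in c(2, 31)) {
    co <- generate_cohort(60, seed = seed, constraint = NULL)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path)
    back <- read_cohort(path)
    a <- as.data.frame(co); b <- as.data.frame(back)
    attributes(a)[c("schema", "provenance", "class")] <- NULL
    attributes(b)[c("schema", "provenance", "class")] <- NULL
    expect_identical(a, b)
  }
  expect_error(read_cohort(file.path(tempdir(), "absent.csv")), "not found")
})

test_that("encode is a pure projection in schema order", {
  co <- generate_cohort(50, seed = 5, constraint = NULL)
  enc <- encode_cohort(co)
  expect_identical(dim(enc$x), c(50L, 18L))
  expect_identical(colnames(enc$x), schema_feature_names())
  expect_true(all(enc$labels %in% 0:2))
  expect_identical(enc$labels, as.integer(co$outcome) - 1L)

  one <- encode_cohort(co, "age")
  expect_identical(dim(one$x), c(50L, 1L))
  expect_identical(as.numeric(one$x), co$age)

  # pattern order is canonicalised to schema order
  two <- encode_cohort(co, c("crea_day2", "gender"))
  expect_identical(colnames(two$x), c("gender", "crea_day2"))

  # permuting records permutes rows identically and changes nothing else
  perm <- sample(nrow(co))
  cop <- as_cohort(as.data.frame(co)[perm, ])
  encp <- encode_cohort(cop, c("age", "ldh_day2"))
  expect_identical(encp$x,
                   encode_cohort(co, c("age", "ldh_day2"))$x[perm, ])

  expect_error(encode_cohort(co, character(0)), "non-empty")
  expect_error(encode_cohort(co, "bmi"), "not in schema")
})
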