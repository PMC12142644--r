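test_that("CSV parsing handles absent follow-ups, bad ids, and empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy_csv(path)
  co <- read_cohort(path, toy_schema)
  expect_s3_class(co, "cohort")
  expect_equal(n_records(co), 3)
  expect_equal(co$i2_present, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(co$i2[2, ])))
  expect_equal(co$i1[2, ], c(f1 = 3, f2 = 4))
  expect_equal(co$i2[3, ], c(f1 = 5.5, f2 = 6.5))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,f1,f2,age", "A,1,2,60", "A,3,4,70"), dup)
  expect_error(read_cohort(dup, toy_schema), "A")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,f1,f2,age", "A,1,x,60"), bad)
  expect_error(read_cohort(bad, toy_schema), "f2")

  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,f1,f2,age", hdr)
  expect_equal(n_records(read_cohort(hdr, toy_schema)), 0)
})

test_that("cohort CSV + sidecar round-trips through write/read", {
  co <- normalize_cohort(toy_cohort(seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  schema <- list(id = "patient_id", features = co$feature_names,
                 labels = co$label_names, synthetic_col = "i2_synthetic")
  back <- read_cohort(path, schema, ranges_path = paste0(path, ".meta.json"))
  expect_true(back$normalized)
  expect_equal(back$i1, co$i1, tolerance = 1e-12)
  expect_equal(back$i2_present, co$i2_present)
  expect_equal(back$feature_ranges$min, co$feature_ranges$min)
  raw <- denormalize_cohort(back)
  expect_equal(raw$i1, denormalize_cohort(co)$i1, tolerance = 1e-9)
})

test_that("min-max normalization maps endpoints, midpoints, constants", {
  i1 <- matrix(c(10, 20, 30, 5, 5, 5), ncol = 2)
  co <- cohort(i1, matrix(0, 3, 1))
  nc <- normalize_cohort(co)
  expect_equal(nc$i1[, 1], c(-1, 0, 1))
  expect_equal(nc$i1[, 2], c(0, 0, 0))   # constant feature -> 0

  dn <- denormalize_cohort(nc)
  expect_equal(dn$i1[, 1], c(10, 20, 30))
  expect_equal(dn$i1[, 2], c(5, 5, 5))   # constant restored

  # supplied ranges clip out-of-range values
  rg <- tibble::tibble(feature = c("f1", "f2"), min = c(12, 0), max = c(28, 10))
  colnames(i1) <- c("f1", "f2")
  cc <- normalize_cohort(cohort(i1, matrix(0, 3, 1),
                                feature_names = c("f1", "f2")), ranges = rg)
  expect_equal(unname(cc$i1[1, 1]), -1)  # 10 < 12, clipped
  expect_equal(unname(cc$i1[3, 1]), 1)   # 30 > 28, clipped
})

test_that("normalize/denormalize round-trip is the identity on in-range data", {
  co <- toy_cohort(n = 30, d = 6, n_paired = 12, seed = 11)
  rt <- denormalize_cohort(normalize_cohort(co))
  expect_lt(max(abs(rt$i1 - co$i1)), 1e-9)
  expect_lt(max(abs(rt$i2 - co$i2), na.rm = TRUE), 1e-9)
  expect_error(denormalize_cohort(co), "not normalized")
})

test_that("chained-regression imputation fills entries and honors contracts", {
  co <- toy_cohort(seed = 3)
  expect_identical(impute_missing_features(co), co)  # nothing missing

  # perfectly collinear pair: x2 = 2 * x1; closed-form regression oracle
  x1 <- c(1, 2, 3, 4, 5)
  i1 <- cbind(f1 = x1, f2 = 2 * x1, f3 = c(5, 4, 3, 2, 1))
  i1[3, 2] <- NA
  com <- cohort(i1, matrix(0, 5, 1))
  imp <- impute_missing_features(com)
  expect_equal(unname(imp$i1[3, 2]), 2 * x1[3], tolerance = 1e-6)
  # observed entries preserved exactly
  expect_identical(imp$i1[-3, ], com$i1[-3, ])
  expect_identical(imp$i1[3, c(1, 3)], com$i1[3, c(1, 3)])

  i1[, 2] <- NA
  expect_error(impute_missing_features(cohort(i1, matrix(0, 5, 1))), "f2")
})

test_that("imputation also fills follow-up vectors", {
  co <- toy_cohort(n = 40, d = 5, n_paired = 20, seed = 9)
  co$i2[4, 2] <- NA
  imp <- impute_missing_features(co)
  expect_false(anyNA(imp$i2[imp$i2_present, ]))
  expect_true(is.finite(imp$i2[4, 2]))
})

test_that("split sizes follow per-stratum ceiling arithmetic", {
  co <- toy_cohort(n = 10, d = 2, n_paired = 10, seed = 5)
  sp <- split_cohort(co, test_frac = 0.2, val_frac = 0.1, seed = 1)
  expect_equal(n_records(sp$test), 2)
  expect_equal(n_records(sp$validation), 1)
  expect_equal(n_records(sp$train), 7)

  # same seed -> identical membership; different seed -> same sizes
  sp2 <- split_cohort(co, seed = 1)
  expect_identical(sp2$test$patient_id, sp$test$patient_id)
  expect_identical(sp2$train$patient_id, sp$train$patient_id)
  sp3 <- split_cohort(co, seed = 2)
  expect_equal(n_records(sp3$test), 2)

  expect_error(split_cohort(toy_cohort(n = 5, n_paired = 1), seed = 1),
               "at least 2")
})

test_that("split cell sizes match closed-form arithmetic for all small cohorts", {
  for (n_long in c(2, 3, 7, 19, 50)) {
    for (n_nonlong in c(0, 1, 13, 50)) {
      co <- toy_cohort(n = n_long + n_nonlong, d = 2, n_paired = n_long,
                       seed = n_long + n_nonlong)
      sp <- split_cohort(co, 0.2, 0.1, seed = 42)
      sz <- split_sizes(sp)
      n_test <- ceiling(0.2 * n_long)
      pool_long <- n_long - n_test
      expect_equal(sz$longitudinal[sz$split == "test"], n_test)
      expect_equal(sz$non_longitudinal[sz$split == "test"], 0)
      expect_equal(sz$longitudinal[sz$split == "validation"],
                   ceiling(0.1 * pool_long))
      expect_equal(sz$non_longitudinal[sz$split == "validation"],
                   ceiling(0.1 * n_nonlong))
      expect_equal(sz$longitudinal[sz$split == "train"],
                   pool_long - ceiling(0.1 * pool_long))
      expect_equal(sz$non_longitudinal[sz$split == "train"],
                   n_nonlong - ceiling(0.1 * n_nonlong))
      # no test record lacks a real follow-up; ids disjoint
      expect_true(all(sp$test$i2_present & !sp$test$i2_synthetic))
      ids <- c(sp$train$patient_id, sp$validation$patient_id, sp$test$patient_id)
      expect_equal(anyDuplicated(ids), 0)
    }
  }
})
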