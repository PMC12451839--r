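test_that("long table round-trips through CSV preserving every field", {
  sim <- sim_caudate(1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_table(sim$data, path)
  back <- read_long_table(path)
  for (col in c("subject_id", "wave", "sex", "region", "software")) {
    expect_identical(back[[col]], sim$data[[col]])
  }
  # numeric fields survive the decimal text round trip
  expect_equal(back$age, sim$data$age, tolerance = 1e-12)
  expect_equal(back$volume, sim$data$volume, tolerance = 1e-12)
  expect_equal(back$euler, sim$data$euler, tolerance = 1e-12)
})

test_that("reading rejects malformed input with row-indexed diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,wave,age,sex,region,volume",
               "S1,1,8.0,female,caudate,4500",
               "S1,2,8.5,female,caudate,NA",
               "S1,3,9.0,female,caudate,4400"), path)
  expect_error(read_long_table(path), "volume.*row 2")

  writeLines(c("subject_id,wave,age,sex,volume",
               "S1,1,8.0,female,4500"), path)
  expect_error(read_long_table(path), "missing required column.*region")

  # column-name mapping picks up nonstandard headers
  writeLines(c("SID,wave,age,sex,region,volume",
               "S1,1,8.0,female,caudate,4500"), path)
  d <- read_long_table(path, col_map = c(subject_id = "SID"))
  expect_equal(d$subject_id, "S1")
})

test_that("dataset invariants are enforced at construction", {
  base <- data.frame(subject_id = "S1", wave = 1:2, age = c(8, 8.5),
                     sex = "female", region = "caudate", volume = c(100, 110))
  expect_s3_class(long_volumes(base), "long_volumes")

  bad_age <- base; bad_age$age[2] <- -1
  expect_error(long_volumes(bad_age), "age")
  bad_vol <- base; bad_vol$volume[1] <- 0
  expect_error(long_volumes(bad_vol), "volume")
  bad_sex <- base; bad_sex$sex <- "other"
  expect_error(long_volumes(bad_sex), "sex")
  bad_region <- base; bad_region$region <- "cerebellum"
  expect_error(long_volumes(bad_region), "region")
  dup <- rbind(base, base[1, ])
  expect_error(long_volumes(dup), "duplicate")
  nonmono <- base; nonmono$age <- c(9, 8.5)
  expect_error(long_volumes(nonmono), "strictly increasing")
})

test_that("average_hemispheres is the symmetric bounded mean", {
  expect_equal(average_hemispheres(100, 100), 100)
  expect_equal(average_hemispheres(4000, 4200), 4100)
  set.seed(7)
  a <- runif(50, 100, 9000); b <- runif(50, 100, 9000)
  expect_equal(average_hemispheres(a, b), average_hemispheres(b, a))
  expect_true(all(average_hemispheres(a, b) >= pmin(a, b) &
                    average_hemispheres(a, b) <= pmax(a, b)))
  expect_error(average_hemispheres(-1, 10), "> 0")
})

test_that("volume rescaling divides, records, refuses twice, and inverts", {
  d <- long_volumes(data.frame(subject_id = "S1", wave = 1, age = 10,
                               sex = "female", region = "cortical_gm",
                               volume = 508972))
  r <- rescale_volumes(d, "cortical_gm", 100)
  expect_equal(r$volume, 5089.72)
  expect_equal(attr(r, "rescale")[["cortical_gm"]], 100)
  expect_error(rescale_volumes(r, "cortical_gm", 100), "twice")
  expect_equal(rescale_volumes(d, "cortical_gm", 1)$volume, d$volume)
  expect_equal(unrescale_volumes(r)$volume, d$volume)
  expect_length(attr(unrescale_volumes(r), "rescale"), 0)
})
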