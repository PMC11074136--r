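test_that("valid rows pass through filtered to the requested metric", {
  path <- write_gbd_fixture(gbd_lines(
    location = c("Kenya", "Nepal", "USA", "USA"),
    year = c(1990, 1990, 1990, 1990),
    val = c(0.48, 0.49, 10.90, 99),
    metric = c("Rate", "Rate", "Rate", "Number")
  ))
  rows <- read_gbd_csv(path, "Rate")
  expect_equal(nrow(rows), 3)
  expect_equal(rows$location, c("Kenya", "Nepal", "USA"))
  expect_equal(rows$val, c(0.48, 0.49, 10.90))
  expect_type(rows$year, "integer")
})

test_that("rows with unparseable values are dropped with a warning", {
  path <- write_gbd_fixture(gbd_lines(
    location = c("A", "B"), year = 1990, val = c("1.5", "NA")
  ))
  expect_warning(rows <- read_gbd_csv(path, "Rate"), "1 row")
  expect_equal(nrow(rows), 1)
})

test_that("header dialects are equivalent: location_name vs location, val vs value", {
  body <- c("Kenya,Both,Age-standardized,Rate,1990,0.48")
  p1 <- write_gbd_fixture(c("location_name,sex_name,age_name,metric_name,year,val", body))
  p2 <- write_gbd_fixture(c("location,sex,age,metric,year,value", body))
  p3 <- write_gbd_fixture(c("LOCATION_NAME,SEX_NAME,AGE_NAME,METRIC_NAME,YEAR,VAL", body))
  r1 <- read_gbd_csv(p1, "Rate")
  r2 <- read_gbd_csv(p2, "Rate")
  r3 <- read_gbd_csv(p3, "Rate")
  for (r in list(r2, r3)) {
    expect_equal(r[c("location", "year", "val")], r1[c("location", "year", "val")])
  }
})

test_that("missing mandatory columns and empty filters are hard errors", {
  no_val <- write_gbd_fixture(c("location_name,year,metric_name", "A,1990,Rate"))
  expect_error(read_gbd_csv(no_val, "Rate"), "val")
  ok <- write_gbd_fixture(gbd_lines("A", 1990, 1))
  expect_error(read_gbd_csv(ok, "SEV"), "no rows")
  expect_error(read_gbd_csv(tempfile(), "Rate"), "not found")
})

test_that("sex and age filters default to both-sex age-standardized rows", {
  path <- write_gbd_fixture(gbd_lines(
    location = rep("A", 3), year = 1990, val = c(1, 2, 3),
    sex = c("Both", "Male", "Both"),
    age = c("Age-standardized", "Age-standardized", "All ages")
  ))
  expect_equal(read_gbd_csv(path, "Rate")$val, 1)
  expect_equal(nrow(read_gbd_csv(path, "Rate", sex = NULL, age = NULL)), 3)
})

test_that("build_panel inner-joins complete cases across both years", {
  rate <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = rep(c("A", "B", "C"), 2),
    year = rep(c(1990, 2019), each = 3),
    val = c(1, 2, 3, 4, 5, 6)
  )), "Rate")
  sev <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = rep(c("A", "B", "C"), 2),
    year = rep(c(1990, 2019), each = 3),
    val = c(10, 20, 30, 40, 50, 60)
  )), "Rate")
  panel <- build_panel(rate, list(bmi = sev), years = c(1990, 2019))
  expect_equal(nrow(panel), 6)
  expect_equal(names(panel), c("location", "year", "outcome", "bmi"))
  expect_equal(panel$outcome[panel$year == 1990], c(1, 2, 3))
  expect_equal(panel$bmi[panel$year == 2019], c(40, 50, 60))
})

test_that("a location missing one covariate-year is dropped from both years", {
  rate <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = rep(c("A", "B", "C"), 2),
    year = rep(c(1990, 2019), each = 3), val = 1:6
  )), "Rate")
  sdi <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = c("A", "C", "A", "B", "C"),     # B missing in 1990
    year = c(1990, 1990, 2019, 2019, 2019),
    val = c(0.5, 0.6, 0.7, 0.8, 0.9)
  )), "Rate")
  expect_message(
    panel <- build_panel(rate, list(sdi = sdi), years = c(1990, 2019)),
    "B"
  )
  expect_equal(nrow(panel), 4)
  expect_false("B" %in% panel$location)
  expect_equal(attr(panel, "excluded"), "B")
})

test_that("duplicates, zero overlap, and out-of-range covariates are rejected", {
  dup <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = c("A", "A", "A"), year = c(1990, 1990, 2019), val = 1:3
  )), "Rate")
  cov1 <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = c("A", "A"), year = c(1990, 2019), val = c(1, 2)
  )), "Rate")
  expect_error(build_panel(dup, list(x = cov1), years = c(1990, 2019)),
               "duplicate.*A 1990")

  rate <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = c("A", "A"), year = c(1990, 2019), val = c(1, 2)
  )), "Rate")
  other <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = c("Z", "Z"), year = c(1990, 2019), val = c(1, 2)
  )), "Rate")
  expect_error(build_panel(rate, list(x = other), years = c(1990, 2019)),
               "zero locations")

  sdi_bad <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = c("A", "A"), year = c(1990, 2019), val = c(0.5, 1.4)
  )), "Rate")
  expect_error(
    build_panel(rate, list(sdi = sdi_bad), years = c(1990, 2019),
                covariate_ranges = list(sdi = c(0, 1))),
    "outside"
  )
})

test_that("a hand-built multi-country fixture reproduces hand-computed means", {
  y90 <- c(3.79, 3.48, 2.61, 0.48, 10.90)
  y19 <- c(12.96, 12.09, 11.17, 0.74, 12.54)
  bmi90 <- c(12, 14, 13, 5, 25)
  bmi19 <- c(25, 24, 26, 9, 33)
  locs <- c("Estonia", "Latvia", "Belarus", "Kenya", "USA")
  rate <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = rep(locs, 2), year = rep(c(1990, 2019), each = 5),
    val = c(y90, y19)
  )), "Rate")
  bmi <- read_gbd_csv(write_gbd_fixture(gbd_lines(
    location = rep(locs, 2), year = rep(c(1990, 2019), each = 5),
    val = c(bmi90, bmi19)
  )), "Rate")
  panel <- build_panel(rate, list(high_bmi = bmi), years = c(1990, 2019))
  expect_equal(mean(panel$outcome[panel$year == 1990]), mean(y90))
  expect_equal(mean(panel$outcome[panel$year == 2019]), mean(y19))
  expect_equal(mean(panel$high_bmi[panel$year == 2019]), mean(bmi19))
})

test_that("panel CSV round-trip is bit-exact for finite doubles", {
  panel <- generate_panel(random_spec(3, 25, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)
  expect_identical(back$outcome, panel$outcome)
  for (cv in panel_covariates(panel)) expect_identical(back[[cv]], panel[[cv]])
  expect_equal(as.data.frame(back), as.data.frame(panel))
})
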