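test_that("load_dataset reads the harmonized CSV dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(
    record_id = sprintf("OTR-%02d", 1:11),
    dataset = "OTR", level = "person",
    incident_date = sprintf("2012-03-%02d", 1:11),
    incident_state = "OR",
    person_index = 1
  )
  write.csv(rows, path, row.names = FALSE, na = "")
  d <- load_dataset(path, "OTR")
  expect_s3_class(d, "fl_dataset")
  expect_equal(nrow(d$records), 11)
  expect_equal(d$region, "OR")
  expect_equal(d$counts[["persons"]], 11)

  # header-only CSV is a valid empty dataset
  writeLines(paste(FL_COLUMNS, collapse = ","), path)
  expect_equal(nrow(load_dataset(path, "OTR")$records), 0)
})

test_that("schema_config maps source dialect columns and reports gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "V1", EventDate = "2013-05-02", st = "wa"),
            path, row.names = FALSE)
  d <- load_dataset(path, "VC",
                    schema_config = c(record_id = "id", incident_date = "EventDate",
                                      incident_state = "st"))
  expect_equal(d$records$incident_state, "WA")
  expect_error(
    load_dataset(path, "VC", schema_config = c(record_id = "id",
                                               incident_date = "WrongCol")),
    class = "fl_schema_error")
  # required harmonized column absent entirely
  write.csv(data.frame(record_id = "V1"), path, row.names = FALSE)
  expect_error(load_dataset(path, "VC"), class = "fl_schema_error",
               regexp = "incident_date")
})

test_that("dates parse across padded and unpadded forms", {
  # oracle: zero-pad by hand, then parse the canonical form
  combos <- expand.grid(y = c(2004, 2013), m = c(1, 8, 11), d = c(2, 15, 30))
  unpadded <- sprintf("%d-%d-%d", combos$y, combos$m, combos$d)
  padded <- sprintf("%04d-%02d-%02d", combos$y, combos$m, combos$d)
  for (i in seq_along(unpadded)) {
    rec <- normalize_record(list(record_id = "x", incident_date = unpadded[i]))
    expect_equal(rec$incident_date, as.Date(padded[i]))
  }
  expect_error(normalize_record(list(record_id = "x", incident_date = "15/08/2010")),
               class = "fl_validation_error", regexp = "row")
})

test_that("normalize_record applies the harmonization rules", {
  rec <- normalize_record(list(record_id = "A1", incident_date = "2010-08-15",
                               vessel_official_number = " or1234ab ",
                               incident_state = "", narrative = "  "))
  expect_equal(rec$vessel_official_number, "OR1234AB")
  expect_true(is.na(rec$incident_state))   # empty string becomes missing
  expect_true(is.na(rec$narrative))

  expect_error(normalize_record(list(record_id = "A1", incident_date = "2010-08-15",
                                     latitude = "95.0")),
               class = "fl_validation_error", regexp = "latitude")
  # west-positive longitude rejected by the sign convention
  expect_error(normalize_record(list(record_id = "A1", incident_date = "2010-08-15",
                                     longitude = "124.5")),
               class = "fl_validation_error", regexp = "longitude")
  expect_error(normalize_record(list(record_id = "A1", incident_date = "2010-08-15",
                                     people_on_board = "-2")),
               class = "fl_validation_error")
})

test_that("dataset container enforces its invariants", {
  r <- tiny_records(c("X1", "X1"), "VC", c("2012-01-01", "2012-01-05"))
  expect_error(new_dataset("VC", r), class = "fl_validation_error",
               regexp = "duplicate")
  r2 <- tiny_records("X1", "VC", "2012-01-01")
  expect_error(new_dataset("VC", r2, date_range = c("2013-01-01", "2013-12-31")),
               class = "fl_validation_error", regexp = "date range")
  r3 <- tiny_records("X1", "NFI", "2012-01-01", level = "person")
  r3$person_index <- NA_integer_
  expect_error(new_dataset("NFI", r3), class = "fl_validation_error",
               regexp = "person_index")
})

test_that("expand_person_level enumerates person cases", {
  d <- tiny_dataset(c("C1", "C2", "C3"), "CFID",
                    c("2010-05-01", "2011-06-02", "2012-07-03"),
                    people = c(3, 1, NA))
  e <- expand_person_level(d)
  expect_equal(nrow(e$records), 5)  # 3 + 1 + max(NA, 1)
  c1 <- e$records[e$records$incident_id == "C1", ]
  expect_equal(c1$person_index, 1:3)
  expect_equal(c1$record_id, c("C1#1", "C1#2", "C1#3"))
  # incident-level fields are carried over unchanged
  expect_true(all(c1$incident_date == as.Date("2010-05-01")))
  expect_equal(unique(c1$incident_state), "OR")
  # single-person incident keeps identical fields under a derived id
  c2 <- e$records[e$records$incident_id == "C2", ]
  expect_equal(c2$person_index, 1L)

  # property: total person rows = sum of max(count, 1), fields never change
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    ppl <- sample(c(NA, 0:4), n, replace = TRUE)
    dd <- tiny_dataset(sprintf("I%d", 1:n), "CFID",
                       as.character(as.Date("2010-01-01") + sample(5000, n)),
                       people = ppl)
    ee <- expand_person_level(dd)
    expect_equal(nrow(ee$records), sum(pmax(ifelse(is.na(ppl), 1, ppl), 1)))
    expect_equal(unique(ee$records$incident_date[ee$records$incident_id == "I1"]),
                 dd$records$incident_date[1])
  }

  # the vessel-casualty dataset has no personnel information
  vc <- tiny_dataset("V1", "VC", "2012-01-01", people = 4)
  expect_error(expand_person_level(vc), class = "fl_validation_error")
})

test_that("write/load round-trip preserves all fields", {
  u <- default_universe()
  d <- u$datasets$NFI
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- load_dataset(path, "NFI", date_range = d$date_range)
  for (col in setdiff(FL_COLUMNS, "dataset")) {
    expect_equal(d2$records[[col]], d$records[[col]], info = col)
  }
  # and a second cycle is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d2, path2)
  expect_identical(readLines(path), readLines(path2))
})
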