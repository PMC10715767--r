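test_that("tidy tables are long over wells and axis, wide over readings", {
  b <- generate_fixture(fixture_style("t", "vertical", "timecourse",
                                      num_readings = 2, axis_len = 5,
                                      decorated = TRUE, seed = 11))
  tidy <- bundle_tidy(b)
  expect_identical(dim(tidy), c(480L, 4L))
  expect_identical(names(tidy), c("well", "time", "OD600", "GFP"))
  expect_identical(tidy$well[1:6], c(rep("A1", 5), "A2"))
  expect_identical(tidy$time[1:5], seq(0, 120, by = 30))
  # no duplicate keys
  expect_identical(anyDuplicated(tidy[c("well", "time")]), 0L)
})

test_that("single readings tidy to one row per well; spectra get a wavelength column", {
  g <- make_grid(list("0.5"))
  spec <- parser_spec("horizontal", "single", block_range("A1"),
                      reading_names = "OD600", wells = wells_explicit("A1"))
  tidy <- build_tidy(extract_all(spec, g), spec)
  expect_identical(dim(tidy), c(1L, 2L))
  expect_identical(names(tidy), c("well", "OD600"))

  bs <- generate_fixture(fixture_style("s", "vertical", "spectrum",
                                       plate_rows = 8, plate_cols = 12,
                                       axis_len = 101, seed = 12))
  tidy_s <- bundle_tidy(bs)
  expect_identical(nrow(tidy_s), 9696L)
  expect_true("wavelength" %in% names(tidy_s))
})

test_that("the axis column name is overridable", {
  b <- generate_fixture(fixture_style("t", "horizontal", "timecourse",
                                      plate_rows = 2, plate_cols = 3,
                                      axis_len = 4, seed = 13))
  tidy <- build_tidy(extract_all(b$spec, b$grid), b$spec, axis_name = "minutes")
  expect_true("minutes" %in% names(tidy))
})

test_that("a complete metadata join attaches every annotation without warnings", {
  b <- generate_fixture(style_catalog()[["horiz-single-plain-csv"]])
  tidy <- bundle_tidy(b)
  expect_no_warning(joined <- join_metadata(tidy, b$metadata))
  expect_identical(nrow(joined), nrow(tidy))
  expect_identical(names(joined)[1:3], c("well", "strain", "inducer_uM"))
  expect_false(anyNA(joined$strain))
  expect_identical(attr(joined, "join_warnings"), character(0))
})

test_that("data rows survive missing metadata; the warning names the wells", {
  b <- generate_fixture(style_catalog()[["horiz-single-plain-csv"]])
  tidy <- bundle_tidy(b)
  meta <- b$metadata[b$metadata$well != "H12", ]
  w <- expect_warning(joined <- join_metadata(tidy, meta),
                      class = "plateparse_warning_unmatched_data_wells")
  expect_identical(w$wells, "H12")
  expect_identical(nrow(joined), nrow(tidy))
  h12 <- joined[joined$well == "H12", ]
  expect_true(all(is.na(h12$strain)))
  expect_identical(h12$OD600, tidy$OD600[tidy$well == "H12"]) # measurements kept
})

test_that("metadata wells absent from the data are dropped with a warning", {
  tidy <- tibble::tibble(well = c("A1", "A2"), OD600 = c(0.1, 0.2))
  meta <- tibble::tibble(well = c("A1", "A2", "C5", "D6"), strain = letters[1:4])
  w <- expect_warning(joined <- join_metadata(tidy, meta),
                      class = "plateparse_warning_unused_metadata_wells")
  expect_setequal(w$wells, c("C5", "D6"))
  expect_identical(nrow(joined), 2L)
})

test_that("joining canonicalizes both sides ('a01' metadata matches 'A1' data)", {
  tidy <- tibble::tibble(well = "A1", OD600 = 0.4)
  meta <- tibble::tibble(Well = "a01", strain = "WT")
  expect_no_warning(joined <- join_metadata(tidy, meta))
  expect_identical(joined$strain, "WT")
  expect_identical(names(joined), c("well", "strain", "OD600"))
})

test_that("output columns are exactly metadata + keys + readings, metadata first", {
  b <- generate_fixture(style_catalog()[["vert-time-dec-csv"]])
  tidy <- bundle_tidy(b)
  joined <- join_metadata(tidy, b$metadata)
  expect_identical(names(joined),
                   c("well", "strain", "inducer_uM", "time", "OD600", "GFP"))
})

test_that("written output round-trips values, renders missing as empty fields", {
  b <- generate_fixture(style_catalog()[["horiz-single-sentinels-csv"]])
  joined <- join_metadata(bundle_tidy(b), b$metadata)
  p <- withr::local_tempfile(fileext = ".csv")
  write_output(joined, p)
  lines <- readLines(p)
  expect_identical(length(lines), nrow(joined) + 1L)
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(joined), ignore_attr = TRUE)
  # sentinel-masked cells are empty fields, not the text "NA"
  expect_false(any(grepl(",NA", lines, fixed = TRUE)))
  expect_true(any(grepl(",(,|$)", lines)))
})

test_that("a 480-row joined fixture writes 481 lines", {
  b <- generate_fixture(fixture_style("t", "vertical", "timecourse",
                                      num_readings = 2, axis_len = 5,
                                      decorated = TRUE, seed = 14))
  joined <- join_metadata(bundle_tidy(b), b$metadata)
  p <- withr::local_tempfile(fileext = ".csv")
  write_output(joined, p)
  expect_identical(length(readLines(p)), 481L)
})
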