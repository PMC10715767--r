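test_that("spreadsheet-style references convert to 1-based (row, col)", {
  r <- plateparse:::as_cell_ref("C7")
  expect_identical(r$row, 7L)
  expect_identical(r$col, 3L)
  b <- block_range("B3:D10")
  expect_identical(c(b$first$row, b$first$col, b$last$row, b$last$col),
                   c(3L, 2L, 10L, 4L))
  expect_error(block_range("D10:B3"), class = "plateparse_error_invalid_spec")
  expect_error(cell_ref(0, 1), class = "plateparse_error_invalid_spec")
})

test_that("constructor enforces structural invariants", {
  fb <- block_range("B2:B7")
  expect_error(
    parser_spec("vertical", "single", fb, num_readings = 2,
                reading_names = "only_one", wells = wells_plate(2, 3)),
    class = "plateparse_error_invalid_spec")
  expect_error(
    parser_spec("vertical", "single", fb, reading_names = "OD600",
                wells = wells_plate(2, 3),
                axis = axis_uniform(0, 30)),
    class = "plateparse_error_invalid_spec") # single + axis
  expect_error(
    parser_spec("vertical", "timecourse", fb, reading_names = "OD600",
                wells = wells_plate(2, 3)),
    class = "plateparse_error_invalid_spec") # timecourse without axis
  expect_error(
    parser_spec("matrix", "single", block_range("A1:L8"),
                reading_names = "OD600", wells = wells_explicit(c("A1", "A2"))),
    class = "plateparse_error_invalid_spec") # matrix needs a plate layout
  expect_error(wells_explicit(c("A1", "a01")),
               class = "plateparse_error_invalid_spec")
})

test_that("a consistent spec validates cleanly against its fixture grid", {
  for (nm in c("horiz-time-plain-csv", "vert-spec-dec-txt", "matrix-single-dec-csv")) {
    b <- generate_fixture(style_catalog()[[nm]])
    expect_identical(nrow(validate_spec(b$spec, b$grid)), 0L, label = nm)
  }
})

test_that("a stride-derived block past the grid edge is a named finding", {
  b <- generate_fixture(style_catalog()[["horiz-single-plain-csv"]])
  short <- cell_grid(unclass(b$grid)[-nrow(b$grid), , drop = FALSE])
  f <- validate_spec(b$spec, short)
  expect_true("BlockOutOfBounds" %in% f$code)
  expect_match(f$message[f$code == "BlockOutOfBounds"][1], "reading 2")
})

test_that("an off-by-one block width is a WellCountMismatch", {
  g <- make_grid(list(as.character(runif(95))))
  spec <- parser_spec("horizontal", "single",
                      block_range(cell_ref(1, 1), cell_ref(1, 95)),
                      reading_names = "OD600", wells = wells_plate(8, 12))
  f <- validate_spec(spec, g)
  expect_true("WellCountMismatch" %in% f$code)
  expect_match(f$message[f$code == "WellCountMismatch"][1], "95")
  expect_match(f$message[f$code == "WellCountMismatch"][1], "96")
})

test_that("axis label counts are checked against block dimensions", {
  g <- make_grid(rep(list(as.character(1:6)), 10))
  spec <- parser_spec("vertical", "timecourse",
                      block_range(cell_ref(1, 1), cell_ref(6, 4)),
                      reading_names = "OD600", wells = wells_plate(2, 3),
                      axis = axis_explicit(c(0, 30, 60))) # block implies 4
  f <- validate_spec(spec, g)
  expect_true("AxisLengthMismatch" %in% f$code)
  spec2 <- parser_spec("vertical", "timecourse",
                       block_range(cell_ref(1, 1), cell_ref(6, 4)),
                       reading_names = "OD600", wells = wells_plate(2, 3),
                       axis = axis_from_grid(block_range("A20:D20")))
  f2 <- validate_spec(spec2, g)
  expect_true("AxisRefOutOfBounds" %in% f2$code)
})

test_that("specs round-trip through JSON and YAML", {
  b <- generate_fixture(style_catalog()[["vert-time-dec-csv"]])
  for (ext in c(".json", ".yaml")) {
    p <- withr::local_tempfile(fileext = ext)
    save_spec(b$spec, p)
    expect_equal(load_spec(p), b$spec, label = ext)
  }
})

test_that("hand-written specs may use spreadsheet notation for blocks", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "schema_version": "1.0",
    "data_format": "matrix", "data_type": "single",
    "first_block": "B5:M12",
    "num_readings": 1, "reading_names": ["OD600"],
    "wells": {"mode": "plate", "plate_rows": 8, "plate_cols": 12}
  }', p)
  spec <- load_spec(p)
  expect_identical(spec$first_block, block_range(cell_ref(5, 2), cell_ref(12, 13)))
})

test_that("schema violations are rejected with the offending path", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "1.0", "data_type": "single"}', p)
  err <- expect_error(load_spec(p), class = "plateparse_error_spec_schema_error")
  expect_match(conditionMessage(err), "data_format")

  writeLines('{
    "schema_version": "1.0", "data_format": "matrix", "data_type": "kinetic",
    "first_block": "B5:M12", "num_readings": 1, "reading_names": ["x"],
    "wells": {"mode": "plate", "plate_rows": 8, "plate_cols": 12}
  }', p)
  err2 <- expect_error(load_spec(p), class = "plateparse_error_spec_schema_error")
  expect_match(conditionMessage(err2), "single")
  expect_match(conditionMessage(err2), "timecourse")
  expect_match(conditionMessage(err2), "spectrum")

  writeLines('{
    "schema_version": "1.0", "data_format": "matrix", "data_type": "single",
    "first_block": "B5:M12", "num_readings": 1, "reading_names": ["x"],
    "wells": {"mode": "plate", "plate_rows": 8, "plate_cols": 12},
    "future_field": 1
  }', p)
  err3 <- expect_error(load_spec(p), class = "plateparse_error_spec_schema_error")
  expect_match(conditionMessage(err3), "future_field")

  writeLines('{"schema_version": "9.0"}', p)
  expect_error(load_spec(p), class = "plateparse_error_spec_schema_error")
  writeLines('{not json', p)
  expect_error(load_spec(p), class = "plateparse_error_spec_schema_error")
})
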