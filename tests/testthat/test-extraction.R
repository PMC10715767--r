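test_that("stride places consecutive reading blocks", {
  # horizontal, 1-row blocks at rows 10, 11, 12
  g <- cell_grid(matrix("1", nrow = 12, ncol = 97))
  spec <- parser_spec("horizontal", "single",
                      block_range(cell_ref(10, 2), cell_ref(10, 97)),
                      num_readings = 3, reading_names = c("a", "b", "c"),
                      wells = wells_plate(8, 12))
  blocks <- locate_reading_blocks(spec, g)
  expect_identical(vapply(blocks, function(b) b$first$row, 1L), c(10L, 11L, 12L))
  expect_identical(vapply(blocks, function(b) b$last$col, 1L), rep(97L, 3))

  # single reading: the first block unchanged
  spec1 <- parser_spec("horizontal", "single",
                       block_range(cell_ref(10, 2), cell_ref(10, 97)),
                       reading_names = "a", wells = wells_plate(8, 12))
  expect_identical(locate_reading_blocks(spec1, g), list(spec1$first_block))

  # matrix with decoration-absorbing stride: 8 data rows + 2 header rows
  g2 <- cell_grid(matrix("1", nrow = 25, ncol = 12))
  spec2 <- parser_spec("matrix", "single",
                       block_range(cell_ref(5, 1), cell_ref(12, 12)),
                       num_readings = 2, reading_names = c("a", "b"),
                       block_stride = 10, wells = wells_plate(8, 12))
  b2 <- locate_reading_blocks(spec2, g2)[[2]]
  expect_identical(c(b2$first$row, b2$last$row), c(15L, 22L))

  # vertical strides move right
  spec3 <- parser_spec("vertical", "single",
                       block_range(cell_ref(1, 3), cell_ref(6, 3)),
                       num_readings = 2, reading_names = c("a", "b"),
                       block_stride = 2, wells = wells_plate(2, 3))
  g3 <- cell_grid(matrix("1", nrow = 6, ncol = 6))
  b3 <- locate_reading_blocks(spec3, g3)[[2]]
  expect_identical(c(b3$first$col, b3$last$col), c(5L, 5L))

  # out-of-bounds is a defensive error here (validate_spec reports it first)
  expect_error(locate_reading_blocks(spec2, cell_grid(matrix("1", 20, 12))),
               class = "plateparse_error_block_out_of_bounds")
})

test_that("coercion strips whitespace, maps sentinels, honours decimal commas", {
  g <- make_grid(list(c("0.42", "OVRFLW", " 1.07 ", "na")))
  v <- coerce_block(g, block_range("A1:D1"))
  expect_identical(as.vector(v), c(0.42, NA, 1.07, NA))

  g2 <- make_grid(list(c("0,42", "1,5")))
  v2 <- coerce_block(g2, block_range("A1:B1"), decimal_comma = TRUE)
  expect_identical(as.vector(v2), c(0.42, 1.5))

  g3 <- make_grid(list(c("0.1", "Temp(°C)", "0.2"), c("0.3", "0.4", "bad")))
  err <- expect_error(coerce_block(g3, block_range("A1:C2")),
                      class = "plateparse_error_non_numeric_cell")
  expect_match(conditionMessage(err), "\\(1, 2, \"Temp")
  expect_match(conditionMessage(err), "\\(2, 3, \"bad\"\\)")
})

test_that("custom sentinel lists are case-insensitive and override defaults", {
  g <- make_grid(list(c("0.5", "missing", "1.0")))
  v <- coerce_block(g, block_range("A1:C1"), sentinels = c("MISSING"))
  expect_identical(is.na(as.vector(v)), c(FALSE, TRUE, FALSE))
  # OVRFLW no longer a sentinel -> non-numeric
  g2 <- make_grid(list(c("OVRFLW")))
  expect_error(coerce_block(g2, block_range("A1"), sentinels = character(0)),
               class = "plateparse_error_non_numeric_cell")
})

test_that("matrix blocks mimic the plate: cell (r, c) is well letter r + column c", {
  vals <- matrix(0, nrow = 8, ncol = 12)
  vals[2, 3] <- 0.9
  m <- map_block_to_wells(vals, "matrix", enumerate_wells(8, 12), 1L)
  expect_identical(dim(m), c(96L, 1L))
  expect_identical(unname(m["B3", 1]), 0.9)
  expect_identical(sum(m), 0.9)
})

test_that("horizontal rows assign wells across columns in A1 order", {
  vals <- matrix(seq_len(96) / 100, nrow = 1)
  m <- map_block_to_wells(vals, "horizontal", enumerate_wells(8, 12), 1L)
  expect_identical(unname(m["A1", 1]), 0.01)
  expect_identical(unname(m["H12", 1]), 0.96)
})

test_that("a vertical block equal to the transpose of a horizontal one maps identically", {
  withr::with_seed(42, {
    wells <- enumerate_wells(2, 3)
    h <- matrix(runif(5 * 6), nrow = 5, ncol = 6) # axis x wells
    mh <- map_block_to_wells(h, "horizontal", wells, 5L)
    mv <- map_block_to_wells(t(h), "vertical", wells, 5L)
    expect_identical(mh, mv)
  })
})

test_that("shape violations name the rule and the shapes", {
  err <- expect_error(
    map_block_to_wells(matrix(0, 2, 5), "horizontal", enumerate_wells(2, 3), 2L),
    class = "plateparse_error_dimension_mismatch")
  expect_match(conditionMessage(err), "2 x 5")
  expect_match(conditionMessage(err), "2 x 6")
  expect_error(
    map_block_to_wells(matrix(0, 8, 11), "matrix", enumerate_wells(8, 12), 1L),
    class = "plateparse_error_dimension_mismatch")
})

test_that("extract_all composes locate, coerce and map over fixtures", {
  b <- generate_fixture(fixture_style("t", "vertical", "timecourse",
                                      num_readings = 2, axis_len = 5,
                                      decorated = TRUE, seed = 9))
  ex <- extract_all(b$spec, b$grid)
  expect_length(ex$readings, 2)
  expect_identical(dim(ex$readings[[1]]$values), c(96L, 5L))
  expect_identical(rownames(ex$readings[[2]]$values), enumerate_wells(8, 12))
  expect_identical(ex$axis_labels, seq(0, 120, by = 30))
})

test_that("a 1x1 grid with one explicit well extracts one scalar", {
  g <- make_grid(list("0.73"))
  spec <- parser_spec("horizontal", "single", block_range("A1"),
                      reading_names = "OD600", wells = wells_explicit("A1"))
  ex <- extract_all(spec, g)
  expect_identical(unname(ex$readings[[1]]$values["A1", 1]), 0.73)
  expect_null(ex$axis_labels)
})

test_that("axis labels read from the grid coerce numerically when possible", {
  g <- make_grid(list(c("", "0", "30", "60", "90", "120"),
                      c("A1", "0.1", "0.2", "0.3", "0.4", "0.5")))
  spec <- parser_spec("vertical", "timecourse",
                      block_range(cell_ref(2, 2), cell_ref(2, 6)),
                      reading_names = "OD600", wells = wells_explicit("A1"),
                      axis = axis_from_grid(block_range(cell_ref(1, 2), cell_ref(1, 6))))
  ex <- extract_all(spec, g)
  expect_identical(ex$axis_labels, c(0, 30, 60, 90, 120))
  # text labels stay text
  g2 <- make_grid(list(c("", "0 s", "30 s", "60 s", "90 s", "120 s"),
                       c("A1", "0.1", "0.2", "0.3", "0.4", "0.5")))
  ex2 <- extract_all(spec, g2)
  expect_identical(ex2$axis_labels, c("0 s", "30 s", "60 s", "90 s", "120 s"))
})

test_that("non-missing extracted values equal non-sentinel cells in the blocks", {
  for (nm in c("horiz-single-sentinels-csv", "matrix-single-sentinels-txt")) {
    b <- generate_fixture(style_catalog()[[nm]])
    blocks <- locate_reading_blocks(b$spec, b$grid)
    n_non_sentinel <- sum(vapply(blocks, function(blk) {
      cells <- trimws(unclass(b$grid)[blk$first$row:blk$last$row,
                                      blk$first$col:blk$last$col])
      sum(!tolower(cells) %in% tolower(b$spec$sentinel_values))
    }, 1L))
    ex <- extract_all(b$spec, b$grid)
    n_extracted <- sum(vapply(ex$readings, function(r) sum(!is.na(r$values)), 1L))
    expect_identical(n_extracted, n_non_sentinel, label = nm)
    expect_gt(sum(vapply(ex$readings, function(r) sum(is.na(r$values)), 1L)), 0)
  }
})

test_that("cells outside the blocks and axis reference never influence output", {
  withr::with_seed(7, {
    for (nm in c("horiz-time-dec-excel", "matrix-single-dec-csv", "vert-spec-dec-txt")) {
      b <- generate_fixture(style_catalog()[[nm]])
      baseline <- bundle_tidy(b)
      mask <- spec_footprint(b$spec, b$grid)
      outside <- which(!mask)
      expect_gt(length(outside), 0)
      for (k in seq_len(25)) {
        g2 <- b$grid
        idx <- sample(outside, 1)
        g2[[idx]] <- sample(c("JUNK", "-99", "Temp: 37C", ""), 1)
        b2 <- b; b2$grid <- g2
        expect_identical(bundle_tidy(b2), baseline, label = paste(nm, "perturbation", k))
      }
    }
  })
})
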