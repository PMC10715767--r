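# Shared helpers: tiny grids built in code, and a random spec generator for
# serialization property tests.

# Build a cell_grid from a list of character vectors (rows padded to the
# widest row), bypassing file I/O.
make_grid <- function(rows, dialect = "csv") {
  n_cols <- max(vapply(rows, length, 1L))
  cells <- matrix("", nrow = length(rows), ncol = n_cols)
  for (r in seq_along(rows)) {
    cells[r, seq_along(rows[[r]])] <- as.character(rows[[r]])
  }
  cell_grid(cells, dialect = dialect)
}

# A structurally valid spec drawn at random from the full combinatorial
# space: format x type x readings x stride/explicit blocks x well layout x
# axis mode x sentinels x dialect hints.
random_spec <- function() {
  fmt <- sample(c("horizontal", "vertical", "matrix"), 1)
  typ <- if (fmt == "matrix") "single" else sample(c("single", "timecourse", "spectrum"), 1)
  ax <- if (typ == "single") 1L else sample(2:6, 1)
  nr <- sample(1:4, 1)
  r0 <- sample(1:15, 1); c0 <- sample(1:15, 1)

  if (fmt == "matrix") {
    pr <- sample(1:8, 1); pc <- sample(1:12, 1)
    wells <- wells_plate(pr, pc)
    bh <- pr; bw <- pc
  } else {
    pr <- sample(1:4, 1); pc <- sample(1:6, 1)
    wells <- if (runif(1) < 0.3) wells_explicit(enumerate_wells(pr, pc))
             else wells_plate(pr, pc)
    n_wells <- pr * pc
    if (fmt == "horizontal") { bh <- ax; bw <- n_wells } else { bh <- n_wells; bw <- ax }
  }
  first_block <- block_range(cell_ref(r0, c0), cell_ref(r0 + bh - 1L, c0 + bw - 1L))

  use_explicit <- runif(1) < 0.25
  explicit_blocks <- NULL; stride <- NULL
  if (use_explicit) {
    gap <- sample(0:3, 1)
    explicit_blocks <- lapply(seq_len(nr) - 1L, function(k) {
      if (fmt == "vertical") {
        block_range(cell_ref(r0, c0 + k * (bw + gap)),
                    cell_ref(r0 + bh - 1L, c0 + k * (bw + gap) + bw - 1L))
      } else {
        block_range(cell_ref(r0 + k * (bh + gap), c0),
                    cell_ref(r0 + k * (bh + gap) + bh - 1L, c0 + bw - 1L))
      }
    })
  } else if (runif(1) < 0.5) {
    stride <- (if (fmt == "vertical") bw else bh) + sample(0:3, 1)
  }

  axis <- if (typ == "single") NULL else switch(sample(c("explicit", "from_grid", "uniform"), 1),
    explicit = if (runif(1) < 0.5) axis_explicit(round(runif(ax), 3))
               else axis_explicit(paste0("t", seq_len(ax))),
    from_grid = if (fmt == "horizontal") {
      axis_from_grid(block_range(cell_ref(r0, max(1L, c0 - 1L)),
                                 cell_ref(r0 + ax - 1L, max(1L, c0 - 1L))))
    } else {
      axis_from_grid(block_range(cell_ref(max(1L, r0 - 1L), c0),
                                 cell_ref(max(1L, r0 - 1L), c0 + ax - 1L)))
    },
    uniform = axis_uniform(round(runif(1, 0, 10), 4), round(runif(1, 0.1, 60), 4)))

  parser_spec(
    data_format = fmt, data_type = typ, first_block = first_block,
    num_readings = nr, reading_names = paste0("r", seq_len(nr)),
    block_stride = stride, explicit_blocks = explicit_blocks,
    wells = wells, axis = axis,
    sentinel_values = if (runif(1) < 0.3) c("", "OVER", "xxx") else default_sentinels(),
    dialect = if (runif(1) < 0.5) sample(c("csv", "csv2", "tsv", "txt", "excel"), 1),
    sheet = if (runif(1) < 0.2) "data",
    delimiter = if (runif(1) < 0.2) ";")
}

# Cells covered by any reading block or axis reference of a spec, as a
# logical mask over the grid.
spec_footprint <- function(spec, grid) {
  mask <- matrix(FALSE, nrow(grid), ncol(grid))
  blocks <- locate_reading_blocks(spec, grid)
  if (!is.null(spec$axis) && identical(spec$axis$mode, "from_grid")) {
    blocks <- c(blocks, list(spec$axis$ref))
  }
  for (b in blocks) {
    mask[b$first$row:b$last$row, b$first$col:b$last$col] <- TRUE
  }
  mask
}

# Tidy output of a bundle computed through the in-memory engine path.
bundle_tidy <- function(bundle) {
  build_tidy(extract_all(bundle$spec, bundle$grid), bundle$spec)
}

expect_same_table <- function(got, want) {
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE, tolerance = NULL)
}
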