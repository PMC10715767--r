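# The parser specification: a declarative, serializable description of where
# measurement data lives inside a raw grid and how to interpret it. It is the
# persistent equivalent of an interactively "built" parser: coordinates that
# a user would otherwise supply by clicking cells live here as 1-based
# (row, col) references.

#' Cell and block references
#'
#' `cell_ref()` addresses one grid cell with 1-based (row, col) coordinates;
#' `block_range()` a rectangle from its first (top-left) to last
#' (bottom-right) cell. Spreadsheet-style strings are accepted anywhere a
#' reference is expected: `"C7"` means row 7, column 3, and `"B3:D10"` a
#' rectangle, so hand-edited spec files can use the notation users see in
#' their spreadsheet program.
#'
#' @param row,col 1-based coordinates (each >= 1).
#' @return `cell_ref()`: a `pp_cell_ref`; `block_range()`: a `pp_block_range`.
#' @examples
#' block_range(cell_ref(10, 2), cell_ref(10, 97))
#' block_range("B3:D10")
#' @export
cell_ref <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (length(row) != 1 || length(col) != 1 || is.na(row) || is.na(col) ||
      row < 1 || col < 1) {
    pp_abort("invalid_spec", "cell_ref requires scalar row >= 1 and col >= 1")
  }
  structure(list(row = row, col = col), class = "pp_cell_ref")
}

as_cell_ref <- function(x, what = "cell reference") {
  if (inherits(x, "pp_cell_ref")) return(x)
  if (is.character(x) && length(x) == 1) {
    addr <- tryCatch(cellranger::as.cell_addr(x, strict = FALSE),
                     error = function(e) NULL)
    if (is.null(addr) || is.na(addr$row) || is.na(addr$col)) {
      pp_abort("invalid_spec", sprintf(
        "cannot parse %s \"%s\" (expected A1-style notation like \"B3\")", what, x))
    }
    return(cell_ref(addr$row, addr$col))
  }
  if (is.list(x) && all(c("row", "col") %in% names(x))) {
    return(cell_ref(x$row, x$col))
  }
  if (is.numeric(x) && length(x) == 2) return(cell_ref(x[1], x[2]))
  pp_abort("invalid_spec", sprintf("cannot interpret %s of class %s",
                                   what, paste(class(x), collapse = "/")))
}

#' @rdname cell_ref
#' @param first,last Corner cells: `cell_ref`s, `"B3"`-style strings, or
#'   (row, col) pairs. A single `"B3:D10"` string may be given as `first`.
#' @export
block_range <- function(first, last = NULL) {
  if (is.null(last)) {
    if (is.character(first) && length(first) == 1 && grepl(":", first, fixed = TRUE)) {
      parts <- strsplit(first, ":", fixed = TRUE)[[1]]
      return(block_range(parts[1], parts[2]))
    }
    last <- first
  }
  first <- as_cell_ref(first, "block first cell")
  last <- as_cell_ref(last, "block last cell")
  if (first$row > last$row || first$col > last$col) {
    pp_abort("invalid_spec", sprintf(
      "block first cell (%d, %d) must be at or above-left of last cell (%d, %d)",
      first$row, first$col, last$row, last$col))
  }
  structure(list(first = first, last = last), class = "pp_block_range")
}

as_block_range <- function(x, what = "block") {
  if (inherits(x, "pp_block_range")) return(x)
  if (is.list(x) && all(c("first", "last") %in% names(x))) {
    return(block_range(as_cell_ref(x$first, paste(what, "first cell")),
                       as_cell_ref(x$last, paste(what, "last cell"))))
  }
  if (is.character(x) && length(x) == 1) return(block_range(x))
  pp_abort("invalid_spec", sprintf("cannot interpret %s of class %s",
                                   what, paste(class(x), collapse = "/")))
}

block_nrow <- function(b) b$last$row - b$first$row + 1L
block_ncol <- function(b) b$last$col - b$first$col + 1L

shift_block <- function(b, rows = 0L, cols = 0L) {
  block_range(cell_ref(b$first$row + rows, b$first$col + cols),
              cell_ref(b$last$row + rows, b$last$col + cols))
}

block_in_grid <- function(b, grid) {
  b$first$row >= 1 && b$first$col >= 1 &&
    b$last$row <= nrow(grid) && b$last$col <= ncol(grid)
}

block_label <- function(b) {
  sprintf("rows %d-%d, cols %d-%d", b$first$row, b$last$row, b$first$col, b$last$col)
}

#' @export
print.pp_block_range <- function(x, ...) {
  cat(sprintf("<block %s (%d x %d)>\n", block_label(x), block_nrow(x), block_ncol(x)))
  invisible(x)
}

#' Well layouts
#'
#' A parser spec needs to know which wells the extracted values belong to.
#' `wells_plate()` declares a standard plate whose wells are enumerated in
#' row-major instrument order (see [enumerate_wells()]); `wells_explicit()`
#' lists identifiers directly, for partial plates or unusual orders.
#'
#' @param plate_rows,plate_cols Plate dimensions (default 8 x 12, the 96-well
#'   plate).
#' @return A `pp_well_layout`.
#' @export
wells_plate <- function(plate_rows = 8, plate_cols = 12) {
  ids <- enumerate_wells(plate_rows, plate_cols) # also validates dims
  structure(list(mode = "plate",
                 plate_rows = as.integer(plate_rows),
                 plate_cols = as.integer(plate_cols)),
            class = "pp_well_layout")
}

#' @rdname wells_plate
#' @param well_ids Character vector of well identifiers (canonicalized on
#'   construction; must be non-empty and unique).
#' @export
wells_explicit <- function(well_ids) {
  if (length(well_ids) == 0) {
    pp_abort("invalid_spec", "explicit well list must be non-empty")
  }
  ids <- canonicalize_well(well_ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    pp_abort("invalid_spec", sprintf(
      "explicit well list has duplicates after canonicalization: %s",
      paste(dup, collapse = ", ")))
  }
  structure(list(mode = "explicit", well_ids = ids), class = "pp_well_layout")
}

resolve_wells <- function(layout) {
  if (identical(layout$mode, "plate")) {
    enumerate_wells(layout$plate_rows, layout$plate_cols)
  } else {
    layout$well_ids
  }
}

#' Axis label sources for timecourse and spectrum data
#'
#' Timecourse data carries a time axis and spectrum data a wavelength axis;
#' the labels can be typed in directly (`axis_explicit()`), read out of the
#' raw grid itself (`axis_from_grid()`, pointing at a single row or column of
#' cells), or generated as an arithmetic sequence (`axis_uniform()`, e.g.
#' start 0, step 30 for a reading every 30 s). Labels read from the grid are
#' coerced to numbers when every label parses as one, otherwise kept as text.
#'
#' @param values Ordered vector of labels (numbers or text).
#' @return A `pp_axis`.
#' @export
axis_explicit <- function(values) {
  if (length(values) == 0) pp_abort("invalid_spec", "axis values must be non-empty")
  if (is.numeric(values)) values <- as.numeric(values) else values <- as.character(values)
  structure(list(mode = "explicit", values = values), class = "pp_axis")
}

#' @rdname axis_explicit
#' @param ref A [block_range()] (or string) covering a single grid row or
#'   column holding the labels.
#' @export
axis_from_grid <- function(ref) {
  ref <- as_block_range(ref, "axis reference")
  structure(list(mode = "from_grid", ref = ref), class = "pp_axis")
}

#' @rdname axis_explicit
#' @param start,step Numbers defining the sequence `start, start + step, ...`.
#' @export
axis_uniform <- function(start, step) {
  start <- as.numeric(start); step <- as.numeric(step)
  if (length(start) != 1 || length(step) != 1 || is.na(start) || is.na(step)) {
    pp_abort("invalid_spec", "axis_uniform requires scalar numeric start and step")
  }
  structure(list(mode = "uniform", start = start, step = step), class = "pp_axis")
}

#' Default sentinel tokens treated as missing values
#'
#' Instruments write placeholder tokens into data cells they could not
#' measure (typically overflow markers). Cells matching one of these tokens
#' (case-insensitively, after stripping surrounding whitespace) become
#' missing values rather than numbers. Fully overridable per spec.
#'
#' @return Character vector of tokens.
#' @export
default_sentinels <- function() c("", "NA", "OVRFLW", "OVER", "Overflow", "?")

PP_FORMATS <- c("horizontal", "vertical", "matrix")
PP_TYPES <- c("single", "timecourse", "spectrum")

#' Construct a parser specification
#'
#' A parser spec fully determines how one family of raw export files is
#' parsed: the layout convention (`data_format`), the kind of measurement
#' (`data_type`), where the first reading's data block sits (`first_block`,
#' enclosing data cells only — no header decorations), how many readings
#' there are and what to call them, where the remaining readings sit (by
#' stride, or listed explicitly), which wells the values map to, where axis
#' labels come from for timecourse/spectrum data, and which sentinel tokens
#' mean "missing".
#'
#' Layout conventions follow instrument practice:
#' \describe{
#'   \item{horizontal}{readings in rows, wells in columns; a block is
#'     `axis length x n_wells` (1 row for single readings), time running down
#'     the block's rows. Consecutive readings sit in consecutive row bands
#'     (default stride = block height).}
#'   \item{vertical}{readings in columns, wells in rows; a block is
#'     `n_wells x axis length`, consecutive readings in consecutive column
#'     bands (default stride = block width).}
#'   \item{matrix}{the plate drawn as a grid that visually mimics it
#'     (8 x 12 for a 96-well plate); one block per reading, stacked down the
#'     file (default stride = block height). Matrix specs are `single` type:
#'     kinetic matrix exports (one plate grid per timepoint) are expressed as
#'     one reading per timepoint.}
#' }
#'
#' @param data_format `"horizontal"`, `"vertical"` or `"matrix"`.
#' @param data_type `"single"`, `"timecourse"` or `"spectrum"`.
#' @param first_block [block_range()] (or `"B3:D10"` string) of the first
#'   reading's data cells.
#' @param num_readings Number of measurement readings (>= 1).
#' @param reading_names Unique non-empty labels, one per reading (e.g.
#'   `c("OD600", "GFP")`).
#' @param block_stride Rows (horizontal/matrix) or columns (vertical) between
#'   the starts of consecutive reading blocks; default = block height/width,
#'   i.e. immediately adjacent blocks. Increase it when decoration rows or
#'   columns separate the blocks.
#' @param explicit_blocks Optional list of [block_range()]s, one per reading,
#'   overriding stride placement for irregular exports; all must have the
#'   same dimensions as `first_block`.
#' @param wells A [wells_plate()] or [wells_explicit()] layout.
#' @param axis A `pp_axis` ([axis_explicit()], [axis_from_grid()] or
#'   [axis_uniform()]); required for timecourse/spectrum, forbidden for
#'   single.
#' @param sentinel_values Tokens treated as missing; see [default_sentinels()].
#' @param dialect,sheet,delimiter Optional hints recorded for the raw file
#'   (used by the CLI when the spec is run against a path).
#' @return A `parser_spec` object.
#' @export
parser_spec <- function(data_format, data_type, first_block,
                        num_readings = 1, reading_names,
                        block_stride = NULL, explicit_blocks = NULL,
                        wells = wells_plate(), axis = NULL,
                        sentinel_values = default_sentinels(),
                        dialect = NULL, sheet = NULL, delimiter = NULL) {
  data_format <- match.arg(data_format, PP_FORMATS)
  data_type <- match.arg(data_type, PP_TYPES)
  first_block <- as_block_range(first_block, "first_block")
  num_readings <- as.integer(num_readings)
  if (is.na(num_readings) || num_readings < 1) {
    pp_abort("invalid_spec", "num_readings must be an integer >= 1")
  }
  reading_names <- as.character(reading_names)
  if (length(reading_names) != num_readings) {
    pp_abort("invalid_spec", sprintf(
      "reading_names has length %d but num_readings is %d",
      length(reading_names), num_readings))
  }
  if (anyDuplicated(reading_names) || any(!nzchar(reading_names))) {
    pp_abort("invalid_spec", "reading_names must be unique and non-empty")
  }
  if (!is.null(block_stride)) {
    block_stride <- as.integer(block_stride)
    if (is.na(block_stride) || block_stride < 1) {
      pp_abort("invalid_spec", "block_stride must be an integer >= 1")
    }
  }
  if (!is.null(explicit_blocks)) {
    explicit_blocks <- lapply(explicit_blocks, as_block_range, what = "explicit block")
    if (length(explicit_blocks) != num_readings) {
      pp_abort("invalid_spec", sprintf(
        "explicit_blocks has length %d but num_readings is %d",
        length(explicit_blocks), num_readings))
    }
    same <- vapply(explicit_blocks, function(b) {
      block_nrow(b) == block_nrow(first_block) && block_ncol(b) == block_ncol(first_block)
    }, TRUE)
    if (!all(same)) {
      pp_abort("invalid_spec", sprintf(
        "explicit block(s) %s differ in shape from first_block (%d x %d)",
        paste(which(!same), collapse = ", "),
        block_nrow(first_block), block_ncol(first_block)))
    }
  }
  if (!inherits(wells, "pp_well_layout")) {
    pp_abort("invalid_spec", "wells must be a wells_plate() or wells_explicit() layout")
  }
  if (identical(data_type, "single")) {
    if (!is.null(axis)) {
      pp_abort("invalid_spec", "data_type \"single\" must not carry an axis")
    }
  } else {
    if (is.null(axis) || !inherits(axis, "pp_axis")) {
      pp_abort("invalid_spec", sprintf(
        "data_type \"%s\" requires an axis (axis_explicit/axis_from_grid/axis_uniform)",
        data_type))
    }
  }
  if (identical(data_format, "matrix")) {
    if (!identical(data_type, "single")) {
      pp_abort("invalid_spec",
               "matrix format requires data_type \"single\"; express kinetic matrix exports as one reading per timepoint")
    }
    if (!identical(wells$mode, "plate")) {
      pp_abort("invalid_spec", "matrix format requires a plate well layout")
    }
  }
  sentinel_values <- as.character(sentinel_values)
  if (!is.null(dialect)) dialect <- match.arg(dialect, PP_DIALECTS)
  if (!is.null(sheet) && is.numeric(sheet)) sheet <- as.integer(sheet)

  structure(list(
    data_format = data_format, data_type = data_type,
    first_block = first_block, num_readings = num_readings,
    reading_names = reading_names, block_stride = block_stride,
    explicit_blocks = explicit_blocks, wells = wells, axis = axis,
    sentinel_values = sentinel_values,
    dialect = dialect, sheet = sheet, delimiter = delimiter
  ), class = "parser_spec")
}

# Expected axis length implied by the spec's geometry (1 for single).
spec_axis_len <- function(spec) {
  if (identical(spec$data_type, "single")) return(1L)
  switch(spec$data_format,
         horizontal = block_nrow(spec$first_block),
         vertical   = block_ncol(spec$first_block),
         1L)
}

default_stride <- function(spec) {
  if (!is.null(spec$block_stride)) return(spec$block_stride)
  switch(spec$data_format,
         horizontal = block_nrow(spec$first_block),
         matrix     = block_nrow(spec$first_block),
         vertical   = block_ncol(spec$first_block))
}

#' @export
print.parser_spec <- function(x, ...) {
  cat(sprintf("<parser_spec: %s %s, %d reading(s): %s>\n",
              x$data_format, x$data_type, x$num_readings,
              paste(x$reading_names, collapse = ", ")))
  cat(sprintf("  first block %s; stride %d%s\n", block_label(x$first_block),
              default_stride(x),
              if (is.null(x$explicit_blocks)) "" else " (explicit blocks given)"))
  w <- x$wells
  if (identical(w$mode, "plate")) {
    cat(sprintf("  wells: %d x %d plate (%d wells)\n",
                w$plate_rows, w$plate_cols, w$plate_rows * w$plate_cols))
  } else {
    cat(sprintf("  wells: explicit list of %d\n", length(w$well_ids)))
  }
  if (!is.null(x$axis)) cat(sprintf("  axis: %s\n", x$axis$mode))
  invisible(x)
}

finding <- function(code, message) tibble(code = code, message = message)

no_findings <- function() tibble(code = character(), message = character())

#' Validate a parser specification against a raw grid
#'
#' Runs every consistency check between a spec and the grid it is meant to
#' parse, returning a report of findings rather than throwing: each violated
#' invariant yields one row with a machine-readable `code` and a human
#' message naming the offending field and values. An empty report means the
#' spec can be extracted safely. Checks cover structural invariants
#' (re-checked even though [parser_spec()] enforces them, so that
#' hand-deserialized objects are caught), every reading block lying inside
#' the grid, block dimensions agreeing with the well layout per
#' `data_format`, and axis label counts agreeing with block dimensions.
#'
#' @param spec A [parser_spec()].
#' @param grid A [cell_grid()].
#' @return A tibble with columns `code` and `message`; zero rows = valid.
#' @export
validate_spec <- function(spec, grid) {
  stopifnot(inherits(spec, "parser_spec"), inherits(grid, "cell_grid"))
  f <- no_findings()
  add <- function(code, msg) f <<- dplyr::bind_rows(f, finding(code, msg))

  if (length(spec$reading_names) != spec$num_readings) {
    add("ReadingNamesLength", sprintf(
      "reading_names has length %d but num_readings is %d",
      length(spec$reading_names), spec$num_readings))
  }
  if (anyDuplicated(spec$reading_names) || any(!nzchar(spec$reading_names))) {
    add("ReadingNamesInvalid", "reading_names must be unique and non-empty")
  }
  if (!is.null(spec$explicit_blocks)) {
    if (length(spec$explicit_blocks) != spec$num_readings) {
      add("ExplicitBlockCount", sprintf(
        "explicit_blocks has length %d but num_readings is %d",
        length(spec$explicit_blocks), spec$num_readings))
    }
    for (i in seq_along(spec$explicit_blocks)) {
      b <- spec$explicit_blocks[[i]]
      if (block_nrow(b) != block_nrow(spec$first_block) ||
          block_ncol(b) != block_ncol(spec$first_block)) {
        add("ExplicitBlockShape", sprintf(
          "explicit block %d (%s) differs in shape from first_block (%d x %d)",
          i, block_label(b), block_nrow(spec$first_block), block_ncol(spec$first_block)))
      }
    }
  }
  if (identical(spec$data_type, "single") && !is.null(spec$axis)) {
    add("AxisUnexpected", "data_type \"single\" must not carry an axis")
  }
  if (!identical(spec$data_type, "single") && is.null(spec$axis)) {
    add("AxisMissing", sprintf("data_type \"%s\" requires an axis", spec$data_type))
  }

  wells <- resolve_wells(spec$wells)
  n_wells <- length(wells)
  bh <- block_nrow(spec$first_block)
  bw <- block_ncol(spec$first_block)
  axis_len <- spec_axis_len(spec)

  if (identical(spec$data_format, "horizontal")) {
    if (bw != n_wells) {
      add("WellCountMismatch", sprintf(
        "horizontal block is %d columns wide but the well layout has %d wells",
        bw, n_wells))
    }
    if (bh != axis_len) {
      add("AxisLengthMismatch", sprintf(
        "horizontal block is %d rows tall but the axis implies %d reading row(s)",
        bh, axis_len))
    }
  } else if (identical(spec$data_format, "vertical")) {
    if (bh != n_wells) {
      add("WellCountMismatch", sprintf(
        "vertical block is %d rows tall but the well layout has %d wells",
        bh, n_wells))
    }
    if (bw != axis_len) {
      add("AxisLengthMismatch", sprintf(
        "vertical block is %d columns wide but the axis implies %d reading column(s)",
        bw, axis_len))
    }
  } else { # matrix
    if (!identical(spec$wells$mode, "plate")) {
      add("WellCountMismatch", "matrix format requires a plate well layout")
    } else if (bh != spec$wells$plate_rows || bw != spec$wells$plate_cols) {
      add("WellCountMismatch", sprintf(
        "matrix block is %d x %d but the plate is %d x %d",
        bh, bw, spec$wells$plate_rows, spec$wells$plate_cols))
    }
  }

  blocks <- derive_blocks(spec)
  for (i in seq_along(blocks)) {
    if (!block_in_grid(blocks[[i]], grid)) {
      add("BlockOutOfBounds", sprintf(
        "reading %d (\"%s\") block (%s) exceeds the %d x %d grid",
        i, if (i <= length(spec$reading_names)) spec$reading_names[i] else "?",
        block_label(blocks[[i]]), nrow(grid), ncol(grid)))
    }
  }

  ax <- spec$axis
  if (!is.null(ax)) {
    if (identical(ax$mode, "explicit") && length(ax$values) != axis_len) {
      add("AxisLengthMismatch", sprintf(
        "axis has %d explicit label(s) but the block implies %d",
        length(ax$values), axis_len))
    }
    if (identical(ax$mode, "from_grid")) {
      r <- ax$ref
      if (block_nrow(r) != 1 && block_ncol(r) != 1) {
        add("AxisLengthMismatch", sprintf(
          "axis reference (%s) must cover a single row or column", block_label(r)))
      } else {
        ref_len <- max(block_nrow(r), block_ncol(r))
        if (ref_len != axis_len) {
          add("AxisLengthMismatch", sprintf(
            "axis reference (%s) holds %d label(s) but the block implies %d",
            block_label(r), ref_len, axis_len))
        }
      }
      if (!block_in_grid(r, grid)) {
        add("AxisRefOutOfBounds", sprintf(
          "axis reference (%s) exceeds the %d x %d grid",
          block_label(r), nrow(grid), ncol(grid)))
      }
    }
  }
  f
}

# Stride- or explicitly-placed blocks for all readings (geometry only; no
# grid bounds check here).
derive_blocks <- function(spec) {
  if (!is.null(spec$explicit_blocks)) return(spec$explicit_blocks)
  stride <- default_stride(spec)
  lapply(seq_len(spec$num_readings) - 1L, function(k) {
    if (identical(spec$data_format, "vertical")) {
      shift_block(spec$first_block, cols = k * stride)
    } else {
      shift_block(spec$first_block, rows = k * stride)
    }
  })
}
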