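# Applying a validated spec to a grid: locate every reading block from
# positional information alone, coerce cell text to numbers (sentinels ->
# missing, decimal commas handled for csv2), and map grid positions to wells
# and axis points.

#' Locate every reading's data block
#'
#' Returns the rectangles holding each reading's data: the first reading's
#' block verbatim, and subsequent readings placed `block_stride` rows
#' (horizontal/matrix) or columns (vertical) after the previous one —
#' immediately adjacent blocks by default. When the spec carries
#' `explicit_blocks` they are returned verbatim instead.
#'
#' @param spec A [parser_spec()] that validated cleanly against `grid`.
#' @param grid A [cell_grid()].
#' @return List of [block_range()]s of length `num_readings`.
#' @export
locate_reading_blocks <- function(spec, grid) {
  blocks <- derive_blocks(spec)
  for (i in seq_along(blocks)) {
    if (!block_in_grid(blocks[[i]], grid)) {
      pp_abort("block_out_of_bounds", sprintf(
        "reading %d block (%s) exceeds the %d x %d grid",
        i, block_label(blocks[[i]]), nrow(grid), ncol(grid)))
    }
  }
  blocks
}

block_cells <- function(grid, block) {
  unclass(grid)[block$first$row:block$last$row,
                block$first$col:block$last$col, drop = FALSE]
}

#' Coerce a block of raw text cells to numbers
#'
#' Each cell is stripped of surrounding whitespace; cells matching a sentinel
#' token (case-insensitively) become missing values; with `decimal_comma` the
#' decimal comma of the csv2 convention is converted; everything remaining
#' must parse as a number. Cells that do not are reported all at once, with
#' their grid coordinates, so a misplaced block can be fixed in one pass.
#'
#' @param grid A [cell_grid()].
#' @param block A [block_range()] lying within the grid.
#' @param sentinels Tokens treated as missing (see [default_sentinels()]).
#' @param decimal_comma Interpret `,` as the decimal mark (csv2 exports).
#' @return Numeric matrix of the block's shape; missing values are `NA`.
#' @export
coerce_block <- function(grid, block, sentinels = default_sentinels(),
                         decimal_comma = FALSE) {
  stopifnot(inherits(grid, "cell_grid"))
  if (!block_in_grid(block, grid)) {
    pp_abort("block_out_of_bounds", sprintf(
      "block (%s) exceeds the %d x %d grid", block_label(block),
      nrow(grid), ncol(grid)))
  }
  raw <- block_cells(grid, block)
  txt <- trimws(raw)
  is_missing <- matrix(tolower(txt) %in% tolower(trimws(sentinels)),
                       nrow = nrow(raw), ncol = ncol(raw))
  num_txt <- txt
  if (decimal_comma) num_txt <- gsub(",", ".", num_txt, fixed = TRUE)
  vals <- matrix(suppressWarnings(as.numeric(num_txt)),
                 nrow = nrow(raw), ncol = ncol(raw))
  bad <- !is_missing & is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    offenders <- sprintf("(%d, %d, \"%s\")",
                         block$first$row + idx[, 1] - 1L,
                         block$first$col + idx[, 2] - 1L,
                         raw[bad])
    pp_abort("non_numeric_cell", sprintf(
      "non-numeric cell(s) in block %s: %s",
      block_label(block), paste(offenders, collapse = ", ")))
  }
  vals[is_missing] <- NA_real_
  vals
}

#' Map a coerced block to wells
#'
#' Applies the layout convention to assign each matrix entry to a well (and
#' axis position): horizontal blocks put wells across the columns and axis
#' points down the rows; vertical blocks the transpose; matrix blocks mimic
#' the plate itself, cell (r, c) belonging to the well with row letter r and
#' column number c.
#'
#' @param values Numeric matrix from [coerce_block()].
#' @param data_format `"horizontal"`, `"vertical"` or `"matrix"`.
#' @param wells Ordered character vector of canonical well identifiers.
#' @param axis_len Number of axis points (1 for single readings).
#' @return Numeric matrix with one row per well (rownames = wells) and one
#'   column per axis point.
#' @export
map_block_to_wells <- function(values, data_format, wells, axis_len = 1L) {
  data_format <- match.arg(data_format, PP_FORMATS)
  n_wells <- length(wells)
  dims <- dim(values)
  expect <- switch(data_format,
    horizontal = c(axis_len, n_wells),
    vertical   = c(n_wells, axis_len),
    matrix     = NULL)
  if (identical(data_format, "matrix")) {
    if (axis_len != 1L) {
      pp_abort("dimension_mismatch",
               "matrix format carries one axis point per block (axis_len must be 1)")
    }
    if (dims[1] * dims[2] != n_wells) {
      pp_abort("dimension_mismatch", sprintf(
        "matrix block is %d x %d (%d cells) but the layout has %d wells (rule: cell (r, c) = well letter r + column c)",
        dims[1], dims[2], dims[1] * dims[2], n_wells))
    }
    out <- matrix(as.vector(t(values)), ncol = 1L)
  } else {
    if (!identical(as.integer(dims), as.integer(expect))) {
      pp_abort("dimension_mismatch", sprintf(
        "%s block is %d x %d but the rule \"%s\" expects %d x %d",
        data_format, dims[1], dims[2],
        if (identical(data_format, "horizontal"))
          "axis rows x well columns" else "well rows x axis columns",
        expect[1], expect[2]))
    }
    out <- if (identical(data_format, "horizontal")) t(values) else values
  }
  dimnames(out) <- list(wells, NULL)
  out
}

resolve_axis <- function(spec, grid, decimal_comma = FALSE) {
  if (is.null(spec$axis)) return(NULL)
  axis_len <- spec_axis_len(spec)
  a <- spec$axis
  if (identical(a$mode, "explicit")) {
    labels <- a$values
  } else if (identical(a$mode, "uniform")) {
    labels <- a$start + a$step * (seq_len(axis_len) - 1)
  } else { # from_grid
    if (!block_in_grid(a$ref, grid)) {
      pp_abort("block_out_of_bounds", sprintf(
        "axis reference (%s) exceeds the %d x %d grid",
        block_label(a$ref), nrow(grid), ncol(grid)))
    }
    txt <- trimws(as.vector(block_cells(grid, a$ref)))
    num_txt <- if (decimal_comma) gsub(",", ".", txt, fixed = TRUE) else txt
    nums <- suppressWarnings(as.numeric(num_txt))
    labels <- if (!any(is.na(nums))) nums else txt
  }
  if (length(labels) != axis_len) {
    pp_abort("axis_length_mismatch", sprintf(
      "resolved %d axis label(s) but the block implies %d",
      length(labels), axis_len))
  }
  labels
}

#' Extract all readings from a grid
#'
#' Composes locate / coerce / map for every reading of a spec and resolves
#' the axis labels, yielding per-reading, per-well values straight out of the
#' grid. Nothing outside the located blocks (and the axis reference, when
#' labels are read from the grid) influences the result.
#'
#' @param spec A [parser_spec()] that validates cleanly against `grid`
#'   (run [validate_spec()] first; extraction re-checks bounds defensively).
#' @param grid A [cell_grid()].
#' @param decimal_comma Interpret decimal commas in data cells; defaults to
#'   `TRUE` when either the spec's dialect hint or the grid's source dialect
#'   is csv2.
#' @return An `extracted_data` object: list with `readings` (each a list with
#'   `name` and a wells x axis `values` matrix, missing as `NA`) and
#'   `axis_labels` (`NULL` for single readings).
#' @export
extract_all <- function(spec, grid, decimal_comma = NULL) {
  stopifnot(inherits(spec, "parser_spec"), inherits(grid, "cell_grid"))
  if (is.null(decimal_comma)) {
    decimal_comma <- identical(spec$dialect, "csv2") ||
      identical(grid_dialect(grid), "csv2")
  }
  blocks <- locate_reading_blocks(spec, grid)
  wells <- resolve_wells(spec$wells)
  axis_len <- spec_axis_len(spec)
  axis_labels <- resolve_axis(spec, grid, decimal_comma)
  readings <- lapply(seq_along(blocks), function(i) {
    vals <- coerce_block(grid, blocks[[i]], spec$sentinel_values, decimal_comma)
    list(name = spec$reading_names[i],
         values = map_block_to_wells(vals, spec$data_format, wells, axis_len))
  })
  structure(list(readings = readings, axis_labels = axis_labels),
            class = "extracted_data")
}

#' @export
print.extracted_data <- function(x, ...) {
  n_axis <- if (is.null(x$axis_labels)) 1L else length(x$axis_labels)
  cat(sprintf("<extracted_data: %d reading(s) x %d well(s) x %d axis point(s)>\n",
              length(x$readings), nrow(x$readings[[1]]$values), n_axis))
  invisible(x)
}
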