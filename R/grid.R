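# CellGrid: a rectangular grid of raw text cells, the programmatic stand-in
# for the file as displayed in a spreadsheet. 1-based addressing, cell (1,1)
# top-left, every value text, no header inference and no type coercion.

new_cell_grid <- function(cells, dialect, sheet = NULL) {
  stopifnot(is.matrix(cells), is.character(cells))
  cells[is.na(cells)] <- ""
  dimnames(cells) <- NULL
  structure(cells,
            class = c("cell_grid", "matrix", "array"),
            dialect = dialect,
            sheet = sheet)
}

#' Construct a cell grid from a character matrix
#'
#' Mostly useful for tests and fixture construction; files are read with
#' [read_raw_grid()].
#'
#' @param cells Character matrix (NAs become empty strings).
#' @param dialect One of `"csv"`, `"csv2"`, `"tsv"`, `"txt"`, `"excel"`.
#' @param sheet Optional Excel sheet name of origin.
#' @return A `cell_grid` object.
#' @export
cell_grid <- function(cells, dialect = "csv", sheet = NULL) {
  dialect <- match.arg(dialect, PP_DIALECTS)
  if (!is.matrix(cells)) cells <- matrix(as.character(cells), nrow = 1)
  storage.mode(cells) <- "character"
  new_cell_grid(cells, dialect, sheet)
}

PP_DIALECTS <- c("csv", "csv2", "tsv", "txt", "excel")

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("<cell_grid: %d x %d, dialect %s%s>\n",
              nrow(x), ncol(x), attr(x, "dialect"),
              if (!is.null(attr(x, "sheet"))) paste0(", sheet \"", attr(x, "sheet"), "\"") else ""))
  preview <- x[seq_len(min(nrow(x), 8L)), seq_len(min(ncol(x), 8L)), drop = FALSE]
  print(unclass(preview))
  invisible(x)
}

#' Read a single cell of a grid
#'
#' @param grid A `cell_grid`.
#' @param row,col 1-based coordinates.
#' @return The cell's text value.
#' @export
grid_cell <- function(grid, row, col) {
  stopifnot(inherits(grid, "cell_grid"))
  if (row < 1 || row > nrow(grid) || col < 1 || col > ncol(grid)) {
    pp_abort("block_out_of_bounds", sprintf(
      "cell (%d, %d) is outside the %d x %d grid", row, col, nrow(grid), ncol(grid)))
  }
  grid[row, col]
}

grid_dialect <- function(grid) attr(grid, "dialect")
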