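# Reading raw export files and metadata files. The guiding rule: a raw file
# is read with NO header row, NO row skipping and NO type inference, so that
# parser-spec coordinates match what the user sees when they open the file in
# a spreadsheet program.

infer_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv  = "csv",
    tsv  = "tsv",
    txt  = "txt",
    xls  = "excel",
    xlsx = "excel",
    pp_abort("unknown_dialect", sprintf(
      "cannot infer a dialect from extension \".%s\" of \"%s\"; pass dialect = one of %s (csv2 must always be requested explicitly)",
      ext, basename(path), paste(PP_DIALECTS, collapse = "/"))))
}

dialect_sep <- function(dialect, delimiter = NULL) {
  switch(dialect,
    csv  = ",",
    csv2 = ";",
    tsv  = "\t",
    txt  = delimiter %||% "\t",
    pp_abort("unknown_dialect", sprintf("no separator for dialect \"%s\"", dialect)))
}

# UTF-8 first, latin-1 fallback with a warning; returns a UTF-8 string.
read_file_text <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(bytes)
  if (all(validUTF8(txt))) {
    Encoding(txt) <- "UTF-8"
    return(txt)
  }
  pp_warn("encoding_fallback", sprintf(
    "\"%s\" is not valid UTF-8; falling back to latin-1", basename(path)))
  iconv(txt, from = "latin1", to = "UTF-8")
}

split_lines <- function(txt) {
  if (identical(txt, "")) return(character())
  strsplit(txt, "\r\n|\n|\r")[[1]]
}

#' Read a raw plate-reader export file into a cell grid
#'
#' Loads the file exactly as a user would see it in a spreadsheet: every
#' physical line becomes one grid row in order, every value is kept as text
#' (decimal commas, overflow markers and all), short rows are right-padded
#' with empty strings, and nothing is skipped, typed or reordered. Positional
#' parser specifications address the result with 1-based (row, col)
#' coordinates where cell (1,1) is the top-left cell of the file.
#'
#' @param path Path to the raw file.
#' @param dialect Dialect override: `"csv"`, `"csv2"` (semicolon separator,
#'   decimal comma), `"tsv"`, `"txt"` (tab unless `delimiter` says otherwise)
#'   or `"excel"`. When `NULL`, inferred from the extension (`.csv` -> csv,
#'   `.tsv` -> tsv, `.txt` -> txt, `.xls`/`.xlsx` -> excel). `csv2` shares the
#'   `.csv` extension and is never inferred; request it explicitly.
#' @param sheet Excel only: sheet name or 1-based index (default: first sheet).
#' @param delimiter `txt` only: field separator override (default tab).
#' @return A [cell_grid()].
#' @export
read_raw_grid <- function(path, dialect = NULL, sheet = NULL, delimiter = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path) ||
      dir.exists(path)) {
    pp_abort("file_unreadable", sprintf("cannot read file \"%s\"", path))
  }
  dialect <- if (is.null(dialect)) infer_dialect(path) else match.arg(dialect, PP_DIALECTS)
  if (identical(dialect, "excel")) {
    read_grid_excel(path, sheet)
  } else {
    read_grid_delim(path, dialect, delimiter)
  }
}

read_grid_delim <- function(path, dialect, delimiter = NULL) {
  sep <- dialect_sep(dialect, delimiter)
  txt <- withCallingHandlers(
    read_file_text(path),
    error = function(e) pp_abort("file_unreadable", sprintf(
      "cannot read file \"%s\": %s", path, conditionMessage(e))))
  lines <- split_lines(txt)
  n_lines <- length(lines)
  if (n_lines == 0 || all(!nzchar(lines))) {
    cells <- matrix("", nrow = n_lines, ncol = if (n_lines) 1L else 0L)
    return(new_cell_grid(cells, dialect))
  }
  dt <- data.table::fread(
    text = txt, sep = sep, header = FALSE, colClasses = "character",
    fill = TRUE, na.strings = NULL, strip.white = FALSE,
    blank.lines.skip = FALSE, quote = "\"")
  cells <- as.matrix(dt)
  cells[is.na(cells)] <- ""
  # fread strips a field's outer quotes but leaves RFC 4180 doubled quotes
  cells <- gsub("\"\"", "\"", cells, fixed = TRUE)
  # fread drops trailing blank lines; restore them so n_rows equals the
  # file's physical line count
  if (nrow(cells) < n_lines) {
    pad <- matrix("", nrow = n_lines - nrow(cells), ncol = ncol(cells))
    cells <- rbind(cells, pad)
  }
  new_cell_grid(cells, dialect)
}

resolve_sheet <- function(path, sheet) {
  sheets <- tryCatch(readxl::excel_sheets(path),
                     error = function(e) pp_abort("file_unreadable", sprintf(
                       "cannot read Excel file \"%s\": %s", path, conditionMessage(e))))
  if (is.null(sheet)) return(sheets[[1]])
  if (is.numeric(sheet)) {
    if (sheet < 1 || sheet > length(sheets)) {
      pp_abort("sheet_not_found", sprintf(
        "sheet index %d out of range; \"%s\" has %d sheet(s): %s",
        as.integer(sheet), basename(path), length(sheets),
        paste(sheets, collapse = ", ")))
    }
    return(sheets[[as.integer(sheet)]])
  }
  if (!sheet %in% sheets) {
    pp_abort("sheet_not_found", sprintf(
      "sheet \"%s\" not found in \"%s\"; available: %s",
      sheet, basename(path), paste(sheets, collapse = ", ")))
  }
  sheet
}

read_grid_excel <- function(path, sheet = NULL) {
  sheet_name <- resolve_sheet(path, sheet)
  tb <- suppressMessages(readxl::read_excel(
    path, sheet = sheet_name, col_names = FALSE, col_types = "text",
    range = cellranger::cell_limits(c(1L, 1L), c(NA, NA)),
    .name_repair = "minimal"))
  cells <- as.matrix(tb)
  if (length(cells) == 0) cells <- matrix(character(), nrow = 0, ncol = 0)
  storage.mode(cells) <- "character"
  cells[is.na(cells)] <- ""
  new_cell_grid(cells, "excel", sheet = sheet_name)
}

#' Read an experiment metadata table
#'
#' Metadata files carry the per-well experimental annotations (strain,
#' inducer concentration, replicate, ...) that downstream analysis needs.
#' The single hard requirement is a column that resolves to `well`
#' (case-insensitive exact match on the stripped header: "well", "Well",
#' "WELL"); well values are canonicalized ("a01" -> "A1") and must be unique.
#' All other columns are free-form and have their types guessed.
#'
#' @inheritParams read_raw_grid
#' @return A tibble of class `metadata_table` with attribute `well_column`
#'   (the resolved header name). Column order follows the file.
#' @export
read_metadata <- function(path, dialect = NULL, sheet = NULL, delimiter = NULL) {
  grid <- read_raw_grid(path, dialect = dialect, sheet = sheet, delimiter = delimiter)
  if (nrow(grid) < 1) {
    pp_abort("missing_well_column",
             sprintf("metadata file \"%s\" is empty", basename(path)))
  }
  header <- trimws(grid[1, ])
  body <- unclass(grid)[-1, , drop = FALSE]
  keep_rows <- apply(body, 1, function(r) any(nzchar(r)))
  body <- body[keep_rows, , drop = FALSE]
  keep_cols <- nzchar(header)
  header <- header[keep_cols]
  body <- body[, keep_cols, drop = FALSE]
  tb <- as_tibble(as.data.frame(body, stringsAsFactors = FALSE),
                  .name_repair = "minimal")
  names(tb) <- header

  idx <- which(tolower(header) == "well")
  if (length(idx) == 0) {
    pp_abort("missing_well_column", sprintf(
      "metadata has no column resolving to \"well\" (case-insensitive); columns found: %s",
      paste(sprintf("\"%s\"", header), collapse = ", ")))
  }
  well_column <- header[idx[1]]
  wells <- canonicalize_well(tb[[well_column]])
  dup <- unique(wells[duplicated(wells)])
  if (length(dup) > 0) {
    pp_abort("duplicate_well", sprintf(
      "metadata wells are not unique after canonicalization; duplicated: %s",
      paste(dup, collapse = ", ")))
  }
  tb[[well_column]] <- wells
  other <- setdiff(names(tb), well_column)
  if (length(other) > 0 && nrow(tb) > 0) {
    dec <- if (identical(grid_dialect(grid), "csv2")) "," else "."
    tb[other] <- suppressMessages(readr::type_convert(
      tb[other], locale = readr::locale(decimal_mark = dec),
      guess_integer = FALSE))
  }
  structure(tb, class = c("metadata_table", class(tb)), well_column = well_column)
}

#' @export
print.metadata_table <- function(x, ...) {
  cat(sprintf("<metadata_table: %d wells, well column \"%s\">\n",
              nrow(x), attr(x, "well_column")))
  NextMethod()
}
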