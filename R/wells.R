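# Well identifiers: row letter + 1-based column number, "A1" .. "H12" on the
# standard 96-well plate. Row letters are single characters (A-Z), so plates
# up to 26 rows are supported; nothing larger is named this way in practice.

#' Enumerate wells of a multiwell plate in row-major order
#'
#' Generates the canonical well identifiers of a `plate_rows` x `plate_cols`
#' plate in the order instruments report them: across each row first
#' ("A1", "A2", ..., "A12", "B1", ...). Row letters run A-Z, column numbers
#' are 1-based with no zero padding, so an 8 x 12 plate yields
#' "A1" .. "H12" (96 wells) and a 16 x 24 plate "A1" .. "P24" (384 wells).
#'
#' @param plate_rows Number of plate rows (1-26).
#' @param plate_cols Number of plate columns (>= 1).
#' @return Character vector of length `plate_rows * plate_cols`.
#' @examples
#' head(enumerate_wells(8, 12))
#' @export
enumerate_wells <- function(plate_rows, plate_cols) {
  plate_rows <- as.integer(plate_rows)
  plate_cols <- as.integer(plate_cols)
  if (is.na(plate_rows) || plate_rows < 1 || plate_rows > 26) {
    pp_abort("unsupported_plate", sprintf(
      "plate_rows must be between 1 and 26 (single-letter row labels), got %s",
      plate_rows))
  }
  if (is.na(plate_cols) || plate_cols < 1) {
    pp_abort("unsupported_plate", sprintf(
      "plate_cols must be >= 1, got %s", plate_cols))
  }
  as.vector(t(outer(LETTERS[seq_len(plate_rows)], seq_len(plate_cols), paste0)))
}

#' Canonicalize well identifiers
#'
#' Normalises free-form well labels to the canonical form used throughout the
#' package and for metadata joining: surrounding whitespace stripped, row
#' letter uppercased, leading zeros removed from the column number
#' ("a01" -> "A1"). Canonicalization is idempotent.
#'
#' @param id Character vector of well labels (letter(s) followed by digits).
#' @return Character vector of canonical identifiers, same length as `id`.
#' @examples
#' canonicalize_well(c("a01", "H12", " b9 "))
#' @export
canonicalize_well <- function(id) {
  id <- trimws(as.character(id))
  m <- regmatches(id, regexec("^([A-Za-z]+)0*([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    pp_abort("malformed_well", sprintf(
      "malformed well identifier(s): %s (expected row letter(s) followed by a column number, e.g. \"B3\")",
      paste(sprintf("\"%s\"", id[bad]), collapse = ", ")))
  }
  vapply(m, function(x) paste0(toupper(x[2]), x[3]), "")
}
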