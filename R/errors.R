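# Typed condition system: every failure mode the engine can signal carries a
# stable machine-readable code, so the CLI can map it to a documented exit
# status and tests can assert on the class rather than the message text.

# code -> CLI exit status; 1 is reserved for uncategorised errors and 2 for
# validation findings (which are returned, not thrown).
PP_EXIT_CODES <- c(
  file_unreadable    = 10L,
  unknown_dialect    = 11L,
  sheet_not_found    = 12L,
  missing_well_column = 13L,
  duplicate_well     = 14L,
  spec_schema_error  = 15L,
  block_out_of_bounds = 16L,
  non_numeric_cell   = 17L,
  dimension_mismatch = 18L,
  axis_length_mismatch = 19L,
  malformed_well     = 20L,
  unsupported_plate  = 21L,
  invalid_style      = 22L,
  path_unwritable    = 23L,
  invalid_spec       = 24L
)

pp_abort <- function(code, message, ...) {
  abort(message,
        class = c(paste0("plateparse_error_", code), "plateparse_error"),
        code = code, ...)
}

pp_warn <- function(code, message, ...) {
  warn(message,
       class = c(paste0("plateparse_warning_", code), "plateparse_warning"),
       code = code, ...)
}

#' Exit status associated with a plateparse error
#'
#' Maps a caught condition to the stable exit status the command-line
#' interface documents: 0 success, 1 uncategorised error, 2 validation
#' findings, and a fixed code per typed error class (10-24).
#'
#' @param cnd A condition object (typically caught with [tryCatch()]).
#' @return An integer exit status.
#' @export
exit_status <- function(cnd) {
  code <- cnd$code
  if (is.null(code) || is.na(match(code, names(PP_EXIT_CODES)))) return(1L)
  unname(PP_EXIT_CODES[[code]])
}
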