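# Parser specs persist as documented JSON (YAML accepted as a convenience),
# so a spec built once can be rerun on every later export from the same
# instrument program. The format is versioned; unknown keys are rejected
# rather than silently ignored, so a document written by a future schema
# cannot be half-understood.

PP_SCHEMA_VERSION <- "1.0"

spec_to_list <- function(spec) {
  ref_list <- function(r) list(row = r$row, col = r$col)
  blk_list <- function(b) list(first = ref_list(b$first), last = ref_list(b$last))
  out <- list(
    schema_version = PP_SCHEMA_VERSION,
    data_format = spec$data_format,
    data_type = spec$data_type,
    first_block = blk_list(spec$first_block),
    num_readings = spec$num_readings,
    reading_names = as.list(spec$reading_names)
  )
  if (!is.null(spec$block_stride)) out$block_stride <- spec$block_stride
  if (!is.null(spec$explicit_blocks)) {
    out$explicit_blocks <- lapply(spec$explicit_blocks, blk_list)
  }
  w <- spec$wells
  out$wells <- if (identical(w$mode, "plate")) {
    list(mode = "plate", plate_rows = w$plate_rows, plate_cols = w$plate_cols)
  } else {
    list(mode = "explicit", well_ids = as.list(w$well_ids))
  }
  if (!is.null(spec$axis)) {
    a <- spec$axis
    out$axis <- switch(a$mode,
      explicit = list(mode = "explicit", values = as.list(a$values)),
      from_grid = list(mode = "from_grid", ref = blk_list(a$ref)),
      uniform = list(mode = "uniform", start = a$start, step = a$step))
  }
  out$sentinel_values <- as.list(spec$sentinel_values)
  if (!is.null(spec$dialect)) out$dialect <- spec$dialect
  if (!is.null(spec$sheet)) out$sheet <- spec$sheet
  if (!is.null(spec$delimiter)) out$delimiter <- spec$delimiter
  out
}

is_yaml_path <- function(path) grepl("\\.ya?ml$", tolower(path))

#' Save and load parser specifications
#'
#' `save_spec()` writes a spec as a versioned JSON document (or YAML when the
#' path ends in `.yaml`/`.yml`); `load_spec()` reads either and reconstructs
#' an identical spec (`load_spec(save_spec(spec))` equals `spec`
#' field-for-field). Block references in hand-written files may use either
#' `{"first": {"row": 3, "col": 2}, ...}` or spreadsheet notation
#' (`"first": "B3"`, or the whole block as `"B3:D10"`). Documents with a
#' different `schema_version`, missing required keys, out-of-enumeration
#' values or unknown keys are rejected with a message citing the offending
#' JSON path.
#'
#' @param spec A [parser_spec()].
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `save_spec()`: `path`, invisibly. `load_spec()`: a [parser_spec()].
#' @export
save_spec <- function(spec, path) {
  stopifnot(inherits(spec, "parser_spec"))
  lst <- spec_to_list(spec)
  ok <- tryCatch({
    if (is_yaml_path(path)) {
      yaml::write_yaml(lst, path)
    } else {
      jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    pp_abort("path_unwritable", sprintf(
      "cannot write spec to \"%s\": %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' @rdname save_spec
#' @export
load_spec <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    pp_abort("file_unreadable", sprintf("cannot read spec file \"%s\"", path))
  }
  doc <- tryCatch({
    if (is_yaml_path(path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = FALSE)
  }, error = function(e) {
    pp_abort("spec_schema_error", sprintf(
      "spec file \"%s\" is not well-formed: %s", path, conditionMessage(e)))
  })
  spec_from_list(doc, source = path)
}

schema_error <- function(source, json_path, msg) {
  pp_abort("spec_schema_error", sprintf(
    "spec \"%s\", at %s: %s", basename(source), json_path, msg))
}

need <- function(doc, key, source) {
  if (is.null(doc[[key]])) {
    schema_error(source, paste0("$.", key), "required field is missing")
  }
  doc[[key]]
}

need_enum <- function(doc, key, allowed, source) {
  v <- need(doc, key, source)
  if (!is.character(v) && !is.null(v)) v <- as.character(v)
  if (length(v) != 1 || !v %in% allowed) {
    schema_error(source, paste0("$.", key), sprintf(
      "value %s is not one of the allowed values: %s",
      deparse(as.character(v)), paste(sprintf("\"%s\"", allowed), collapse = ", ")))
  }
  v
}

PP_SPEC_KEYS <- c("schema_version", "data_format", "data_type", "first_block",
                  "num_readings", "reading_names", "block_stride",
                  "explicit_blocks", "wells", "axis", "sentinel_values",
                  "dialect", "sheet", "delimiter")

spec_from_list <- function(doc, source = "<in-memory>") {
  if (!is.list(doc)) {
    schema_error(source, "$", "document is not a JSON object")
  }
  unknown <- setdiff(names(doc), PP_SPEC_KEYS)
  if (length(unknown) > 0) {
    schema_error(source, paste0("$.", unknown[1]), sprintf(
      "unknown field(s): %s (this implementation understands schema %s)",
      paste(unknown, collapse = ", "), PP_SCHEMA_VERSION))
  }
  ver <- need(doc, "schema_version", source)
  if (!identical(as.character(ver), PP_SCHEMA_VERSION)) {
    schema_error(source, "$.schema_version", sprintf(
      "version \"%s\" is not supported (expected \"%s\")",
      as.character(ver), PP_SCHEMA_VERSION))
  }
  data_format <- need_enum(doc, "data_format", PP_FORMATS, source)
  data_type <- need_enum(doc, "data_type", PP_TYPES, source)

  wells_doc <- need(doc, "wells", source)
  wells_mode <- if (is.list(wells_doc)) wells_doc$mode else NULL
  wells <- if (identical(wells_mode, "plate")) {
    if (is.null(wells_doc$plate_rows) || is.null(wells_doc$plate_cols)) {
      schema_error(source, "$.wells", "plate mode requires plate_rows and plate_cols")
    }
    wells_plate(wells_doc$plate_rows, wells_doc$plate_cols)
  } else if (identical(wells_mode, "explicit")) {
    if (is.null(wells_doc$well_ids)) {
      schema_error(source, "$.wells.well_ids", "explicit mode requires well_ids")
    }
    wells_explicit(unlist(wells_doc$well_ids))
  } else {
    schema_error(source, "$.wells.mode",
                 "must be \"plate\" or \"explicit\"")
  }

  axis <- NULL
  if (!is.null(doc$axis)) {
    a <- doc$axis
    mode <- if (is.list(a)) a$mode else NULL
    axis <- if (identical(mode, "explicit")) {
      if (is.null(a$values)) schema_error(source, "$.axis.values", "explicit mode requires values")
      axis_explicit(unlist(a$values))
    } else if (identical(mode, "from_grid")) {
      if (is.null(a$ref)) schema_error(source, "$.axis.ref", "from_grid mode requires ref")
      axis_from_grid(as_block_range(a$ref, "axis reference"))
    } else if (identical(mode, "uniform")) {
      if (is.null(a$start) || is.null(a$step)) {
        schema_error(source, "$.axis", "uniform mode requires start and step")
      }
      axis_uniform(a$start, a$step)
    } else {
      schema_error(source, "$.axis.mode",
                   "must be \"explicit\", \"from_grid\" or \"uniform\"")
    }
  }

  explicit_blocks <- NULL
  if (!is.null(doc$explicit_blocks)) {
    explicit_blocks <- lapply(doc$explicit_blocks, as_block_range,
                              what = "explicit block")
  }

  spec <- tryCatch(
    parser_spec(
      data_format = data_format, data_type = data_type,
      first_block = as_block_range(need(doc, "first_block", source), "first_block"),
      num_readings = need(doc, "num_readings", source),
      reading_names = unlist(need(doc, "reading_names", source)),
      block_stride = doc$block_stride,
      explicit_blocks = explicit_blocks,
      wells = wells, axis = axis,
      sentinel_values = if (is.null(doc$sentinel_values)) default_sentinels()
                        else unlist(doc$sentinel_values),
      dialect = doc$dialect, sheet = doc$sheet, delimiter = doc$delimiter),
    plateparse_error_invalid_spec = function(e) {
      schema_error(source, "$", conditionMessage(e))
    })
  spec
}
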