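# Reshaping extracted values into a tidy long table and attaching metadata:
# the final, analysis-ready output. One row per well (x timepoint or
# x wavelength), one column per reading, metadata on the left.

#' Reshape extracted data into a tidy long table
#'
#' Produces the tidy form downstream analysis tools consume: long over wells
#' and axis points, wide over readings. Key columns are `well` plus `time`
#' (timecourse) or `wavelength` (spectrum); value columns carry the readings
#' in spec order. Rows are ordered well-major (all axis points of "A1", then
#' "A2", ...), wells in spec order and axis points in label order.
#'
#' @param extracted An `extracted_data` from [extract_all()].
#' @param spec The [parser_spec()] that produced it.
#' @param axis_name Override for the axis column name (default `"time"` for
#'   timecourse, `"wavelength"` for spectrum).
#' @return A tibble with `length(wells) * length(axis_labels)` rows.
#' @export
build_tidy <- function(extracted, spec, axis_name = NULL) {
  stopifnot(inherits(extracted, "extracted_data"), inherits(spec, "parser_spec"))
  wells <- rownames(extracted$readings[[1]]$values)
  labels <- extracted$axis_labels
  n_axis <- if (is.null(labels)) 1L else length(labels)
  out <- tibble(well = rep(wells, each = n_axis))
  if (!is.null(labels)) {
    nm <- axis_name %||% switch(spec$data_type,
                                timecourse = "time",
                                spectrum = "wavelength",
                                "axis")
    out[[nm]] <- rep(labels, times = length(wells))
  }
  for (r in extracted$readings) {
    # values is wells x axis; well-major flattening walks each well's series
    out[[r$name]] <- as.vector(t(r$values))
  }
  out
}

#' Join a tidy measurement table to experiment metadata
#'
#' Attaches the metadata columns on the canonical well key, metadata on the
#' left (its `well` column first) and measurements on the right. The join
#' never drops data: tidy rows whose well has no metadata are retained with
#' empty metadata fields, and a warning lists exactly the unmatched wells;
#' metadata rows for wells absent from the data are dropped, likewise with a
#' warning. Warnings never block output — degraded annotations must not cost
#' measurements.
#'
#' @param tidy A tibble from [build_tidy()] (first column `well`).
#' @param metadata A `metadata_table` from [read_metadata()], or any data
#'   frame with a `well` column.
#' @return A tibble: metadata columns (well first), then the axis column (if
#'   any), then the reading columns. Attribute `join_warnings` records the
#'   warning messages emitted.
#' @export
join_metadata <- function(tidy, metadata) {
  well_col <- attr(metadata, "well_column") %||% {
    hit <- which(tolower(trimws(names(metadata))) == "well")
    if (length(hit) == 0) {
      pp_abort("missing_well_column", sprintf(
        "metadata has no column resolving to \"well\"; columns found: %s",
        paste(sprintf("\"%s\"", names(metadata)), collapse = ", ")))
    }
    names(metadata)[hit[1]]
  }
  meta <- as_tibble(as.data.frame(metadata, stringsAsFactors = FALSE))
  meta[[well_col]] <- canonicalize_well(meta[[well_col]])
  # metadata file order, well moved to the front
  meta <- meta[, c(well_col, setdiff(names(meta), well_col)), drop = FALSE]
  names(meta)[1] <- "well"

  warnings <- character()
  data_wells <- unique(tidy$well)
  unmatched_data <- setdiff(data_wells, meta$well)
  if (length(unmatched_data) > 0) {
    msg <- sprintf("no metadata for well(s): %s (rows retained with empty metadata)",
                   paste(unmatched_data, collapse = ", "))
    warnings <- c(warnings, msg)
    pp_warn("unmatched_data_wells", msg, wells = unmatched_data)
  }
  unused_meta <- setdiff(meta$well, data_wells)
  if (length(unused_meta) > 0) {
    msg <- sprintf("metadata well(s) absent from the data: %s (dropped)",
                   paste(unused_meta, collapse = ", "))
    warnings <- c(warnings, msg)
    pp_warn("unused_metadata_wells", msg, wells = unused_meta)
  }

  joined <- dplyr::left_join(tidy, meta, by = "well")
  ord <- c(names(meta), setdiff(names(tidy), "well"))
  joined <- joined[, ord, drop = FALSE]
  attr(joined, "join_warnings") <- warnings
  joined
}

#' Write the joined table to disk
#'
#' UTF-8, one header row, missing values as empty fields, numbers at full
#' precision (a re-read reproduces the values exactly).
#'
#' @param joined A tibble (typically from [join_metadata()]).
#' @param path Output file path.
#' @param delim Field separator: `","` (default, CSV) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
write_output <- function(joined, path, delim = ",") {
  ok <- tryCatch({
    readr::write_delim(joined, path, delim = delim, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    pp_abort("path_unwritable", sprintf(
      "cannot write output to \"%s\": %s", path, conditionMessage(ok)))
  }
  invisible(path)
}
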